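# Structural annotation of discovered loci: paired/solitary LTR detection,
# U3/U5 truncation signatures, poly-A tails, target-site duplications, and
# the provirus / processed-pseudogene / solitary-LTR / undefined taxonomy.

.align_local <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1
  )
}

.safe_pid <- function(pa) {
  p <- suppressWarnings(Biostrings::pid(pa))
  if (!is.finite(p)) 0 else p
}

.align_global <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1
  )
}

#' Detect LTRs and integration signatures within a locus
#'
#' The two terminal windows of the locus (1.5 x the model LTR length each)
#' are aligned locally against each other to find a 5'/3' LTR pair, and
#' each window is aligned against the model LTR to decide which parts of an
#' LTR are present at each end. U3 presence at the 5' end and U5 presence
#' at the 3' end are the discriminating signature: both present in a
#' provirus, both absent in an L1-processed pseudogene. A poly-A tail is
#' called when at least `config$polya_min_a` of the terminal
#' `config$polya_window` nt (locus or immediately downstream flank) are A;
#' a target-site duplication is called when the flanks share an exact
#' terminal duplication of `config$tsd_min`..`config$tsd_max` nt.
#'
#' @param locus_seq Locus sequence, element orientation (reverse-complement
#'   minus-strand loci before calling; [annotate_loci()] does this).
#' @param model An [erv_model()] providing the LTR master and its U3/R/U5
#'   layout.
#' @param config A [pipeline_config()].
#' @param flank5,flank3 Optional flanks (element orientation) used for the
#'   TSD and poly-A calls.
#' @return A one-row tibble: LTR intervals (locus-relative, 0-based, NA if
#'   absent), `ltr_identity`, `has_u3_5prime`, `has_u5_3prime`, `polya`,
#'   `tsd`, `ltr5_cov`, `ltr3_cov` (nt of model LTR matched at each end).
#' @export
detect_ltrs <- function(locus_seq, model, config = pipeline_config(),
                        flank5 = "", flank3 = "") {
  L <- nchar(locus_seq)
  min_len <- min(200L, as.integer(ceiling(model$ltr_len / 2)))
  if (L < min_len) stop("detect_ltrs: locus shorter than ", min_len, " nt")
  W <- min(L, as.integer(round(1.5 * model$ltr_len)))
  w5 <- slice0(locus_seq, 0L, W)
  w3 <- slice0(locus_seq, L - W, L)
  w3_off <- L - W

  out <- tibble::tibble(
    ltr5_start0 = NA_integer_, ltr5_end0 = NA_integer_,
    ltr3_start0 = NA_integer_, ltr3_end0 = NA_integer_,
    ltr_identity = NA_real_,
    has_u3_5prime = FALSE, has_u5_3prime = FALSE,
    polya = FALSE, tsd = NA_character_,
    ltr5_cov = 0L, ltr3_cov = 0L
  )

  # paired LTRs: terminal windows against each other (skip if windows
  # overlap heavily, i.e. the locus is barely longer than one window)
  if (L >= W + 100L) {
    pa <- .align_local(w5, w3)
    alen <- Biostrings::nchar(pa)
    if (alen >= config$ltr_min_align &&
        .safe_pid(pa) / 100 >= config$ltr_min_identity) {
      p <- Biostrings::pattern(pa)
      s <- Biostrings::subject(pa)
      out$ltr5_start0 <- BiocGenerics::start(p) - 1L
      out$ltr5_end0 <- BiocGenerics::end(p)
      out$ltr3_start0 <- w3_off + BiocGenerics::start(s) - 1L
      out$ltr3_end0 <- w3_off + BiocGenerics::end(s)
      out$ltr_identity <- .safe_pid(pa) / 100
    }
  }

  # model-anchored termini: which part of an LTR is present at each end
  m5 <- .align_local(w5, model$ltr_seq)
  m3 <- .align_local(w3, model$ltr_seq)
  u3_iv <- c(0L, model$u3_len)
  u5_iv <- c(model$u3_len + model$r_len, model$ltr_len)
  cov_of <- function(pa, iv) {
    if (Biostrings::nchar(pa) < 30L || .safe_pid(pa) / 100 < 0.55) {
      return(0L)
    }
    s0 <- BiocGenerics::start(Biostrings::subject(pa)) - 1L
    e0 <- BiocGenerics::end(Biostrings::subject(pa))
    max(0L, min(e0, iv[2L]) - max(s0, iv[1L]))
  }
  m5_len <- if (.safe_pid(m5) / 100 >= 0.55) Biostrings::nchar(m5) else 0L
  m3_len <- if (.safe_pid(m3) / 100 >= 0.55) Biostrings::nchar(m3) else 0L
  out$ltr5_cov <- as.integer(m5_len)
  out$ltr3_cov <- as.integer(m3_len)
  out$has_u3_5prime <- cov_of(m5, u3_iv) >= config$seg_cov_frac * model$u3_len
  out$has_u5_3prime <- cov_of(m3, u5_iv) >= config$seg_cov_frac * model$u5_len

  # poly-A: any polya_window-sized window in the terminal region of the
  # locus (or just downstream of it) rich enough in A — tolerant of a few
  # extra nucleotides picked up by hit extension past the tail
  scan <- paste0(slice0(locus_seq, max(0L, L - 30L), L),
                 if (nchar(flank3)) substr(flank3, 1L, 15L) else "")
  sv <- strsplit(scan, "")[[1]] == "A"
  w <- config$polya_window
  out$polya <- length(sv) >= w &&
    max(vapply(seq_len(length(sv) - w + 1L),
               function(i) sum(sv[i:(i + w - 1L)]), integer(1))) >=
      config$polya_min_a

  # exact terminal target-site duplication shared by the flanks
  if (nchar(flank5) >= config$tsd_max && nchar(flank3) >= config$tsd_max) {
    for (s in config$tsd_max:config$tsd_min) {
      a <- substr(flank5, nchar(flank5) - s + 1L, nchar(flank5))
      b <- substr(flank3, 1L, s)
      if (identical(a, b)) { out$tsd <- a; break }
    }
  }
  out
}

#' Classify a locus from its LTR annotation
#'
#' Decision order: solitary LTR (no internal sequence), provirus (two
#' complete LTRs, U3 at the 5' end and U5 at the 3' end), processed
#' pseudogene (internal sequence with the truncated-LTR signature and/or a
#' poly-A tail), undefined (internal sequence but no LTR-derived termini).
#' The ambiguous case of one complete and one truncated LTR resolves to
#' processed pseudogene with a warning flag, since L1 truncation is
#' one-sided in practice.
#'
#' @param annotation One-row tibble from [detect_ltrs()].
#' @param internal_cov Coverage (nt) of the model internal region by the
#'   locus (from [merge_hits()] or an alignment).
#' @param config A [pipeline_config()].
#' @return A list with `structure` (one of `provirus`,
#'   `processed_pseudogene`, `solitary_ltr`, `undefined`, `unclassified`)
#'   and `flag` (character, possibly NA).
#' @export
classify_locus <- function(annotation, internal_cov,
                           config = pipeline_config()) {
  an <- annotation
  has_internal <- !is.na(internal_cov) && internal_cov >= config$internal_min_cov
  ltr_evidence <- max(an$ltr5_cov, an$ltr3_cov) >= config$ltr_min_align
  flag <- NA_character_
  label <-
    if (!has_internal) {
      if (ltr_evidence) "solitary_ltr" else "unclassified"
    } else if (!is.na(an$ltr_identity) && an$has_u3_5prime &&
               an$has_u5_3prime) {
      "provirus"
    } else if (an$polya || (!an$has_u3_5prime && !an$has_u5_3prime &&
                            ltr_evidence)) {
      if (xor(an$has_u3_5prime, an$has_u5_3prime)) {
        flag <- "one_complete_one_truncated_ltr"
      }
      "processed_pseudogene"
    } else if (!ltr_evidence) {
      "undefined"
    } else {
      flag <- "ambiguous_ltr_signature"
      "undefined"
    }
  list(structure = label, flag = flag)
}

#' Annotate and classify a table of loci
#'
#' Runs [detect_ltrs()] and [classify_locus()] over every locus of a
#' [discover_loci()] table. Minus-strand loci are reverse-complemented (and
#' their flanks swapped) before annotation, so 5'/3' signatures are always
#' reported in element orientation.
#'
#' @param loci Loci tibble from [discover_loci()]/[merge_hits()].
#' @param model An [erv_model()].
#' @param config A [pipeline_config()].
#' @return `loci` with annotation columns and `structure`/`struct_flag`
#'   appended.
#' @export
classify_loci <- function(loci, model, config = pipeline_config()) {
  if (!nrow(loci)) {
    return(dplyr::mutate(loci, structure = character(0),
                         struct_flag = character(0)))
  }
  ann <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    minus <- loci$strand[i] == "-"
    s <- if (minus) revcomp(loci$sequence[i]) else loci$sequence[i]
    min_len <- min(200L, as.integer(ceiling(model$ltr_len / 2)))
    if (nchar(s) < min_len) {
      # fragment too short to annotate at all
      a <- detect_ltrs(strrep("N", max(min_len, 10L)), model, config)
      return(dplyr::mutate(a, structure = "unclassified",
                           struct_flag = "too_short"))
    }
    f5 <- if (minus) revcomp(loci$flank3[i]) else loci$flank5[i]
    f3 <- if (minus) revcomp(loci$flank5[i]) else loci$flank3[i]
    a <- detect_ltrs(s, model, config, flank5 = f5, flank3 = f3)
    cl <- classify_locus(a, loci$internal_cov[i], config)
    dplyr::mutate(a, structure = cl$structure, struct_flag = cl$flag)
  })
  dplyr::bind_cols(loci, ann)
}

#' Date an insertion from the divergence of its two LTRs
#'
#' The two LTRs of a provirus are identical at integration, so their
#' Kimura 2-parameter distance `d` dates the insertion as `d / (2 * rate)`.
#' A binomial 95% confidence interval on the underlying mismatch proportion
#' is propagated through the K2P correction to an age interval. The
#' estimate is flagged unreliable when the alignment is shorter than 200 nt
#' or `d > 0.3`.
#'
#' @param ltr5,ltr3 LTR sequences (either order).
#' @param rate Substitution rate, substitutions/site/MY.
#' @return A one-row tibble: `d_k2p`, `age_mya`, `age_lo`, `age_hi`,
#'   `n_sites`, `unreliable`.
#' @export
#' @examples
#' ltr_age("ACGTACGTAC", "ACGTACGTAC", rate = 2.2e-3)  # age 0
ltr_age <- function(ltr5, ltr3, rate = 2.2e-3) {
  if (is.null(ltr5) || is.null(ltr3) || !nchar(ltr5) || !nchar(ltr3) ||
      is.na(ltr5) || is.na(ltr3)) {
    stop("ltr_age: both LTR sequences are required")
  }
  pa <- .align_global(ltr5, ltr3)
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  cmp <- .pairwise_site_classes(a, b)
  n <- cmp$n_sites
  if (n < 1L) stop("ltr_age: no comparable sites")
  d <- k2p_from_counts(cmp$n_ts, cmp$n_tv, n)
  # Clopper-Pearson CI on the mismatch proportion, P:Q split preserved
  mism <- cmp$n_ts + cmp$n_tv
  p_lo <- if (mism == 0L) 0 else stats::qbeta(0.025, mism, n - mism + 1)
  p_hi <- stats::qbeta(0.975, mism + 1, n - mism)
  frac_ts <- if (mism > 0L) cmp$n_ts / mism else 2 / 3
  d_lo <- k2p_from_counts(p_lo * frac_ts * n, p_lo * (1 - frac_ts) * n, n)
  d_hi <- k2p_from_counts(p_hi * frac_ts * n, p_hi * (1 - frac_ts) * n, n)
  tibble::tibble(
    d_k2p = d, age_mya = d / (2 * rate),
    age_lo = d_lo / (2 * rate), age_hi = d_hi / (2 * rate),
    n_sites = n,
    unreliable = n < 200L || (is.finite(d) && d > 0.3) || !is.finite(d)
  )
}

#' Extract putative proteins (puteins) from an element consensus
#'
#' Translates the consensus in all three frames on both strands, collects
#' open reading frames (ATG to stop, or running into the sequence end), and
#' reports for each model gene (gag, pol, env) the longest ORF overlapping
#' the gene's segment. Genes whose best ORF covers less than
#' `min_cov_frac` of the segment are flagged disrupted.
#'
#' @param consensus Element-orientation DNA string (full-element layout, as
#'   produced by consensus building over proviral copies).
#' @param model An [erv_model()].
#' @param min_cov_frac Segment coverage below which a gene is flagged
#'   disrupted.
#' @return A tibble with one row per gene: `gene`, `aa_seq`, `frame`
#'   (0..2), `strand`, `start0`, `end0` (nt, consensus coordinates),
#'   `disrupted`.
#' @export
find_puteins <- function(consensus, model, min_cov_frac = 0.8) {
  L <- nchar(consensus)
  min_len <- min(1000L, nchar(model$internal_seq))
  if (L < min_len) {
    stop("find_puteins: consensus shorter than ", min_len, " nt")
  }
  genes <- model$segments[model$segments$segment %in% c("gag", "pol", "env"), ]

  orfs <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") consensus else revcomp(consensus)
    for (frame in 0:2) {
      sub <- substr(s, frame + 1L, L)
      sub <- substr(sub, 1L, 3L * (nchar(sub) %/% 3L))
      if (nchar(sub) < 3L) next
      aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X")))
      # ORFs: ATG .. stop (or sequence end)
      m <- gregexpr("M[^*]*", aa)[[1]]
      if (m[1] == -1L) next
      for (j in seq_along(m)) {
        aa_start <- m[j]
        aa_len <- attr(m, "match.length")[j]
        if (aa_len < 10L) next
        nt_start <- frame + (aa_start - 1L) * 3L          # 0-based, on s
        nt_end <- nt_start + aa_len * 3L
        # map to plus-strand consensus coordinates
        if (strand == "+") {
          s0 <- nt_start; e0 <- nt_end
        } else {
          s0 <- L - nt_end; e0 <- L - nt_start
        }
        orfs[[length(orfs) + 1L]] <- tibble::tibble(
          aa_seq = substr(aa, aa_start, aa_start + aa_len - 1L),
          frame = frame, strand = strand, start0 = s0, end0 = e0,
          aa_len = aa_len
        )
      }
    }
  }
  orfs <- dplyr::bind_rows(orfs)
  if (nrow(orfs)) {
    # ORF interval in element orientation: a minus-strand ORF at plus
    # coordinates [s, e) sits at [L - e, L - s) of the element read 5'->3'
    orfs$el_start0 <- ifelse(orfs$strand == "+", orfs$start0,
                             L - orfs$end0)
    orfs$el_end0 <- ifelse(orfs$strand == "+", orfs$end0, L - orfs$start0)
  }

  purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
    g0 <- genes$start0[gi]; g1 <- genes$end0[gi]
    cand <- if (nrow(orfs)) {
      dplyr::filter(orfs,
                    pmin(.data$el_end0, g1) - pmax(.data$el_start0, g0) > 0)
    } else orfs
    if (!is.null(cand) && nrow(cand)) {
      best <- cand[order(-cand$aa_len, cand$start0), ][1L, ]
      cov <- (min(best$el_end0, g1) - max(best$el_start0, g0)) / (g1 - g0)
      tibble::tibble(gene = genes$segment[gi], aa_seq = best$aa_seq,
                     frame = best$frame, strand = best$strand,
                     start0 = best$start0, end0 = best$end0,
                     disrupted = cov < min_cov_frac)
    } else {
      tibble::tibble(gene = genes$segment[gi], aa_seq = "",
                     frame = NA_integer_, strand = NA_character_,
                     start0 = NA_integer_, end0 = NA_integer_,
                     disrupted = TRUE)
    }
  })
}
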