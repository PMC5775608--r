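# BLAT-like similarity search: an exact k-mer seed index over the plus
# strand of each contig, seed chaining by diagonal, and ungapped X-drop
# extension. Minus-strand hits are found by searching the reverse
# complement of the query; target coordinates are always reported on the
# plus strand with a strand flag.

#' Build a k-mer seed index over a genome sequence
#'
#' Indexes every position of every k-mer free of N in the plus strand.
#' Queries against the minus strand are served by searching the reverse
#' complement of the query against this same index.
#'
#' @param seq DNA string, or a one-row genome tibble with `seq`,
#'   `contig_id`, `species_id`.
#' @param k k-mer size (>= 8; must not exceed the sequence length).
#' @param contig_id,species_id Identifiers attached to reported hits.
#' @return An object of class `erv_seed_index`.
#' @export
#' @examples
#' idx <- build_seed_index("ACGTACGT", k = 4)
#' seed_positions(idx, "ACGT")
build_seed_index <- function(seq, k = 12L, contig_id = "chr1",
                             species_id = "genome") {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    contig_id <- seq$contig_id
    species_id <- seq$species_id %||% species_id
    seq <- seq$seq
  }
  k <- as.integer(k)
  if (k < 8L && k < nchar(seq)) {
    # small k permitted for toy examples, but warn-free; hard floor is 2
    if (k < 2L) stop("build_seed_index: k must be >= 2")
  }
  if (k > nchar(seq)) stop("build_seed_index: k exceeds sequence length")
  x <- encode_dna(seq)
  ids <- kmer_ids(x, k)
  dt <- data.table::data.table(kmer = ids,
                               pos = 0:(length(ids) - 1L))
  dt <- dt[!is.na(dt$kmer)]
  data.table::setkeyv(dt, "kmer")
  structure(list(dt = dt, x = x, seq = seq, k = k, len = nchar(seq),
                 contig_id = contig_id, species_id = species_id),
            class = "erv_seed_index")
}

# rolling k-mer ids (base-4); NA wherever the window touches an N
kmer_ids <- function(x, k) {
  n <- length(x) - k + 1L
  if (n < 1L) return(numeric(0))
  id <- numeric(n)
  for (j in seq_len(k)) id <- id * 4 + x[j:(n + j - 1L)]
  id
}

#' @rdname build_seed_index
#' @param index An `erv_seed_index`.
#' @param kmer A k-mer string of the indexed size.
#' @return `seed_positions()`: integer vector of 0-based match positions.
#' @export
seed_positions <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  id <- kmer_ids(encode_dna(kmer), index$k)
  if (is.na(id)) return(integer(0))
  sort(index$dt[list(id), on = "kmer", nomatch = NULL]$pos)
}

#' @export
print.erv_seed_index <- function(x, ...) {
  cat("<erv_seed_index> ", x$species_id, ":", x$contig_id, " — ",
      x$len, " nt, k = ", x$k, ", ", nrow(x$dt), " indexed positions\n",
      sep = "")
  invisible(x)
}

# one strand pass: seeds of `qx` (encoded query) against the index, chained
# and extended; returns a data.frame of hit candidates
.search_one_strand <- function(index, qx, config) {
  k <- index$k
  qids <- kmer_ids(qx, k)
  if (!length(qids)) return(NULL)
  q <- data.table::data.table(kmer = qids, qpos = 0:(length(qids) - 1L))
  q <- q[!is.na(q$kmer)]
  if (!nrow(q)) return(NULL)
  hits <- index$dt[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(NULL)
  hits[, "diag" := hits$pos - hits$qpos]
  data.table::setorderv(hits, c("diag", "pos"))
  d <- hits$diag
  p <- hits$pos
  brk <- c(TRUE, abs(diff(d)) > config$band_width |
                 diff(p) > config$chain_gap | diff(p) < 0)
  cid <- cumsum(brk)
  ch <- hits[, list(qs = min(.SD$qpos), qe = max(.SD$qpos) + k,
                    diag0 = .SD$diag[(.N + 1L) %/% 2L],   # sorted: median
                    n_seeds = .N),
             by = list(chain = cid)]
  ch <- ch[ch$n_seeds >= config$min_chain_seeds]
  if (!nrow(ch)) return(NULL)
  tx <- index$x
  out <- matrix(NA_real_, nrow(ch), 6L)
  for (i in seq_len(nrow(ch))) {
    # re-anchor the chain on its median diagonal so extension is ungapped
    qs <- ch$qs[i]; qe <- ch$qe[i]
    ts <- qs + ch$diag0[i]; te <- qe + ch$diag0[i]
    if (ts < 0L) { qs <- qs - ts; ts <- 0L }
    if (te > length(tx)) { qe <- qe - (te - length(tx)); te <- length(tx) }
    if (qe - qs < k) next
    out[i, ] <- .extend_ungapped(qx, tx, qs, qe, ts, te, config$xdrop)
  }
  kept <- !is.na(out[, 1L])
  if (!any(kept)) return(NULL)
  res <- data.frame(qstart0 = out[kept, 1L], qend0 = out[kept, 2L],
                    tstart0 = out[kept, 3L], tend0 = out[kept, 4L],
                    aligned_len = out[kept, 5L], identity = out[kept, 6L])
  res$n_seeds <- ch$n_seeds[kept]
  res
}

# ungapped X-drop extension of a chained seed block; returns data.frame with
# final query/target intervals and identity
.extend_ungapped <- function(qx, tx, qs, qe, ts, te, xdrop, cap = 3000L) {
  # left
  m <- min(qs, ts, cap)
  if (m > 0L) {
    eq <- qx[qs:(qs - m + 1L)] == tx[ts:(ts - m + 1L)]
    eq[is.na(eq)] <- FALSE
    sc <- cumsum(ifelse(eq, 1L, -1L))
    stop_at <- which(cummax(sc) - sc > xdrop)[1L]
    lim <- if (is.na(stop_at)) m else stop_at
    ext_l <- which.max(sc[seq_len(lim)])
    if (sc[ext_l] <= 0L) ext_l <- 0L
  } else ext_l <- 0L
  # right
  m <- min(length(qx) - qe, length(tx) - te, cap)
  if (m > 0L) {
    eq <- qx[(qe + 1L):(qe + m)] == tx[(te + 1L):(te + m)]
    eq[is.na(eq)] <- FALSE
    sc <- cumsum(ifelse(eq, 1L, -1L))
    stop_at <- which(cummax(sc) - sc > xdrop)[1L]
    lim <- if (is.na(stop_at)) m else stop_at
    ext_r <- which.max(sc[seq_len(lim)])
    if (sc[ext_r] <= 0L) ext_r <- 0L
  } else ext_r <- 0L
  qs2 <- qs - ext_l; qe2 <- qe + ext_r
  ts2 <- ts - ext_l; te2 <- te + ext_r
  eq <- qx[(qs2 + 1L):qe2] == tx[(ts2 + 1L):te2]
  eq[is.na(eq)] <- FALSE
  c(qs2, qe2, ts2, te2, qe2 - qs2, mean(eq))
}

#' Search a query sequence against a genome
#'
#' Seed-and-extend similarity search: exact k-mers of the query are looked
#' up in the genome's seed index, chained by diagonal proximity, and
#' extended without gaps under an X-drop rule. Both strands are searched;
#' target coordinates are always on the plus strand. Hits shorter than
#' `config$min_hit_len` or below `config$min_hit_identity` are discarded.
#'
#' @param query DNA string.
#' @param genome An `erv_seed_index`, a DNA string, or a one-row genome
#'   tibble.
#' @param config A [pipeline_config()].
#' @param both_strands Search the reverse complement of the query as well.
#' @return A tibble of hits: `species_id`, `contig_id`, `tstart0`, `tend0`,
#'   `strand`, `qstart0`, `qend0` (plus-query coordinates), `identity`,
#'   `aligned_len`, `n_seeds`.
#' @export
search_genome <- function(query, genome, config = pipeline_config(),
                          both_strands = TRUE) {
  index <- if (inherits(genome, "erv_seed_index")) genome
           else build_seed_index(genome, k = config$seed_k)
  if (nchar(query) < index$k) {
    stop("search_genome: query shorter than the index k-mer size")
  }
  qlen <- nchar(query)
  fwd <- .search_one_strand(index, encode_dna(query), config)
  if (!is.null(fwd) && nrow(fwd)) fwd$strand <- "+"
  rev <- NULL
  if (both_strands) {
    rev <- .search_one_strand(index, encode_dna(revcomp(query)), config)
    if (!is.null(rev) && nrow(rev)) {
      rev$strand <- "-"
      qs <- qlen - rev$qend0          # map back to plus-query coordinates
      rev$qend0 <- qlen - rev$qstart0
      rev$qstart0 <- qs
    }
  }
  res <- rbind(fwd, rev)
  if (is.null(res) || !nrow(res)) {
    return(tibble::tibble(species_id = character(), contig_id = character(),
                          tstart0 = integer(), tend0 = integer(),
                          strand = character(), qstart0 = integer(),
                          qend0 = integer(), identity = numeric(),
                          aligned_len = integer(), n_seeds = integer()))
  }
  res <- res[res$aligned_len >= config$min_hit_len &
               res$identity >= config$min_hit_identity, , drop = FALSE]
  res <- res[order(res$tstart0, res$tend0, res$strand), , drop = FALSE]
  # identical hits can arise from repeated query regions (the two LTRs)
  res <- res[!duplicated(res[, c("tstart0", "tend0", "strand")]), ,
             drop = FALSE]
  tibble::tibble(species_id = index$species_id, contig_id = index$contig_id,
                 tstart0 = as.integer(res$tstart0),
                 tend0 = as.integer(res$tend0), strand = res$strand,
                 qstart0 = as.integer(res$qstart0),
                 qend0 = as.integer(res$qend0),
                 identity = res$identity,
                 aligned_len = as.integer(res$aligned_len),
                 n_seeds = as.integer(res$n_seeds))
}

#' Merge hits into candidate loci with flanking context
#'
#' Same-strand hits whose target intervals lie within `config$merge_gap` of
#' each other are merged transitively into one locus; merged loci never
#' overlap. Flanks of `config$flank_len` are extracted on each side
#' (truncated at contig ends with a warning). Locus ids are deterministic:
#' `species.contig.start-end` (0-based).
#'
#' @param hits A hits tibble from [search_genome()] (one genome).
#' @param genome The genome searched: an `erv_seed_index`, DNA string, or
#'   one-row genome tibble (needed to extract sequence and flanks).
#' @param config A [pipeline_config()].
#' @param model Optional [erv_model()]; when given, per-locus coverage of
#'   the model's internal region and LTRs by the hits' query intervals is
#'   recorded (`internal_cov`, `ltr_cov` in nt).
#' @return A loci tibble: `locus_id`, `species_id`, `contig_id`, `start0`,
#'   `end0`, `strand`, `identity`, `n_hits`, `internal_cov`, `ltr_cov`,
#'   `sequence`, `flank5`, `flank3`.
#' @export
merge_hits <- function(hits, genome, config = pipeline_config(),
                       model = NULL) {
  seq <- if (inherits(genome, "erv_seed_index")) genome$seq
         else if (is.data.frame(genome)) genome$seq[[1]]
         else genome
  glen <- nchar(seq)
  empty <- tibble::tibble(locus_id = character(), species_id = character(),
                          contig_id = character(), start0 = integer(),
                          end0 = integer(), strand = character(),
                          identity = numeric(), n_hits = integer(),
                          internal_cov = integer(), ltr_cov = integer(),
                          sequence = character(), flank5 = character(),
                          flank3 = character())
  if (!nrow(hits)) return(empty)

  seg_cov <- function(qs, qe, s0, e0) {
    # total coverage (nt) of [s0,e0) by the union of [qs,qe) intervals
    if (!length(qs)) return(0L)
    qs <- pmax(qs, s0); qe <- pmin(qe, e0)
    keep <- qe > qs
    if (!any(keep)) return(0L)
    qs <- qs[keep]; qe <- qe[keep]
    o <- order(qs)
    qs <- qs[o]; qe <- qe[o]
    tot <- 0L; cur_s <- qs[1L]; cur_e <- qe[1L]
    for (i in seq_along(qs)[-1L]) {
      if (qs[i] <= cur_e) cur_e <- max(cur_e, qe[i])
      else { tot <- tot + (cur_e - cur_s); cur_s <- qs[i]; cur_e <- qe[i] }
    }
    as.integer(tot + (cur_e - cur_s))
  }

  res <- hits |>
    dplyr::group_by(.data$species_id, .data$contig_id, .data$strand) |>
    dplyr::arrange(.data$tstart0, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(
      c(TRUE, .data$tstart0[-1L] >
          cummax(.data$tend0)[-dplyr::n()] + config$merge_gap))) |>
    dplyr::group_by(.data$cluster, .add = TRUE) |>
    dplyr::summarise(
      start0 = min(.data$tstart0), end0 = max(.data$tend0),
      identity = sum(.data$identity * .data$aligned_len) /
        sum(.data$aligned_len),
      n_hits = dplyr::n(),
      internal_cov = if (is.null(model)) NA_integer_ else seg_cov(
        .data$qstart0, .data$qend0,
        model$segments$start0[model$segments$segment == "pre_gag"],
        model$segments$end0[model$segments$segment == "env"]),
      ltr_cov = if (is.null(model)) NA_integer_ else {
        seg_cov(.data$qstart0, .data$qend0, 0L, model$ltr_len) +
          seg_cov(.data$qstart0, .data$qend0,
                  nchar(model$query_seq) - model$ltr_len,
                  nchar(model$query_seq))
      },
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$contig_id, .data$start0, .data$strand)

  if (any(res$start0 < config$flank_len | res$end0 > glen - config$flank_len)) {
    warning("merge_hits: flank(s) truncated at contig end")
  }
  res |>
    dplyr::mutate(
      locus_id = paste0(.data$species_id, ".", .data$contig_id, ".",
                        .data$start0, "-", .data$end0),
      sequence = slice0(seq, .data$start0, .data$end0),
      flank5 = slice0(seq, pmax(0L, .data$start0 - config$flank_len),
                      .data$start0),
      flank3 = slice0(seq, .data$end0,
                      pmin(glen, .data$end0 + config$flank_len))
    ) |>
    dplyr::select(dplyr::all_of(names(empty)))
}

#' Discover candidate ERV loci in a genome
#'
#' Convenience wrapper running [search_genome()] and [merge_hits()] per
#' contig with the model's assembled LTR-internal-LTR query.
#'
#' @param genome Genome tibble (one or more contigs of one species).
#' @param model An [erv_model()] (or a plain query string).
#' @param config A [pipeline_config()].
#' @param index Optional pre-built `erv_seed_index` (single-contig genomes
#'   only) to avoid re-indexing.
#' @return A loci tibble (see [merge_hits()]).
#' @export
discover_loci <- function(genome, model, config = pipeline_config(),
                          index = NULL) {
  query <- if (inherits(model, "erv_model")) model$query_seq else model
  mdl <- if (inherits(model, "erv_model")) model else NULL
  rows <- split(genome, seq_len(nrow(genome)))
  out <- lapply(rows, function(g) {
    idx <- if (!is.null(index) && nrow(genome) == 1L) index
           else build_seed_index(g$seq, k = config$seed_k,
                                 contig_id = g$contig_id,
                                 species_id = g$species_id)
    merge_hits(search_genome(query, idx, config), idx, config, model = mdl)
  })
  dplyr::bind_rows(out)
}
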