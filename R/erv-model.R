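#' Model of an endogenous retrovirus element
#'
#' Holds the master sequences from which simulated insertions are copied and
#' against which discovered loci are annotated. A full provirus is
#' LTR–internal–LTR; each LTR is partitioned U3 | R | U5, and the internal
#' region is segmented pre-gag | gag | pol | env. The gag/pol/env segments
#' are generated as intact open reading frames (ATG start, no internal stop,
#' terminal stop) so that putein extraction from an undecayed consensus has
#' a defined truth. L1-mediated processed pseudogene copies of the element
#' lack the 5' LTR U3 and the 3' LTR U5 and carry a poly-A tail.
#'
#' @param ltr_len,u3_len,r_len,u5_len LTR length and its U3/R/U5 partition
#'   (nt); the partition must sum to `ltr_len`.
#' @param internal_segments Named integer vector of internal segment lengths
#'   in order `pre_gag`, `gag`, `pol`, `env`; gene segments must be
#'   multiples of 3.
#' @param tsd_len Target-site duplication length (nt) generated on
#'   integration.
#' @param polya_len Poly-A tail length (nt) appended to processed
#'   pseudogenes.
#' @param seed Optional seed for the master-sequence draw.
#' @param ltr_seq,internal_seq Optional explicit master sequences overriding
#'   the random draw (lengths must match the declared layout).
#'
#' @return An object of class `erv_model`: master sequences, a `segments`
#'   tibble of element-relative 0-based intervals, and `query_seq`, the
#'   assembled LTR-internal-LTR search query.
#' @export
#' @examples
#' m <- erv_model(seed = 1)
#' m$segments
erv_model <- function(ltr_len = 780L, u3_len = 455L, r_len = 70L,
                      u5_len = 255L,
                      internal_segments = c(pre_gag = 1900L, gag = 1500L,
                                            pol = 2400L, env = 1200L),
                      tsd_len = 4L, polya_len = 12L, seed = NULL,
                      ltr_seq = NULL, internal_seq = NULL) {
  ltr_len <- as.integer(ltr_len)
  u3_len <- as.integer(u3_len); r_len <- as.integer(r_len)
  u5_len <- as.integer(u5_len)
  internal_segments <- vapply(internal_segments, as.integer, integer(1))
  if (u3_len + r_len + u5_len != ltr_len) {
    stop("erv_model: u3_len + r_len + u5_len must equal ltr_len")
  }
  if (any(c(u3_len, r_len, u5_len, internal_segments, tsd_len,
            polya_len) <= 0L)) {
    stop("erv_model: all segment lengths must be positive")
  }
  need <- c("pre_gag", "gag", "pol", "env")
  if (!identical(names(internal_segments), need)) {
    stop("erv_model: internal_segments must be named ",
         paste(need, collapse = ", "), " in that order")
  }
  if (any(internal_segments[c("gag", "pol", "env")] %% 3L != 0L)) {
    stop("erv_model: gene segment lengths must be multiples of 3")
  }

  ltr_seq <- ltr_seq %||% with_seed(seed, random_dna(ltr_len))
  if (nchar(ltr_seq) != ltr_len) stop("erv_model: ltr_seq length mismatch")
  if (is.null(internal_seq)) {
    internal_seq <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
      paste0(random_dna(internal_segments[["pre_gag"]]),
             random_orf(internal_segments[["gag"]]),
             random_orf(internal_segments[["pol"]]),
             random_orf(internal_segments[["env"]]))
    })
  }
  if (nchar(internal_seq) != sum(internal_segments)) {
    stop("erv_model: internal_seq length mismatch")
  }

  int_start <- ltr_len
  seg_ends <- int_start + cumsum(internal_segments)
  segments <- tibble::tibble(
    segment = c("ltr5", need, "ltr3"),
    start0 = c(0L, int_start, seg_ends[-4L], seg_ends[4L]),
    end0 = c(int_start, seg_ends, seg_ends[4L] + ltr_len)
  )
  structure(list(
    ltr_seq = ltr_seq, internal_seq = internal_seq,
    ltr_len = ltr_len, u3_len = u3_len, r_len = r_len, u5_len = u5_len,
    internal_segments = internal_segments,
    tsd_len = as.integer(tsd_len), polya_len = as.integer(polya_len),
    segments = segments,
    query_seq = paste0(ltr_seq, internal_seq, ltr_seq)
  ), class = "erv_model")
}

# random open reading frame: ATG + non-stop codons + TAA, length n (mult. of 3)
random_orf <- function(n) {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                  paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG",
         paste(sample(codons, n / 3L - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

#' @export
print.erv_model <- function(x, ...) {
  cat("<erv_model> LTR ", x$ltr_len, " nt (U3 ", x$u3_len, " | R ", x$r_len,
      " | U5 ", x$u5_len, "), internal ", nchar(x$internal_seq),
      " nt, query ", nchar(x$query_seq), " nt\n", sep = "")
  invisible(x)
}

#' Element sequences realized by each formation mechanism
#'
#' `build_provirus()` returns the full LTR-internal-LTR copy;
#' `build_processed_pseudogene()` returns the L1-retrotransposed copy: a 5'
#' LTR reduced to R+U5, the internal region, a 3' LTR reduced to U3+R, and a
#' poly-A tail.
#'
#' @param model An [erv_model()].
#' @return A DNA string.
#' @export
build_provirus <- function(model) {
  model$query_seq
}

#' @rdname build_provirus
#' @export
build_processed_pseudogene <- function(model) {
  L <- model$ltr_len
  paste0(
    slice0(model$ltr_seq, model$u3_len, L),             # R + U5
    model$internal_seq,
    slice0(model$ltr_seq, 0L, model$u3_len + model$r_len), # U3 + R
    strrep("A", model$polya_len)
  )
}

#' Collapse a provirus to a solitary LTR by LTR-LTR recombination
#'
#' Homologous recombination between the two LTRs of a provirus removes the
#' internal region and one LTR, leaving a single chimeric LTR: the 5' part
#' of the 5' LTR joined to the 3' part of the 3' LTR at the crossover.
#' Processed pseudogenes are refused: their truncated LTRs lack the extended
#' homology this recombination requires, and no solitary LTR with pseudogene
#' signatures has been observed.
#'
#' @param element_seq Element sequence (element orientation).
#' @param mechanism Formation mechanism of the element; must be
#'   `"provirus"`.
#' @param ltr_len LTR length within `element_seq`.
#' @param crossover 0-based position of the crossover within the LTR;
#'   `NULL` draws it uniformly from `1:(ltr_len - 1)`.
#' @param min_identity Minimum identity between the two LTRs for
#'   recombination to be considered possible.
#' @return The recombinant LTR sequence.
#' @export
apply_ltr_recombination <- function(element_seq, mechanism = "provirus",
                                    ltr_len, crossover = NULL,
                                    min_identity = 0.80) {
  if (!identical(mechanism, "provirus")) {
    stop("apply_ltr_recombination: only proviruses recombine via LTR-LTR ",
         "homology (got mechanism \"", mechanism, "\")")
  }
  n <- nchar(element_seq)
  if (n < 2L * ltr_len) stop("apply_ltr_recombination: element too short")
  ltr5 <- slice0(element_seq, 0L, ltr_len)
  ltr3 <- slice0(element_seq, n - ltr_len, n)
  if (string_identity(ltr5, ltr3) < min_identity) {
    stop("apply_ltr_recombination: LTRs below ", min_identity,
         " identity; homologous recombination implausible")
  }
  x <- as.integer(crossover %||% sample.int(ltr_len - 1L, 1L))
  stopifnot(x >= 1L, x <= ltr_len - 1L)
  paste0(slice0(ltr5, 0L, x), slice0(ltr3, x, ltr_len))
}
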