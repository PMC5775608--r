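# Alignment-based comparative statistics: pairwise and progressive
# alignment, majority-rule consensus, CpG-stripped p-distance, Kimura
# 2-parameter distance, neighbor-joining trees with bootstrap support, and
# windowed dot-plots.

#' Alignment container
#'
#' An `erv_alignment` is a named character vector of equal-length aligned
#' rows (gaps as `-`).
#'
#' @param x Named character vector of aligned sequences.
#' @return An `erv_alignment`.
#' @export
as_alignment <- function(x) {
  x <- toupper(unlist(x))
  if (length(unique(nchar(x))) != 1L) {
    stop("as_alignment: rows differ in length")
  }
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  structure(x, class = "erv_alignment")
}

#' @export
print.erv_alignment <- function(x, ...) {
  cat("<erv_alignment> ", length(x), " rows x ", nchar(x[[1]]),
      " columns\n", sep = "")
  invisible(x)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), ""))
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (match +1, mismatch
#' -1, gap opening 4, gap extension 1) via Biostrings, returned as a
#' two-row [as_alignment()] with a `score` attribute.
#'
#' @param a,b DNA strings.
#' @return An `erv_alignment` of `a` and `b`.
#' @export
#' @examples
#' pairwise_align("ACGT", "AGT")
pairwise_align <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("pairwise_align: empty input")
  pa <- .align_global(a, b)
  out <- as_alignment(c(a = as.character(Biostrings::alignedPattern(pa)),
                        b = as.character(Biostrings::alignedSubject(pa))))
  attr(out, "score") <- BiocGenerics::score(pa)
  out
}

#' Progressive multiple sequence alignment
#'
#' Aligns a set of sequences with MAFFT (the standard progressive/iterative
#' aligner for this kind of data, available on the command line), preserving
#' input order and names. Every input is recoverable from its alignment row
#' by gap removal. A single sequence is returned unchanged.
#'
#' @param seqs Named character vector of DNA sequences (>= 1).
#' @param mafft_args Extra MAFFT arguments.
#' @return An `erv_alignment`.
#' @export
progressive_msa <- function(seqs, mafft_args = c("--retree", "2")) {
  seqs <- unlist(seqs)
  if (!length(seqs)) stop("progressive_msa: no sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  if (length(seqs) == 1L) return(as_alignment(seqs))
  if (Sys.which("mafft") == "") {
    stop("progressive_msa: the `mafft` executable is required but not found")
  }
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)))
  # write with positional names to survive any name mangling
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fin)
  status <- system2("mafft", c(mafft_args, "--quiet", "--inputorder", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) stop("progressive_msa: mafft exited with status ", status)
  out <- Biostrings::readBStringSet(fout)
  rows <- toupper(as.character(out))
  ord <- match(paste0("s", seq_along(seqs)), sub("\\s.*$", "", names(out)))
  rows <- unname(rows[ord])
  names(rows) <- names(seqs)
  aln <- as_alignment(rows)
  stripped <- gsub("-", "", unclass(aln))
  if (!identical(unname(stripped), unname(toupper(seqs)))) {
    stop("progressive_msa: aligner output does not round-trip to its input")
  }
  aln
}

#' Majority-rule consensus of an alignment
#'
#' Per column: if gaps hold a strict majority the column is deleted;
#' otherwise the most frequent residue is emitted, with ties between
#' residues emitting `N`. The per-column support (frequency of the emitted
#' residue among rows) is recorded.
#'
#' @param alignment An [as_alignment()] (>= 2 rows).
#' @param min_support Retained for interface symmetry; the majority rule is
#'   strict (> 0.5) for gap deletion.
#' @return An object of class `erv_consensus`: list with `seq` and
#'   `support`.
#' @export
#' @examples
#' majority_consensus(as_alignment(c("AAA", "AAA", "AAT")))
majority_consensus <- function(alignment, min_support = 0.5) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("majority_consensus: need >= 2 rows")
  cons <- character(0)
  supp <- numeric(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (sum(col == "-") > n / 2) next                 # strict-majority gap
    res <- col[col != "-"]
    tab <- sort(table(res), decreasing = TRUE)
    top <- names(tab)[tab == tab[1L]]
    cons <- c(cons, if (length(top) > 1L) "N" else top)
    supp <- c(supp, tab[[1L]] / n)
  }
  structure(list(seq = paste(cons, collapse = ""), support = supp),
            class = "erv_consensus")
}

#' @export
print.erv_consensus <- function(x, ...) {
  cat("<erv_consensus> ", nchar(x$seq), " nt, mean support ",
      round(mean(x$support), 3), "\n", sep = "")
  invisible(x)
}

# -- pairwise distances -------------------------------------------------

.TS_PAIRS <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

# classify comparable sites of two aligned rows (pairwise deletion)
.pairwise_site_classes <- function(a, b, keep = NULL) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  use <- av %in% DNA_BASES & bv %in% DNA_BASES
  if (!is.null(keep)) use <- use & keep
  av <- av[use]; bv <- bv[use]
  mism <- av != bv
  pair <- paste0(av[mism], bv[mism])
  n_ts <- sum(pair %in% names(.TS_PAIRS))
  list(n_sites = length(av), n_ts = n_ts, n_tv = sum(mism) - n_ts)
}

# columns that are part of a CG dinucleotide in either row, skipping gaps
# when testing adjacency
.cpg_columns <- function(rows) {
  L <- nchar(rows[[1]])
  drop <- rep(FALSE, L)
  for (r in rows) {
    v <- strsplit(r, "")[[1]]
    idx <- which(v != "-")
    if (length(idx) < 2L) next
    res <- v[idx]
    cg <- which(res[-length(res)] == "C" & res[-1L] == "G")
    if (length(cg)) drop[c(idx[cg], idx[cg + 1L])] <- TRUE
  }
  drop
}

#' p-distance with CpG stripping and pairwise deletion
#'
#' Proportion of differing sites between two aligned rows after (i)
#' removing every column that is the C or the G of a CpG dinucleotide in
#' either row (gap-skipping adjacency) — CpG sites hypermutate and distort
#' neutral divergence — and (ii) pairwise deletion of columns gapped or
#' ambiguous in either row.
#'
#' @param a,b Equal-length aligned rows.
#' @param strip_cpg Remove CpG-dinucleotide columns first.
#' @return The p-distance; `NA` (with a warning) if no columns remain.
#' @export
#' @examples
#' p_distance_cpg_stripped("ACGTT", "ATGTT")  # 0: the CpG columns drop out
p_distance_cpg_stripped <- function(a, b, strip_cpg = TRUE) {
  if (nchar(a) != nchar(b)) stop("p_distance: rows differ in length")
  keep <- if (strip_cpg) !.cpg_columns(c(a, b)) else NULL
  cmp <- .pairwise_site_classes(a, b, keep = keep)
  if (cmp$n_sites == 0L) {
    warning("p_distance: no comparable columns remain; distance undefined")
    return(NA_real_)
  }
  (cmp$n_ts + cmp$n_tv) / cmp$n_sites
}

# closed-form K2P from transition/transversion counts
k2p_from_counts <- function(n_ts, n_tv, n_sites) {
  P <- n_ts / n_sites
  Q <- n_tv / n_sites
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(Inf)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with `P` and `Q` the transition
#' and transversion proportions over pairwise-deleted columns. Saturated
#' pairs (logarithm argument <= 0) return `Inf` with a `"saturated"`
#' attribute.
#'
#' @param a,b Equal-length aligned rows.
#' @return The K2P distance (substitutions/site).
#' @export
#' @examples
#' a <- strrep("A", 100)
#' k2p_distance(a, a)  # 0
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("k2p_distance: rows differ in length")
  cmp <- .pairwise_site_classes(a, b)
  if (cmp$n_sites == 0L) {
    warning("k2p_distance: no comparable columns remain")
    return(NA_real_)
  }
  d <- k2p_from_counts(cmp$n_ts, cmp$n_tv, cmp$n_sites)
  if (is.infinite(d)) {
    attr(d, "saturated") <- TRUE
    warning("k2p_distance: saturated pair; distance undefined (Inf)")
  }
  d
}

#' Pairwise distance matrix over an alignment
#'
#' @param alignment An [as_alignment()].
#' @param model `"k2p"`, `"p"` (plain p-distance) or `"p_cpg"`
#'   (CpG-stripped p-distance).
#' @return A symmetric matrix of class `erv_dist` with zero diagonal;
#'   saturated pairs are `Inf`.
#' @export
distance_matrix <- function(alignment, model = c("k2p", "p", "p_cpg")) {
  model <- match.arg(model)
  rows <- unclass(alignment)
  n <- length(rows)
  f <- switch(model,
              k2p = function(a, b) suppressWarnings(k2p_distance(a, b)),
              p = function(a, b)
                suppressWarnings(p_distance_cpg_stripped(a, b,
                                                         strip_cpg = FALSE)),
              p_cpg = function(a, b)
                suppressWarnings(p_distance_cpg_stripped(a, b)))
  m <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- as.numeric(f(rows[[i]], rows[[j]]))
      m[i, j] <- m[j, i] <- d
    }
  }
  structure(m, class = c("erv_dist", "matrix"), model = model)
}

#' @method tidy erv_dist
#' @export
tidy.erv_dist <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(item1 = labs[idx[, 1L]], item2 = labs[idx[, 2L]],
                 distance = x[idx])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining; labels are canonicalised to alphabetical
#' order before joining so equal-scoring ties always break the same way,
#' making the output invariant to input row order. Negative branch lengths
#' are clamped to zero with a warning. Taxa involved in non-finite
#' (saturated) distances are dropped with a warning before joining.
#'
#' @param dm An `erv_dist` or plain symmetric matrix.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  m <- unclass(dm)
  if (!isSymmetric(unname(m))) stop("nj_tree: matrix is not symmetric")
  while (any(!is.finite(m))) {
    worst <- which.max(rowSums(!is.finite(m)))
    warning("nj_tree: dropping taxon with saturated distances: ",
            rownames(m)[worst])
    m <- m[-worst, -worst, drop = FALSE]
  }
  if (nrow(m) < 3L) stop("nj_tree: need >= 3 taxa with finite distances")
  ord <- order(rownames(m))
  m <- m[ord, ord]
  tr <- ape::nj(m)
  if (any(tr$edge.length < 0)) {
    warning("nj_tree: negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for the splits of an alignment's tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `tree_fun`, and reports for each internal edge of the
#' original tree the percentage of replicates containing the same split.
#'
#' @param alignment An [as_alignment()] (>= 4 rows).
#' @param tree_fun Function alignment -> `phylo`; defaults to NJ on K2P
#'   distances.
#' @param reps Number of replicates.
#' @param seed RNG seed; same seed, same supports.
#' @return A list: `tree` (reference tree with `node.label` set to support
#'   percentages) and `support` (numeric per internal node).
#' @export
bootstrap_support <- function(alignment,
                              tree_fun = function(a)
                                nj_tree(distance_matrix(a, "k2p")),
                              reps = 100L, seed = 1L) {
  rows <- unclass(alignment)
  if (length(rows) < 4L) stop("bootstrap_support: need >= 4 rows")
  m <- alignment_matrix(alignment)
  ref <- tree_fun(alignment)
  boots <- with_seed(seed, {
    lapply(seq_len(reps), function(i) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      res <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      # replicate trees routinely clamp tiny negative branches; only the
      # reference tree's warnings are surfaced
      suppressWarnings(tree_fun(as_alignment(res)))
    })
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / reps
  ref$node.label <- formatC(support, format = "f", digits = 0)
  list(tree = ref, support = support)
}

# -- dot-plots ----------------------------------------------------------

#' Windowed identity dot-plot of two sequences
#'
#' Ungapped identity between every pair of fixed-size windows of two
#' sequences; a cell is highlighted when its identity reaches the
#' threshold. With `both_strands = TRUE` a second pass against the reverse
#' complement of `b` records anti-diagonal (inverted) matches.
#'
#' @param a,b DNA strings (each at least one window long).
#' @param window Window length (nt).
#' @param step Step between window starts (nt).
#' @param threshold Identity fraction at or above which a cell is
#'   highlighted.
#' @param both_strands Also scan `a` against the reverse complement of `b`.
#' @return An object of class `erv_dotplot`; `tidy()` returns the window
#'   grid, `autoplot()` draws it.
#' @export
#' @examples
#' dp <- dotplot(strrep("ACGT", 50), strrep("ACGT", 50), window = 20,
#'               step = 10)
dotplot <- function(a, b, window = 100L, step = 25L, threshold = 0.5,
                    both_strands = FALSE) {
  if (nchar(a) < window || nchar(b) < window) {
    stop("dotplot: window exceeds a sequence length")
  }
  grid_one <- function(bseq, strand) {
    xa <- encode_dna(a); xb <- encode_dna(bseq)
    sa <- seq(0L, nchar(a) - window, by = step)
    sb <- seq(0L, nchar(bseq) - window, by = step)
    offs <- seq_len(window)
    Wa <- outer(sa, offs, `+`)            # windows x window, 1-based idx
    Wb <- outer(sb, offs, `+`)
    Ma <- matrix(xa[Wa], nrow = length(sa))
    Mb <- matrix(xb[Wb], nrow = length(sb))
    cnt <- matrix(0L, length(sa), length(sb))
    for (v in 0:3) {
      Av <- (Ma == v); Av[is.na(Av)] <- FALSE
      Bv <- (Mb == v); Bv[is.na(Bv)] <- FALSE
      cnt <- cnt + Av %*% t(Bv)
    }
    id <- cnt / window
    tibble::tibble(
      apos0 = rep(sa, times = length(sb)),
      bpos0 = if (strand == "+") rep(sb, each = length(sa))
              else nchar(bseq) - window - rep(sb, each = length(sa)),
      strand = strand,
      identity = as.vector(id),
      highlight = as.vector(id >= threshold)
    )
  }
  grid <- grid_one(b, "+")
  if (both_strands) grid <- dplyr::bind_rows(grid, grid_one(revcomp(b), "-"))
  structure(list(grid = grid, window = as.integer(window),
                 step = as.integer(step), threshold = threshold,
                 len_a = nchar(a), len_b = nchar(b)),
            class = "erv_dotplot")
}

#' @export
print.erv_dotplot <- function(x, ...) {
  cat("<erv_dotplot> ", x$len_a, " x ", x$len_b, " nt, window ", x$window,
      ", step ", x$step, "; ", sum(x$grid$highlight), "/", nrow(x$grid),
      " cells highlighted at >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' @method tidy erv_dotplot
#' @export
tidy.erv_dotplot <- function(x, ...) x$grid

#' @rdname dotplot
#' @param object An `erv_dotplot`.
#' @param ... Ignored.
#' @method autoplot erv_dotplot
#' @export
autoplot.erv_dotplot <- function(object, ...) {
  g <- dplyr::filter(object$grid, .data$highlight)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$apos0, y = .data$bpos0,
                                  colour = .data$strand)) +
    ggplot2::geom_point(shape = 15, size = 0.6) +
    ggplot2::scale_colour_manual(values = c("+" = "grey20", "-" = "red3"),
                                 guide = "none") +
    ggplot2::coord_fixed(xlim = c(0, object$len_a),
                         ylim = c(0, object$len_b)) +
    ggplot2::labs(
      x = "sequence a (nt)", y = "sequence b (nt)",
      title = sprintf("windows of %d nt at >= %.0f%% identity",
                      object$window, 100 * object$threshold)) +
    ggplot2::theme_minimal()
}
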