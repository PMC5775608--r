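#' Pipeline configuration
#'
#' Bundles every tunable threshold used across the pipeline stages into one
#' validated list, so that a whole run is reproducible from a single object.
#' Defaults mirror the published analysis protocol where it states a value
#' (500 nt flanks for orthology; 50% identity over a 100 nt window for
#' dot-plots; 100 bootstrap replicates) and otherwise hold explicit,
#' documented choices.
#'
#' @param flank_len Length (nt) of 5' and 3' flanking sequence attached to
#'   each locus and used to anchor cross-species ortholog mapping.
#' @param dotplot_window,dotplot_threshold Window size (nt) and identity
#'   fraction above which a dot-plot cell is highlighted.
#' @param bootstrap_reps Bootstrap replicates for tree support values.
#' @param seed_k k-mer size of the seed index used by the similarity search.
#' @param merge_gap Maximum gap (nt) between same-strand hits merged into one
#'   locus.
#' @param min_hit_len Minimum aligned length (nt) for a reported hit.
#' @param min_hit_identity Minimum identity fraction for a reported hit.
#'   Deliberately permissive (0.6) so that divergent, borderline elements
#'   (the "ERV-like" tier at roughly 63% identity) remain discoverable and
#'   can be triaged downstream.
#' @param subst_rate Neutral substitution rate, substitutions/site/MY, used
#'   by the simulator and by LTR-divergence dating.
#' @param kappa Transition/transversion bias of the two-class substitution
#'   model used by the simulator.
#' @param rng_seed Default seed for stochastic stages; `NULL` leaves the
#'   caller's RNG stream untouched.
#' @param chain_gap Maximum distance (nt) between consecutive seeds chained
#'   into one candidate hit.
#' @param band_width Diagonal tolerance (nt) when chaining seeds.
#' @param xdrop Score drop-off terminating ungapped hit extension
#'   (match +1 / mismatch -1).
#' @param min_chain_seeds Minimum seeds per chain; chains of one seed are
#'   k-mer noise in megabase targets.
#' @param flank_min_identity,flank_min_match Flank-anchoring acceptance: a
#'   flank is considered mapped when it aligns at >= `flank_min_identity`
#'   over >= `flank_min_match` nt of the `flank_len` flank.
#' @param empty_site_slack Residual length (nt) tolerated between juxtaposed
#'   flanks when calling a pre-insertion empty site (absorbs target-site
#'   duplications and micro-indels).
#' @param ltr_min_align,ltr_min_identity Minimum local alignment length and
#'   identity for calling a 5'/3' LTR pair within a locus.
#' @param seg_cov_frac Fraction of a model LTR segment (U3 or U5) that must
#'   be covered by alignment for the segment to count as present.
#' @param internal_min_cov Minimum coverage (nt) of the model internal region
#'   for a locus to be considered to carry internal (non-LTR) sequence.
#' @param polya_window,polya_min_a A poly-A tail is called when at least
#'   `polya_min_a` of the terminal `polya_window` nt are A.
#' @param tsd_min,tsd_max Length range of exact terminal duplications
#'   reported as target-site duplications.
#' @param dotplot_step Step (nt) between dot-plot windows.
#' @param n_policy `"reject"` refuses sequence letters outside A/C/G/T/N;
#'   `"coerce"` maps them to N.
#'
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(flank_len = 300)
#' cfg$flank_len
pipeline_config <- function(flank_len = 500L,
                            dotplot_window = 100L,
                            dotplot_threshold = 0.50,
                            bootstrap_reps = 100L,
                            seed_k = 12L,
                            merge_gap = 2000L,
                            min_hit_len = 100L,
                            min_hit_identity = 0.60,
                            subst_rate = 2.2e-3,
                            kappa = 2,
                            rng_seed = NULL,
                            chain_gap = 500L,
                            band_width = 32L,
                            xdrop = 20L,
                            min_chain_seeds = 2L,
                            flank_min_identity = 0.75,
                            flank_min_match = 300L,
                            empty_site_slack = 50L,
                            ltr_min_align = 200L,
                            ltr_min_identity = 0.70,
                            seg_cov_frac = 0.50,
                            internal_min_cov = 200L,
                            polya_window = 12L,
                            polya_min_a = 8L,
                            tsd_min = 3L,
                            tsd_max = 8L,
                            dotplot_step = 25L,
                            n_policy = c("reject", "coerce")) {
  n_policy <- match.arg(n_policy)
  cfg <- list(
    flank_len = as.integer(flank_len),
    dotplot_window = as.integer(dotplot_window),
    dotplot_threshold = as.numeric(dotplot_threshold),
    bootstrap_reps = as.integer(bootstrap_reps),
    seed_k = as.integer(seed_k),
    merge_gap = as.integer(merge_gap),
    min_hit_len = as.integer(min_hit_len),
    min_hit_identity = as.numeric(min_hit_identity),
    subst_rate = as.numeric(subst_rate),
    kappa = as.numeric(kappa),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
    chain_gap = as.integer(chain_gap),
    band_width = as.integer(band_width),
    xdrop = as.integer(xdrop),
    min_chain_seeds = as.integer(min_chain_seeds),
    flank_min_identity = as.numeric(flank_min_identity),
    flank_min_match = as.integer(flank_min_match),
    empty_site_slack = as.integer(empty_site_slack),
    ltr_min_align = as.integer(ltr_min_align),
    ltr_min_identity = as.numeric(ltr_min_identity),
    seg_cov_frac = as.numeric(seg_cov_frac),
    internal_min_cov = as.integer(internal_min_cov),
    polya_window = as.integer(polya_window),
    polya_min_a = as.integer(polya_min_a),
    tsd_min = as.integer(tsd_min),
    tsd_max = as.integer(tsd_max),
    dotplot_step = as.integer(dotplot_step),
    n_policy = n_policy
  )
  num <- cfg[!vapply(cfg, is.null, logical(1))]
  num <- num[vapply(num, is.numeric, logical(1))]
  bad <- names(num)[vapply(num, function(v) !is.finite(v) || v <= 0, logical(1))]
  bad <- setdiff(bad, "rng_seed")
  if (length(bad)) {
    stop("pipeline_config: fields must be positive and finite: ",
         paste(bad, collapse = ", "))
  }
  if (cfg$dotplot_threshold > 1) {
    stop("pipeline_config: dotplot_threshold must lie in (0, 1]")
  }
  if (cfg$tsd_min > cfg$tsd_max) stop("pipeline_config: tsd_min > tsd_max")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ","), character(1))
  cat(paste0("  ", format(names(flat)), " : ", flat, collapse = "\n"), "\n")
  invisible(x)
}

as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  do.call(pipeline_config, x)
}
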