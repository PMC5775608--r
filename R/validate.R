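#' Score a pipeline result against simulator ground truth
#'
#' Matches every inferred insertion cluster to a planted locus (by interval
#' overlap of member loci with the truth intervals) and measures, over the
#' matched set: per-cell ortholog-state agreement, formation-branch
#' accuracy, structural-class accuracy, and recovery of planted LTR-LTR
#' recombination events. Planted loci whose elements were deleted
#' everywhere are excluded from the denominator (nothing observable
#' remains). A truth `deleted_region` state is expected to be observed as
#' `empty`: the deletion restores a clean pre-insertion site.
#'
#' @param result An `erv_pipeline_result` run on `sim$genomes`.
#' @param sim The `erv_simulation` that produced the genomes.
#' @return A list of class `erv_truth_score`: `per_locus` (tibble with one
#'   row per observable planted locus) and scalar accuracies
#'   `state_accuracy`, `formation_accuracy`, `class_accuracy`,
#'   `recombination_recovered`, `recombination_calls`, `n_unmatched_truth`,
#'   `n_false_clusters`.
#' @export
score_against_truth <- function(result, sim) {
  truth <- sim$truth
  events <- sim$events
  mat <- result$matrix
  species <- sim$tree$phylo$tip.label

  # observable planted loci: present (full/solitary) somewhere
  obs <- truth |>
    dplyr::filter(.data$state %in% c("full", "solitary_ltr")) |>
    dplyr::distinct(.data$locus_id)

  # match clusters to truth loci via member interval overlap
  members <- mat$states |>
    dplyr::filter(.data$source == "discovered", !is.na(.data$start0))
  pres_truth <- truth |>
    dplyr::filter(!is.na(.data$start0)) |>
    dplyr::select("locus_id", "species_id", t_s = "start0", t_e = "end0")
  hits <- members |>
    dplyr::inner_join(pres_truth, by = "species_id",
                      relationship = "many-to-many") |>
    dplyr::filter(pmin(.data$end0, .data$t_e) -
                    pmax(.data$start0, .data$t_s) > 0) |>
    dplyr::count(.data$cluster_id, .data$locus_id) |>
    dplyr::arrange(dplyr::desc(.data$n))
  # greedy 1:1 assignment, best-supported first
  assign <- hits |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::slice_max(.data$n, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::slice_max(.data$n, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()

  expected_state <- function(st) {
    ifelse(st == "deleted_region", "empty", st)
  }

  per_locus <- purrr::map_dfr(obs$locus_id, function(lid) {
    cid <- assign$cluster_id[assign$locus_id == lid]
    ev <- events[events$locus_id == lid, ]
    tr_states <- truth[truth$locus_id == lid, ]
    tr_states <- stats::setNames(expected_state(tr_states$state),
                                 tr_states$species_id)[species]
    if (!length(cid)) {
      return(tibble::tibble(locus_id = lid, cluster_id = NA_character_,
                            matched = FALSE, states_equal = FALSE,
                            n_state_match = 0L,
                            formation_ok = FALSE, class_ok = FALSE))
    }
    inf <- mat$states[mat$states$cluster_id == cid, ]
    inf_states <- stats::setNames(inf$state, inf$species_id)[species]
    cl <- mat$clusters[mat$clusters$cluster_id == cid, ]
    tibble::tibble(
      locus_id = lid, cluster_id = cid, matched = TRUE,
      states_equal = identical(unname(inf_states), unname(tr_states)),
      n_state_match = sum(inf_states == tr_states),
      formation_ok = identical(cl$formation_branch, ev$branch_id),
      class_ok = identical(cl$cluster_class, ev$mechanism)
    )
  })

  # recombination recovery: planted (locus, branch) vs called (cluster,
  # branch)
  planted_rec <- events[!is.na(events$recomb_branch), ]
  called <- result$recombination
  rec_ok <- vapply(seq_len(nrow(planted_rec)), function(i) {
    cid <- assign$cluster_id[assign$locus_id == planted_rec$locus_id[i]]
    length(cid) == 1L &&
      any(called$cluster_id == cid &
            called$branch_id == planted_rec$recomb_branch[i])
  }, logical(1))

  structure(list(
    per_locus = per_locus,
    state_accuracy = mean(per_locus$n_state_match) / length(species),
    all_states_equal = all(per_locus$states_equal),
    formation_accuracy = mean(per_locus$formation_ok),
    class_accuracy = mean(per_locus$class_ok),
    recombination_recovered = sum(rec_ok),
    recombination_planted = nrow(planted_rec),
    recombination_calls = nrow(called),
    n_unmatched_truth = sum(!per_locus$matched),
    n_false_clusters = nrow(mat$clusters) - sum(per_locus$matched)
  ), class = "erv_truth_score")
}

#' @export
print.erv_truth_score <- function(x, ...) {
  cat("<erv_truth_score>\n")
  cat("  state accuracy:      ", round(x$state_accuracy, 4), "\n")
  cat("  formation accuracy:  ", round(x$formation_accuracy, 4), "\n")
  cat("  class accuracy:      ", round(x$class_accuracy, 4), "\n")
  cat("  recombinations:      ", x$recombination_recovered, "/",
      x$recombination_planted, " recovered (", x$recombination_calls,
      " called)\n", sep = "")
  cat("  unmatched truth loci:", x$n_unmatched_truth,
      "; false clusters:", x$n_false_clusters, "\n")
  invisible(x)
}
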