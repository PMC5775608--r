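# End-to-end driver: discovery -> classification -> orthology -> Dollo
# dating -> recombination inference -> report tables, with optional
# on-disk output bundle mirroring the shapes of the published
# supplementary tables.

#' Run the full ERV colonization analysis
#'
#' Discovers loci in every genome with the model query, classifies them
#' structurally, builds the cross-species ortholog matrix, assigns
#' formation branches (Dollo), infers LTR-LTR recombination events, and
#' assembles report tables. Optionally builds per-species proviral
#' consensus sequences and NJ trees with bootstrap support for
#' well-populated clusters, and writes the whole bundle to `out_dir`.
#'
#' @param genomes Genome tibble (`species_id`, `contig_id`, `seq`), one
#'   contig per species.
#' @param tree A [species_tree()] covering the genomes' species.
#' @param model An [erv_model()] (the search query and annotation master).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the on-disk bundle.
#' @param seed Seed for the stochastic stages (bootstrap).
#' @param comparative Also build consensus sequences and cluster trees
#'   (needs `mafft`; skipped when `FALSE`).
#' @param include_timestamp Record wall-clock time in the manifest (off by
#'   default so same-seed runs are byte-identical).
#' @return An object of class `erv_pipeline_result`.
#' @export
run_erv_pipeline <- function(genomes, tree, model,
                             config = pipeline_config(), out_dir = NULL,
                             seed = 1L, comparative = TRUE,
                             include_timestamp = FALSE) {
  species <- tree$phylo$tip.label
  if (!all(species %in% genomes$species_id)) {
    stop("run_erv_pipeline: genomes missing for: ",
         paste(setdiff(species, genomes$species_id), collapse = ", "))
  }

  indexes <- lapply(stats::setNames(species, species), function(sp) {
    g <- genomes[genomes$species_id == sp, ]
    build_seed_index(g$seq[[1]], k = config$seed_k,
                     contig_id = g$contig_id[[1]], species_id = sp)
  })

  loci <- dplyr::bind_rows(lapply(species, function(sp) {
    g <- genomes[genomes$species_id == sp, ]
    classify_loci(discover_loci(g, model, config, index = indexes[[sp]]),
                  model, config)
  }))

  mat <- build_ortholog_matrix(loci, genomes, tree, model, config,
                               indexes = indexes)
  mat <- assign_formation_branches(mat)
  recomb <- infer_recombination_events(mat)
  report <- formation_report(mat)
  summary <- summarize_counts(mat)

  # per-species ortholog counts (Table-1 shape) and state breakdown
  table1 <- mat$states |>
    dplyr::filter(.data$state %in% c("full", "solitary_ltr")) |>
    dplyr::count(.data$species_id, name = "n_orthologous_loci")
  table2 <- mat$states |>
    dplyr::count(.data$species_id, .data$state) |>
    tidyr::pivot_wider(names_from = "state", values_from = "n",
                       values_fill = 0L)
  species_specific <- mat$clusters |>
    dplyr::filter(.data$cluster_id %in% summary$species_specific) |>
    dplyr::mutate(species_id = vapply(.data$member_species, `[`, "", 1L)) |>
    dplyr::select("cluster_id", "species_id", "cluster_class",
                  "formation_branch")

  consensus <- list(); cluster_trees <- list()
  if (comparative) {
    # species-specific proviral consensus (the published procedure:
    # complete proviruses per species -> MSA -> majority-rule consensus)
    for (sp in species) {
      pv <- loci[loci$species_id == sp & loci$structure == "provirus", ]
      if (nrow(pv) >= 3L) {
        seqs <- ifelse(pv$strand == "-", vapply(pv$sequence, revcomp, ""),
                       pv$sequence)
        names(seqs) <- pv$locus_id
        consensus[[sp]] <- majority_consensus(progressive_msa(seqs))
      }
    }
    # NJ + bootstrap over clusters with a full element in >= 4 species
    good <- mat$clusters$cluster_id[vapply(
      mat$clusters$cluster_id, function(cid)
        sum(mat$states$state[mat$states$cluster_id == cid] == "full") >= 4L,
      logical(1))]
    for (cid in utils::head(sort(good), 3L)) {
      st <- mat$states[mat$states$cluster_id == cid &
                         mat$states$state == "full", ]
      seqs <- vapply(seq_len(nrow(st)), function(i) {
        ix <- indexes[[st$species_id[i]]]
        slice0(ix$seq, st$start0[i], st$end0[i])
      }, character(1))
      names(seqs) <- st$species_id
      aln <- progressive_msa(seqs)
      bs <- bootstrap_support(aln, reps = config$bootstrap_reps,
                              seed = seed)
      cluster_trees[[cid]] <- bs$tree
    }
  }

  res <- structure(list(
    loci = loci, matrix = mat, recombination = recomb,
    formation_report = report, summary = summary,
    table1 = table1, table2 = table2,
    species_specific = species_specific,
    consensus = consensus, cluster_trees = cluster_trees,
    tree = tree, model = model, config = config, seed = seed
  ), class = "erv_pipeline_result")

  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, out_dir,
                           include_timestamp = include_timestamp)
  }
  res
}

#' @export
print.erv_pipeline_result <- function(x, ...) {
  cat("<erv_pipeline_result> ", nrow(x$loci), " loci in ",
      length(unique(x$loci$species_id)), " species -> ",
      nrow(x$matrix$clusters), " insertion clusters\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @method glance erv_pipeline_result
#' @export
glance.erv_pipeline_result <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_loci = nrow(x$loci), n_clusters = s$n_clusters,
    shared_strict = s$shared_strict, shared_lca = s$shared_lca,
    n_species_specific = s$n_species_specific,
    n_recombination_calls = nrow(x$recombination)
  )
}

#' Headline statistics of an ortholog matrix
#'
#' Computes the summary counts reported for this kind of analysis: the
#' strict-intersection shared count (present in every species), the
#' LCA-rule shared count (formed on the stem branch, so absences in
#' intermediate species are interpreted as losses), per-species ortholog
#' totals, species-specific totals, and the provirus : processed-pseudogene
#' mix per formation branch.
#'
#' @param matrix An `erv_ortholog_matrix` (after
#'   [assign_formation_branches()]; the LCA-rule count needs formation
#'   branches).
#' @return A list of class `erv_summary`.
#' @export
summarize_counts <- function(matrix) {
  st <- matrix$states
  cl <- matrix$clusters
  n_species <- matrix$tree$n_tip
  present <- st |>
    dplyr::filter(.data$state %in% c("full", "solitary_ltr")) |>
    dplyr::count(.data$cluster_id, name = "n_present")
  shared_strict <- sum(present$n_present == n_species)
  shared_lca <- if ("formation_branch" %in% names(cl)) {
    sum(cl$formation_branch == "stem", na.rm = TRUE)
  } else NA_integer_
  per_species <- st |>
    dplyr::filter(.data$state %in% c("full", "solitary_ltr")) |>
    dplyr::count(.data$species_id, name = "n_orthologous_loci")
  spec1 <- present$cluster_id[present$n_present == 1L]
  spec_specific <- cl |> dplyr::filter(.data$cluster_id %in% spec1)
  ratio <- if ("formation_branch" %in% names(cl)) {
    cl |>
      dplyr::filter(!is.na(.data$formation_branch),
                    .data$cluster_class %in% c("provirus",
                                               "processed_pseudogene")) |>
      dplyr::count(.data$formation_branch, .data$cluster_class) |>
      tidyr::pivot_wider(names_from = "cluster_class", values_from = "n",
                         values_fill = 0L)
  } else NULL
  structure(list(
    n_clusters = nrow(cl), shared_strict = shared_strict,
    shared_lca = shared_lca, per_species = per_species,
    n_species_specific = nrow(spec_specific),
    species_specific = spec_specific$cluster_id,
    mechanism_by_branch = ratio
  ), class = "erv_summary")
}

#' @export
print.erv_summary <- function(x, ...) {
  cat("insertion clusters:           ", x$n_clusters, "\n")
  cat("shared by all species (strict):", x$shared_strict, "\n")
  cat("shared by stem formation (LCA):", x$shared_lca, "\n")
  cat("species-specific clusters:    ", x$n_species_specific, "\n")
  invisible(x)
}

#' Write the pipeline output bundle
#'
#' Writes the report tables (TSV with a commented legend where state codes
#' are used), loci BED, consensus FASTA, cluster trees (Newick with
#' bootstrap supports as node labels) and a JSON run manifest (config,
#' seed, output checksums).
#'
#' @param res An `erv_pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @param include_timestamp Record wall-clock time in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir,
                                   include_timestamp = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  con <- file(p("matrix.tsv"), "w")
  writeLines(c("# ortholog state matrix: one row per insertion cluster",
               "# F = full element, S = solitary LTR, E = empty site,",
               "# U = unresolved"), con)
  close(con)
  readr::write_tsv(res$matrix$wide, p("matrix.tsv"), append = TRUE,
                   col_names = TRUE)
  readr::write_tsv(res$table1, p("table1.tsv"))
  readr::write_tsv(res$table2, p("table2.tsv"))
  readr::write_tsv(res$formation_report, p("formation_report.tsv"))
  readr::write_tsv(
    dplyr::mutate(res$recombination,
                  species = vapply(.data$species, paste, "",
                                   collapse = ",")),
    p("recombination_events.tsv"))
  readr::write_tsv(res$species_specific, p("species_specific.tsv"))
  readr::write_tsv(
    dplyr::select(res$loci, -"sequence", -"flank5", -"flank3"),
    p("loci.tsv"))
  write_bed(res$loci, p("loci.bed"))
  for (sp in names(res$consensus)) {
    writeLines(c(paste0(">", sp, "_PVconsensus"), res$consensus[[sp]]$seq),
               p(paste0("consensus_", sp, ".fasta")))
  }
  if (length(res$cluster_trees)) {
    ape::write.tree(do.call(c, unname(res$cluster_trees)),
                    p("cluster_trees.nwk"))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ervography")),
    seed = res$seed,
    config = res$config[!vapply(res$config, is.null, logical(1))],
    outputs = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$outputs) <- files
  if (include_timestamp) manifest$timestamp <- format(Sys.time())
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Plot per-branch formation counts
#'
#' Stacked bars of formation counts per branch and structural class, in
#' root-to-tip branch order.
#'
#' @param report A [formation_report()] tibble.
#' @return A ggplot object.
#' @export
plot_formation_report <- function(report) {
  long <- report |>
    dplyr::select(-"total") |>
    tidyr::pivot_longer(-"formation_branch", names_to = "class",
                        values_to = "n") |>
    dplyr::filter(.data$n > 0)
  long$formation_branch <- factor(long$formation_branch,
                                  levels = report$formation_branch)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$formation_branch,
                                     y = .data$n, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "formation branch", y = "insertion events",
                  fill = "class") +
    ggplot2::theme_minimal()
}
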