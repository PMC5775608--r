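# Flank-anchored cross-species orthology. The identity of an insertion is
# established by its flanking genomic sequence: when both 500-nt flanks of
# a locus map concordantly (same contig, same strand, correct order) into
# another genome, the interval between them is the orthologous site, and
# its content decides the state — the full element, a solitary LTR, an
# empty pre-insertion site, or unresolved.

#' Map one locus into another genome by its flanks
#'
#' Both flanks are searched in the target; a concordant pair defines the
#' candidate orthologous interval. The interval is then searched with the
#' ERV model query: substantial internal-region coverage calls `full`, an
#' LTR-scale-only match calls `solitary_ltr`, a residual interval no longer
#' than `config$empty_site_slack` (plus one target-site duplication) calls
#' `empty`. Unmapped or discordant flanks, or an interval overlapping an
#' N-run, return `unresolved` — never a guess.
#'
#' @param locus One-row loci tibble (needs `flank5`, `flank3`).
#' @param target An `erv_seed_index` of the target contig (or a DNA
#'   string / one-row genome tibble).
#' @param model The [erv_model()] used for discovery.
#' @param config A [pipeline_config()].
#' @return A one-row tibble: `state` (full/solitary_ltr/empty/unresolved),
#'   `t_start0`, `t_end0` (candidate interval), `t_strand`,
#'   `flank5_identity`, `flank3_identity`, `note`.
#' @export
map_locus <- function(locus, target, model, config = pipeline_config()) {
  indexes <- if (inherits(target, "erv_seed_index")) list(target)
             else if (is.list(target) &&
                      all(vapply(target, inherits, logical(1),
                                 "erv_seed_index"))) target
             else list(build_seed_index(target, k = config$seed_k))
  unres <- function(note) {
    tibble::tibble(state = "unresolved", t_start0 = NA_integer_,
                   t_end0 = NA_integer_, t_strand = NA_character_,
                   flank5_identity = NA_real_, flank3_identity = NA_real_,
                   note = note)
  }
  if (nchar(locus$flank5) < config$flank_min_match ||
      nchar(locus$flank3) < config$flank_min_match) {
    return(unres("flank_truncated"))
  }
  fcfg <- config
  fcfg$min_hit_len <- config$flank_min_match
  fcfg$min_hit_identity <- config$flank_min_identity
  best_hit <- function(fl) {
    h <- dplyr::bind_rows(lapply(indexes, function(ix)
      search_genome(fl, ix, fcfg)))
    if (!nrow(h)) return(NULL)
    h[order(-(h$identity * h$aligned_len)), ][1L, ]
  }
  # trim the element-facing edge of each flank: a discovery span that
  # undershot the element boundary leaves element k-mers in the flank,
  # which would seed spurious matches at every other locus
  trim <- config$seed_k + 4L
  f5 <- substr(locus$flank5, 1L, nchar(locus$flank5) - trim)
  f3 <- substring(locus$flank3, trim + 1L)
  h5 <- best_hit(f5)
  h3 <- best_hit(f3)
  if (is.null(h5) || is.null(h3)) return(unres("flank_unmapped"))
  if (h5$contig_id != h3$contig_id) return(unres("flank_split_contigs"))
  if (h5$strand != h3$strand) return(unres("flank_discordant_strand"))
  index <- indexes[[match(h5$contig_id,
                          vapply(indexes, `[[`, "", "contig_id"))]]

  # order along the plus strand depends on relative orientation
  if (h5$strand == "+") { left <- h5; right <- h3 }
  else { left <- h3; right <- h5 }
  gap_s <- left$tend0
  gap_e <- right$tstart0
  if (gap_e < gap_s - (config$tsd_max + config$empty_site_slack)) {
    return(unres("flank_discordant_order"))
  }
  gap_s <- min(gap_s, gap_e)
  res <- tibble::tibble(state = "unresolved",
                        t_start0 = as.integer(gap_s),
                        t_end0 = as.integer(gap_e),
                        t_strand = h5$strand,
                        flank5_identity = h5$identity,
                        flank3_identity = h3$identity,
                        note = NA_character_)
  gap_len <- gap_e - gap_s
  if (gap_len <= config$empty_site_slack + config$tsd_max) {
    res$state <- "empty"
    return(res)
  }
  gap_seq <- slice0(index$seq, gap_s, gap_e)
  if (grepl("NNNNNNNNNN", gap_seq, fixed = TRUE)) {
    res$note <- "assembly_gap"
    return(res)                                   # unresolved
  }
  hits <- search_genome(model$query_seq, gap_seq, config)
  if (!nrow(hits)) {
    res$note <- "occupied_by_unrelated_sequence"
    return(res)                                   # unresolved
  }
  cov <- function(s0, e0) {
    iv <- dplyr::filter(hits, pmin(.data$qend0, e0) -
                          pmax(.data$qstart0, s0) > 0)
    if (!nrow(iv)) return(0L)
    sum(pmin(iv$qend0, e0) - pmax(iv$qstart0, s0))
  }
  qlen <- nchar(model$query_seq)
  internal_cov <- cov(model$ltr_len, qlen - model$ltr_len)
  ltr_cov <- cov(0L, model$ltr_len) + cov(qlen - model$ltr_len, qlen)
  if (internal_cov >= config$internal_min_cov) {
    res$state <- "full"
  } else if (ltr_cov >= config$internal_min_cov) {
    res$state <- "solitary_ltr"
  } else {
    res$note <- "weak_erv_match"
  }
  res
}

#' Build the loci x species ortholog matrix
#'
#' Anchors every discovered locus at its orthologous position in a
#' reference genome (the first species of the tree by default — mirroring
#' the published protocol, which mapped every non-human locus back to the
#' human assembly), clusters loci whose reference anchors coincide into
#' insertion events, and fills the matrix with per-species states.
#' Reciprocity is enforced against the reference: a non-reference locus
#' joins a reference locus's cluster only if each maps into an interval
#' overlapping the other, and violations are flagged. Loci that cannot be
#' anchored in the reference are cross-mapped directly. Species carrying a
#' clustered locus contribute their structural classification; species
#' without one receive the state mapped from a cluster member (majority
#' vote, ties resolved full > solitary_ltr > empty > unresolved).
#'
#' @param loci Classified loci of all species ([classify_loci()] output,
#'   bound rows).
#' @param genomes Genome tibble covering every species in the tree.
#' @param tree A [species_tree()].
#' @param model An [erv_model()].
#' @param config A [pipeline_config()].
#' @param indexes Optional named list of pre-built `erv_seed_index`es (one
#'   per species, single-contig genomes).
#' @param reference_species Species used as the anchoring reference;
#'   defaults to the first tip of the tree.
#' @return An object of class `erv_ortholog_matrix`: `states` (long tibble
#'   cluster_id x species_id with state and interval), `clusters` (one row
#'   per cluster: members, class, conflict flag), `wide` (Table-S1-shaped
#'   state matrix with codes F/S/E/U), and the tree.
#' @export
build_ortholog_matrix <- function(loci, genomes, tree, model,
                                  config = pipeline_config(),
                                  indexes = NULL,
                                  reference_species = NULL) {
  species <- tree$phylo$tip.label
  if (!all(unique(loci$species_id) %in% species)) {
    stop("build_ortholog_matrix: loci from species absent in the tree")
  }
  if (is.null(indexes)) {
    indexes <- lapply(stats::setNames(species, species), function(sp) {
      g <- genomes[genomes$species_id == sp, ]
      stopifnot(nrow(g) == 1L)
      build_seed_index(g$seq, k = config$seed_k, contig_id = g$contig_id,
                       species_id = sp)
    })
  }

  ref <- reference_species %||% species[1L]
  stopifnot(ref %in% species)
  n <- nrow(loci)

  map_one <- function(i, sp) {
    m <- if (identical(loci$species_id[i], sp)) {
      tibble::tibble(state = NA_character_, t_start0 = loci$start0[i],
                     t_end0 = loci$end0[i], t_strand = loci$strand[i],
                     flank5_identity = 1, flank3_identity = 1,
                     note = "self")
    } else {
      map_locus(loci[i, ], indexes[[sp]], model, config)
    }
    dplyr::mutate(m, locus_id = loci$locus_id[i],
                  source_species = loci$species_id[i],
                  target_species = sp)
  }

  # anchor every locus in the reference genome; reference loci are mapped
  # into every species (their maps later fill non-member matrix cells)
  maps <- list()
  for (i in seq_len(n)) {
    if (loci$species_id[i] == ref) {
      for (sp in species) maps[[length(maps) + 1L]] <- map_one(i, sp)
    } else {
      maps[[length(maps) + 1L]] <- map_one(i, ref)
    }
  }
  maps <- dplyr::bind_rows(maps)

  # clustering: loci whose (padded) reference anchors overlap are the same
  # insertion; the padding absorbs the near-zero span of empty-site anchors
  pad <- 50L
  anch <- maps |>
    dplyr::filter(.data$target_species == ref, !is.na(.data$t_start0)) |>
    dplyr::transmute(locus_id = .data$locus_id,
                     a_s = .data$t_start0 - pad, a_e = .data$t_end0 + pad)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (nrow(anch) > 1L) {
    o <- order(anch$a_s)
    idx <- match(anch$locus_id[o], loci$locus_id)
    run_end <- anch$a_e[o][1L]
    for (e in seq_along(o)[-1L]) {
      if (anch$a_s[o][e] < run_end) union_(idx[e - 1L], idx[e])
      run_end <- max(run_end, anch$a_e[o][e])
    }
  }

  # loci without a reference anchor: cross-map directly into the other
  # species and link by overlap with discovered loci there
  unanch <- setdiff(loci$locus_id, anch$locus_id)
  if (length(unanch)) {
    extra <- list()
    for (lid in unanch) {
      i <- match(lid, loci$locus_id)
      for (sp in setdiff(species, c(ref, loci$species_id[i]))) {
        extra[[length(extra) + 1L]] <- map_one(i, sp)
      }
    }
    extra <- dplyr::bind_rows(extra)
    maps <- dplyr::bind_rows(maps, extra)
    hits_ov <- extra |>
      dplyr::filter(!is.na(.data$t_start0)) |>
      dplyr::inner_join(
        dplyr::select(loci, other_id = "locus_id",
                      target_species = "species_id",
                      o_start0 = "start0", o_end0 = "end0"),
        by = "target_species", relationship = "many-to-many") |>
      dplyr::filter(pmin(.data$t_end0, .data$o_end0) -
                      pmax(.data$t_start0, .data$o_start0) > 0)
    ii <- match(hits_ov$locus_id, loci$locus_id)
    jj <- match(hits_ov$other_id, loci$locus_id)
    for (e in seq_along(ii)) union_(ii[e], jj[e])
  }
  roots <- vapply(seq_len(n), find, integer(1))

  # reciprocity audit against the reference: for every clustered pair of a
  # reference locus r and a non-reference locus l, r's map into l's
  # species must overlap l
  nonrec_ids <- character(0)
  rmaps <- maps[maps$source_species == ref &
                  maps$target_species != ref, ]
  for (i in which(loci$species_id != ref)) {
    r_mates <- which(roots == roots[i] & loci$species_id == ref)
    for (r in r_mates) {
      rm <- rmaps[rmaps$locus_id == loci$locus_id[r] &
                    rmaps$target_species == loci$species_id[i], ]
      ok <- nrow(rm) == 1L && !is.na(rm$t_start0) &&
        min(rm$t_end0, loci$end0[i]) - max(rm$t_start0, loci$start0[i]) > 0
      if (!ok) nonrec_ids <- c(nonrec_ids, loci$locus_id[i])
    }
  }
  if (length(nonrec_ids)) {
    warning("build_ortholog_matrix: ", length(nonrec_ids),
            " non-reciprocal flank mapping edge(s); merged and flagged")
  }

  # deterministic cluster ids by (first species in tree order, coordinate)
  sp_rank <- match(loci$species_id, species)
  key <- stats::aggregate(
    data.frame(rank = sp_rank, start = loci$start0),
    by = list(root = roots), FUN = min)
  key <- key[order(key$rank, key$start), ]
  cl_id <- stats::setNames(sprintf("C%04d", seq_len(nrow(key))), key$root)
  cluster_of <- unname(cl_id[as.character(roots)])

  member_tbl <- tibble::tibble(cluster_id = cluster_of,
                               locus_id = loci$locus_id,
                               species_id = loci$species_id,
                               structure = loci$structure,
                               start0 = loci$start0, end0 = loci$end0)
  # flag clusters that merged non-reciprocal or conflicting memberships
  dup_sp <- member_tbl |>
    dplyr::count(.data$cluster_id, .data$species_id) |>
    dplyr::filter(.data$n > 1L)

  clusters <- member_tbl |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      member_species = list(sort(unique(.data$species_id))),
      member_loci = list(.data$locus_id),
      cluster_class = {
        full_cl <- setdiff(.data$structure, "solitary_ltr")
        if (!length(full_cl)) "solitary_only"
        else names(sort(table(full_cl), decreasing = TRUE))[1L]
      },
      conflict = .data$cluster_id[1L] %in% dup_sp$cluster_id ||
        any(.data$locus_id %in% nonrec_ids),
      .groups = "drop"
    )
  if (any(clusters$conflict)) {
    warning("build_ortholog_matrix: ", sum(clusters$conflict),
            " cluster(s) carry conflicting memberships; flagged")
  }

  # clusters without a reference member still need their remaining matrix
  # cells filled: map one representative member into every species not yet
  # covered
  maps$cluster_id <- cluster_of[match(maps$locus_id, loci$locus_id)]
  extra2 <- list()
  for (cid in unique(cluster_of)) {
    mem_idx <- which(cluster_of == cid)
    if (any(loci$species_id[mem_idx] == ref)) next
    repi <- mem_idx[order(loci$locus_id[mem_idx])][1L]
    have <- unique(c(loci$species_id[mem_idx],
                     maps$target_species[maps$locus_id ==
                                           loci$locus_id[repi]]))
    for (sp in setdiff(species, have)) {
      extra2[[length(extra2) + 1L]] <- map_one(repi, sp)
    }
  }
  if (length(extra2)) {
    extra2 <- dplyr::bind_rows(extra2)
    extra2$cluster_id <- cluster_of[match(extra2$locus_id, loci$locus_id)]
    maps <- dplyr::bind_rows(maps, extra2)
  }
  states <- purrr::map_dfr(clusters$cluster_id, function(cid) {
    mem <- member_tbl[member_tbl$cluster_id == cid, ]
    purrr::map_dfr(species, function(sp) {
      mrow <- mem[mem$species_id == sp, ]
      if (nrow(mrow)) {
        st <- if (any(mrow$structure == "solitary_ltr")) "solitary_ltr"
              else "full"
        tibble::tibble(cluster_id = cid, species_id = sp, state = st,
                       start0 = mrow$start0[1L], end0 = mrow$end0[1L],
                       source = "discovered")
      } else {
        mm <- maps[maps$cluster_id == cid & maps$target_species == sp &
                     maps$target_species != maps$source_species, ]
        st <- if (nrow(mm)) {
          tab <- table(mm$state)
          best <- names(tab)[tab == max(tab)]
          prio <- c("full", "solitary_ltr", "empty", "unresolved")
          prio[prio %in% best][1L]
        } else "unresolved"
        pick <- if (nrow(mm)) mm[mm$state == st, ][1L, ] else NULL
        tibble::tibble(cluster_id = cid, species_id = sp, state = st,
                       start0 = pick$t_start0 %||% NA_integer_,
                       end0 = pick$t_end0 %||% NA_integer_,
                       source = "mapped")
      }
    })
  })

  wide <- states |>
    dplyr::mutate(code = c(full = "F", solitary_ltr = "S", empty = "E",
                           unresolved = "U")[.data$state]) |>
    dplyr::select("cluster_id", "species_id", "code") |>
    tidyr::pivot_wider(names_from = "species_id", values_from = "code")

  structure(list(states = states, clusters = clusters, wide = wide,
                 maps = maps, tree = tree),
            class = "erv_ortholog_matrix")
}

#' @export
print.erv_ortholog_matrix <- function(x, ...) {
  cat("<erv_ortholog_matrix> ", nrow(x$clusters), " insertion clusters x ",
      x$tree$n_tip, " species\n", sep = "")
  print(utils::head(x$wide, 10))
  invisible(x)
}

#' Assign each insertion to its formation branch (Dollo rule)
#'
#' An insertion is gained once: its formation branch is the stem branch of
#' the last common ancestor of every species where it is present (a
#' solitary LTR counts as presence — the element was there, only its
#' internal portion was lost). Descendant species with an empty state are
#' recorded as losses; unresolved species are no-calls. All-unresolved
#' rows receive no assignment and are flagged.
#'
#' @param matrix An `erv_ortholog_matrix`.
#' @return The matrix with `clusters` gaining `formation_branch`,
#'   `n_losses`, `loss_species`, `n_nocall`.
#' @export
assign_formation_branches <- function(matrix) {
  tree <- matrix$tree
  info <- purrr::map_dfr(matrix$clusters$cluster_id, function(cid) {
    st <- matrix$states[matrix$states$cluster_id == cid, ]
    pres <- st$species_id[st$state %in% c("full", "solitary_ltr")]
    if (!length(pres)) {
      return(tibble::tibble(cluster_id = cid,
                            formation_branch = NA_character_,
                            n_losses = NA_integer_, loss_species = list(
                              character(0)),
                            n_nocall = sum(st$state == "unresolved")))
    }
    br <- stem_branch_of(tree, pres)
    below <- tips_of_branch(tree, br)
    losses <- st$species_id[st$species_id %in% below & st$state == "empty"]
    tibble::tibble(cluster_id = cid, formation_branch = br,
                   n_losses = length(losses), loss_species = list(losses),
                   n_nocall = sum(st$species_id %in% below &
                                    st$state == "unresolved"))
  })
  matrix$clusters <- dplyr::left_join(matrix$clusters, info,
                                      by = "cluster_id")
  matrix
}

#' Infer LTR-LTR recombination events from mixed rows
#'
#' Within a cluster mixing full and solitary-LTR states, each maximal clade
#' whose present members are all solitary LTRs (while a species outside it
#' retains the full element) is explained by one LTR-LTR homologous
#' recombination on that clade's stem branch. Calls are only made for
#' clusters of proviral origin: processed pseudogenes lack the LTR homology
#' such recombination requires, and calls on pseudogene clusters are
#' suppressed with a warning.
#'
#' @param matrix An `erv_ortholog_matrix` (after classification).
#' @return A tibble of calls: `cluster_id`, `branch_id`, `species` (tips
#'   below the recombination branch).
#' @export
infer_recombination_events <- function(matrix) {
  tree <- matrix$tree
  out <- list()
  for (cid in matrix$clusters$cluster_id) {
    st <- matrix$states[matrix$states$cluster_id == cid, ]
    sol <- st$species_id[st$state == "solitary_ltr"]
    full <- st$species_id[st$state == "full"]
    if (!length(sol) || !length(full)) next
    cls <- matrix$clusters$cluster_class[
      matrix$clusters$cluster_id == cid]
    if (identical(cls, "processed_pseudogene")) {
      warning("infer_recombination_events: solitary LTRs in ",
              "pseudogene-classified cluster ", cid, "; call suppressed")
      next
    }
    # candidate nodes: clades whose present members are all solitary
    br <- tree$branches
    all_sol <- vapply(br$tips, function(tp) {
      p <- intersect(tp, c(sol, full))
      length(p) > 0 && all(p %in% sol)
    }, logical(1))
    cand <- br$branch_id[all_sol & br$branch_id != "stem"]
    # keep maximal candidates only
    keep <- vapply(cand, function(b) {
      tp <- tips_of_branch(tree, b)
      !any(vapply(cand, function(o) {
        op <- tips_of_branch(tree, o)
        length(op) > length(tp) && all(tp %in% op)
      }, logical(1)))
    }, logical(1))
    for (b in cand[keep]) {
      out[[length(out) + 1L]] <- tibble::tibble(
        cluster_id = cid, branch_id = b,
        species = list(intersect(tips_of_branch(tree, b), sol)))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(cluster_id = character(), branch_id = character(),
                          species = list()))
  }
  dplyr::bind_rows(out)
}

#' Per-branch formation counts by structural class
#'
#' Cross-tabulates formation branches against cluster classes (provirus,
#' processed pseudogene, undefined, solitary-only). Every cluster with an
#' assigned branch appears in exactly one cell.
#'
#' @param matrix An `erv_ortholog_matrix` after
#'   [assign_formation_branches()].
#' @return A tibble, one row per branch of the tree (zero-filled), columns
#'   per class plus `total`.
#' @export
formation_report <- function(matrix) {
  classes <- c("provirus", "processed_pseudogene", "undefined",
               "solitary_only", "unclassified")
  cl <- matrix$clusters |>
    dplyr::filter(!is.na(.data$formation_branch)) |>
    dplyr::count(.data$formation_branch, .data$cluster_class)
  base <- tidyr::expand_grid(formation_branch = preorder_branches(matrix$tree),
                             cluster_class = classes)
  base |>
    dplyr::left_join(cl, by = c("formation_branch", "cluster_class")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "cluster_class", values_from = "n") |>
    dplyr::mutate(total = rowSums(dplyr::across(dplyr::all_of(classes))))
}
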