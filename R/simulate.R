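#' Apply neutral substitutions to a sequence
#'
#' Two-class (transition-biased) substitution process: each site receives a
#' Poisson number of substitution events with mean `expected_subs_per_site`;
#' each event is a transition with probability `kappa / (kappa + 2)` and
#' otherwise one of the two transversions, applied sequentially so
#' multiple-hit and back-substitution effects emerge naturally. N sites are
#' left untouched; length is preserved.
#'
#' @param seq DNA string.
#' @param expected_subs_per_site Expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate bias (`Inf` forbids
#'   transversions).
#' @return The mutated DNA string.
#' @export
#' @examples
#' set.seed(1)
#' mutate_sequence("ACGTACGTAC", 0.5)
mutate_sequence <- function(seq, expected_subs_per_site, kappa = 2) {
  if (is.na(expected_subs_per_site) || expected_subs_per_site < 0) {
    stop("mutate_sequence: expected_subs_per_site must be >= 0")
  }
  if (expected_subs_per_site == 0) return(seq)
  x <- encode_dna(seq)
  n <- length(x)
  hits <- stats::rpois(n, expected_subs_per_site)
  hits[is.na(x)] <- 0L
  p_ts <- if (is.infinite(kappa)) 1 else kappa / (kappa + 2)
  todo <- which(hits > 0L)
  rounds <- 0L
  while (length(todo)) {
    rounds <- rounds + 1L
    u <- stats::runif(length(todo))
    step <- integer(length(todo))
    step[u < p_ts] <- 2L                                 # transition
    step[u >= p_ts] <- sample(c(1L, 3L), sum(u >= p_ts), replace = TRUE)
    x[todo] <- (x[todo] + step) %% 4L
    todo <- todo[hits[todo] > rounds]
  }
  out <- decode_dna(x)
  # restore N positions verbatim
  if (anyNA(encode_dna(seq))) {
    sv <- strsplit(seq, "")[[1]]
    ov <- strsplit(out, "")[[1]]
    keep <- sv == "N"
    ov[keep] <- "N"
    out <- paste(ov, collapse = "")
  }
  out
}

#' Per-branch insertion intensities emulating a colonization wave
#'
#' The formation-rate profile peaks on the stem of the crown clade (the
#' "first and major wave" of germ-line colonization) and is `peak_factor`
#' times lower per MY on all crown branches; intensities are scaled so the
#' expected total equals `n_expected`.
#'
#' @param tree A [species_tree()].
#' @param n_expected Expected total number of insertion events.
#' @param peak_factor Per-MY intensity ratio stem : crown branches.
#' @return Named numeric vector of expected event counts per branch.
#' @export
default_insertion_rates <- function(tree, n_expected = 150, peak_factor = 10) {
  br <- tree$branches
  w <- ifelse(br$branch_id == "stem", br$length, br$length / peak_factor)
  if (sum(w) <= 0) stop("default_insertion_rates: tree has no branch length")
  stats::setNames(n_expected * w / sum(w), br$branch_id)
}

#' Simulate ERV colonization of a clade with full ground truth
#'
#' Evolves a background genome down a dated species tree, planting ERV
#' insertion events with known branch, mechanism and coordinates. Per
#' branch, event counts are Poisson with the given intensity; mechanisms are
#' drawn provirus : processed pseudogene at `mix` (default 1:2, the ratio
#' observed for this group); every insertion duplicates a target site.
#' Sequences accumulate substitutions at `config$subst_rate` x branch
#' length under the transition-biased model of [mutate_sequence()].
#' Optionally, planted proviruses later collapse to solitary LTRs by LTR-LTR
#' recombination on a descendant branch, and loci are deleted in individual
#' species (a clean empty site remains).
#'
#' Insertion positions are drawn from a pre-sampled pool of well-separated
#' ancestral positions, so loci never nest and remain independent across
#' lineages. Insertions take effect at the top of their branch.
#'
#' @param tree A [species_tree()].
#' @param model An [erv_model()].
#' @param rates Named expected event count per branch; defaults to
#'   [default_insertion_rates()] with 150 expected events.
#' @param config A [pipeline_config()].
#' @param bg_len Ancestral background genome length (nt); `NULL` auto-sizes
#'   to ten times the expected planted sequence (1 Mb floor).
#' @param prov_frac Probability that an event is a provirus (default 1/3,
#'   i.e. a 2:1 pseudogene:provirus mix).
#' @param n_recomb Number of planted LTR-LTR recombination events (placed on
#'   proviruses inserted on internal branches, on a uniformly drawn strictly
#'   descendant branch).
#' @param p_del Per-(locus, descendant species) deletion probability.
#' @param seed Seed for the whole simulation (`NULL`: current RNG stream).
#'
#' @return An object of class `erv_simulation`: `genomes` (tibble
#'   species_id/contig_id/seq), `truth` (tibble locus_id/species_id/state/
#'   start0/end0/strand/seq with states full, solitary_ltr, empty,
#'   deleted_region), `events` (one row per insertion event), plus the tree,
#'   model, rates and config used.
#' @export
simulate_erv_history <- function(tree, model = erv_model(seed = 99L),
                                 rates = NULL,
                                 config = pipeline_config(),
                                 bg_len = NULL, prov_frac = 1 / 3,
                                 n_recomb = 0L, p_del = 0,
                                 seed = NULL) {
  rates <- rates %||% default_insertion_rates(tree)
  br <- tree$branches
  if (!all(names(rates) %in% br$branch_id)) {
    stop("simulate_erv_history: rates name unknown branches: ",
         paste(setdiff(names(rates), br$branch_id), collapse = ", "))
  }
  rates <- stats::setNames(rates[br$branch_id], br$branch_id)
  rates[is.na(rates)] <- 0

  elem_max <- max(nchar(build_provirus(model)),
                  nchar(build_processed_pseudogene(model)))
  e_total <- sum(rates)
  bg_len <- as.integer(bg_len %||% max(1e6, ceiling(10 * e_total * elem_max)))
  min_dist <- 2L * config$flank_len + config$merge_gap + 1000L
  margin <- config$flank_len + 1000L
  pool_size <- ceiling(e_total + 6 * sqrt(e_total) + 10)
  if (pool_size * min_dist > bg_len - 2L * margin) {
    stop("simulate_erv_history: infeasible — expected insertions (",
         round(e_total), ") need ~", pool_size * min_dist,
         " nt of spacing but the background is ", bg_len, " nt")
  }

  with_seed(seed %||% config$rng_seed, {
    bg <- random_dna(bg_len)

    # pool of well-separated ancestral anchors
    anchors <- integer(0)
    tries <- 0L
    while (length(anchors) < pool_size && tries < 50L * pool_size) {
      tries <- tries + 1L
      a <- sample.int(bg_len - 2L * margin, 1L) + margin
      if (!length(anchors) || min(abs(anchors - a)) >= min_dist) {
        anchors <- c(anchors, a)
      }
    }
    if (length(anchors) < pool_size) {
      stop("simulate_erv_history: could not place a well-separated anchor pool")
    }

    # ---- pass 1: draw all insertion events, branch by branch (preorder)
    ord <- preorder_branches(tree)
    n_ev <- stats::rpois(length(ord), rates[ord])
    total <- sum(n_ev)
    if (total > length(anchors)) {           # extreme Poisson tail
      stop("simulate_erv_history: realized events exceed anchor pool; ",
           "increase bg_len")
    }
    events <- tibble::tibble(
      locus_id = sprintf("L%04d", seq_len(total)),
      branch_id = rep(ord, n_ev),
      mechanism = ifelse(stats::runif(total) < prov_frac, "provirus",
                         "processed_pseudogene"),
      anchor = anchors[seq_len(total)],
      strand = sample(c("+", "-"), total, replace = TRUE),
      recomb_branch = NA_character_
    )

    # ---- schedule LTR-LTR recombinations on strictly descendant branches
    if (n_recomb > 0L) {
      desc <- lapply(events$branch_id, descendant_branches, tree = tree)
      eligible <- which(events$mechanism == "provirus" & lengths(desc) > 0L)
      if (length(eligible) < n_recomb) {
        stop("simulate_erv_history: only ", length(eligible),
             " proviruses on internal branches; cannot place ", n_recomb,
             " recombination events")
      }
      chosen <- sample(eligible, n_recomb)
      events$recomb_branch[chosen] <- vapply(
        desc[chosen], function(d) d[sample.int(length(d), 1L)], character(1))
    }

    # ---- deletions per (event, descendant species)
    tipset <- lapply(events$branch_id, tips_of_branch, tree = tree)
    deletions <- if (p_del > 0 && total > 0L) {
      del <- purrr::map2_dfr(events$locus_id, tipset, function(id, tips) {
        hit <- tips[stats::runif(length(tips)) < p_del]
        if (length(hit)) tibble::tibble(locus_id = id, species_id = hit)
        else NULL
      })
      del
    } else {
      tibble::tibble(locus_id = character(), species_id = character())
    }

    # element master copies (genome orientation)
    events$seq0 <- vapply(seq_len(total), function(i) {
      s <- if (events$mechanism[i] == "provirus") build_provirus(model)
           else build_processed_pseudogene(model)
      if (events$strand[i] == "-") revcomp(s) else s
    }, character(1))

    # ---- pass 2: evolve lineages down the tree
    # lineage state: list(bg = string, elems = named list locus_id -> seq,
    #                      solitary = character())
    root_state <- list(bg = bg, elems = list(), solitary = character(0))
    states <- list()  # keyed by child_node of each branch

    branch_row <- function(id) br[br$branch_id == id, ]
    evolve_branch <- function(state, id) {
      row <- branch_row(id)
      # recombination scheduled on this branch
      rec <- events$locus_id[!is.na(events$recomb_branch) &
                               events$recomb_branch == id]
      for (lid in intersect(rec, names(state$elems))) {
        i <- match(lid, events$locus_id)
        s <- state$elems[[lid]]
        if (events$strand[i] == "-") s <- revcomp(s)
        ltr <- apply_ltr_recombination(s, "provirus", model$ltr_len)
        if (events$strand[i] == "-") ltr <- revcomp(ltr)
        state$elems[[lid]] <- ltr
        state$solitary <- c(state$solitary, lid)
      }
      # new insertions at the top of this branch
      new <- which(events$branch_id == id)
      for (i in new) state$elems[[events$locus_id[i]]] <- events$seq0[i]
      # deletions on terminal branches (after insertion, so an event both
      # gained and deleted on a terminal branch leaves a clean empty site)
      tips <- tips_of_branch(tree, id)
      if (length(tips) == 1L && nrow(deletions)) {
        gone <- deletions$locus_id[deletions$species_id == tips]
        keep <- setdiff(names(state$elems), gone)
        state$elems <- state$elems[keep]
        state$solitary <- setdiff(state$solitary, gone)
      }
      # substitutions over the branch
      mu <- config$subst_rate * row$length
      if (mu > 0) {
        state$bg <- mutate_sequence(state$bg, mu, config$kappa)
        state$elems <- lapply(state$elems, mutate_sequence, mu, config$kappa)
      }
      state
    }

    for (id in ord) {
      row <- branch_row(id)
      parent_state <- if (id == "stem") root_state
                      else states[[as.character(row$parent_node)]]
      states[[as.character(row$child_node)]] <- evolve_branch(parent_state, id)
    }

    # ---- assemble leaf genomes and truth
    tsd <- model$tsd_len
    tip_labels <- tree$phylo$tip.label
    genomes <- vector("list", length(tip_labels))
    truth <- vector("list", length(tip_labels))
    for (si in seq_along(tip_labels)) {
      sp <- tip_labels[si]
      node <- match(sp, tree$phylo$tip.label)
      st <- states[[as.character(node)]]
      present <- names(st$elems)
      ord_i <- order(events$anchor[match(present, events$locus_id)])
      present <- present[ord_i]
      a <- events$anchor[match(present, events$locus_id)]
      pieces <- character(0)
      starts <- integer(length(present))
      ends <- integer(length(present))
      cursor <- 0L
      offset <- 0L
      for (j in seq_along(present)) {
        cut <- a[j] + tsd
        pieces <- c(pieces, slice0(st$bg, cursor, cut))
        starts[j] <- cut + offset
        el <- st$elems[[present[j]]]
        pieces <- c(pieces, el)
        ends[j] <- starts[j] + nchar(el)
        offset <- offset + nchar(el) + tsd
        cursor <- a[j]                      # duplicates the TSD
      }
      pieces <- c(pieces, slice0(st$bg, cursor, bg_len))
      gseq <- paste(pieces, collapse = "")
      genomes[[si]] <- tibble::tibble(species_id = sp, contig_id = "chr1",
                                      seq = gseq, length = nchar(gseq))

      below <- vapply(tipset, function(tp) sp %in% tp, logical(1))
      state_lab <- ifelse(!below, "empty",
                   ifelse(events$locus_id %in%
                            deletions$locus_id[deletions$species_id == sp],
                          "deleted_region",
                   ifelse(events$locus_id %in% st$solitary, "solitary_ltr",
                          "full")))
      idx <- match(events$locus_id, present)
      ok <- !is.na(idx)
      sv <- rep(NA_character_, nrow(events))
      s0 <- rep(NA_integer_, nrow(events))
      e0 <- rep(NA_integer_, nrow(events))
      if (any(ok)) {
        elem_seqs <- unlist(st$elems[present], use.names = FALSE)
        sv[ok] <- elem_seqs[idx[ok]]
        s0[ok] <- starts[idx[ok]]
        e0[ok] <- ends[idx[ok]]
      }
      truth[[si]] <- tibble::tibble(
        locus_id = events$locus_id, species_id = sp, state = state_lab,
        contig_id = "chr1", start0 = s0, end0 = e0,
        strand = events$strand, seq = sv
      )
    }

    structure(list(
      genomes = dplyr::bind_rows(genomes),
      truth = dplyr::bind_rows(truth),
      events = dplyr::select(events, -"seq0"),
      deletions = deletions,
      tree = tree, model = model, rates = rates, config = config,
      bg_len = bg_len, seed = seed
    ), class = "erv_simulation")
  })
}

#' @export
print.erv_simulation <- function(x, ...) {
  cat("<erv_simulation> ", nrow(x$events), " insertion events across ",
      x$tree$n_tip, " species (background ", x$bg_len, " nt)\n", sep = "")
  print(dplyr::count(x$events, .data$branch_id, .data$mechanism))
  invisible(x)
}

#' @method glance erv_simulation
#' @export
glance.erv_simulation <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$events),
    n_provirus = sum(x$events$mechanism == "provirus"),
    n_pseudogene = sum(x$events$mechanism == "processed_pseudogene"),
    n_recombined = sum(!is.na(x$events$recomb_branch)),
    n_deletions = nrow(x$deletions),
    n_species = x$tree$n_tip,
    bg_len = x$bg_len
  )
}
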