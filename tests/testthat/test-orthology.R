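# Constructed-target tests for the flank-anchored mapper, then
# whole-matrix checks against simulator truth.

make_locus_row <- function(f5, f3, seq, cfg) {
  tibble::tibble(locus_id = "L", species_id = "src", contig_id = "c",
                 start0 = nchar(f5), end0 = nchar(f5) + nchar(seq),
                 strand = "+", identity = 1, n_hits = 1L,
                 internal_cov = NA_integer_, ltr_cov = NA_integer_,
                 sequence = seq, flank5 = f5, flank3 = f3)
}

test_that("map_locus distinguishes full, solitary and empty targets", {
  m <- mini_model()
  cfg <- mini_config()
  f5 <- random_seq(300, seed = 101)
  f3 <- random_seq(300, seed = 102)
  pad1 <- random_seq(5000, seed = 103)
  pad2 <- random_seq(5000, seed = 104)
  loc <- make_locus_row(f5, f3, build_provirus(m), cfg)

  target_full <- paste0(pad1, f5, build_provirus(m), f3, pad2)
  expect_equal(map_locus(loc, target_full, m, cfg)$state, "full")

  target_sol <- paste0(pad1, f5, m$ltr_seq, f3, pad2)
  r_sol <- map_locus(loc, target_sol, m, cfg)
  expect_equal(r_sol$state, "solitary_ltr")

  target_empty <- paste0(pad1, f5, f3, pad2)
  r_empty <- map_locus(loc, target_empty, m, cfg)
  expect_equal(r_empty$state, "empty")

  # flanks absent entirely -> unresolved, not a guess
  r_un <- map_locus(loc, paste0(pad1, pad2), m, cfg)
  expect_equal(r_un$state, "unresolved")

  # pre-insertion site on the minus strand still reads as empty
  target_rc <- ervography:::revcomp(target_empty)
  expect_equal(map_locus(loc, target_rc, m, cfg)$state, "empty")

  # interval overlapping an assembly gap -> unresolved
  target_n <- paste0(pad1, f5, strrep("N", 400), f3, pad2)
  expect_equal(map_locus(loc, target_n, m, cfg)$state, "unresolved")
})

test_that("ortholog matrix equals simulator truth state-for-state", {
  sim <- mini_sim()
  res <- mini_pipeline()
  sc <- score_against_truth(res, sim)
  expect_true(sc$all_states_equal)
  expect_equal(sc$state_accuracy, 1)
  expect_equal(sc$n_unmatched_truth, 0L)
  expect_equal(sc$n_false_clusters, 0L)
})

test_that("Dollo assignment follows the LCA-of-presence rule", {
  tr <- default_catarrhini_tree()
  fake_matrix <- function(pres, sol = character(0)) {
    sp <- tr$phylo$tip.label
    st <- tibble::tibble(
      cluster_id = "C0001", species_id = sp,
      state = ifelse(sp %in% sol, "solitary_ltr",
                     ifelse(sp %in% pres, "full", "empty")),
      start0 = NA_integer_, end0 = NA_integer_, source = "mapped")
    structure(list(states = st,
                   clusters = tibble::tibble(cluster_id = "C0001",
                                             cluster_class = "provirus"),
                   tree = tr), class = "erv_ortholog_matrix")
  }

  m1 <- assign_formation_branches(fake_matrix(c("human", "chimp",
                                                "gorilla")))
  expect_equal(m1$clusters$formation_branch, "chimp+gorilla+human")
  expect_equal(m1$clusters$n_losses, 0L)

  # presence only at the two ends of the tree: stem formation, 4 losses
  m2 <- assign_formation_branches(fake_matrix(c("human", "rhesus")))
  expect_equal(m2$clusters$formation_branch, "stem")
  expect_equal(m2$clusters$n_losses, 4L)
  expect_setequal(m2$clusters$loss_species[[1]],
                  c("chimp", "gorilla", "orangutan", "gibbon"))

  # single species: terminal branch
  m3 <- assign_formation_branches(fake_matrix("rhesus"))
  expect_equal(m3$clusters$formation_branch, "rhesus")

  # solitary LTRs count as presence
  m4 <- assign_formation_branches(fake_matrix("rhesus", sol = "human"))
  expect_equal(m4$clusters$formation_branch, "stem")

  # monotonicity: adding a presence never moves the branch tipward
  depth <- function(br) {
    b <- tr$branches
    b$parent_age[b$branch_id == br]
  }
  base <- c("human", "chimp")
  d0 <- depth(assign_formation_branches(
    fake_matrix(base))$clusters$formation_branch)
  for (extra in c("gorilla", "gibbon", "rhesus")) {
    d1 <- depth(assign_formation_branches(
      fake_matrix(c(base, extra)))$clusters$formation_branch)
    expect_gte(d1, d0)
  }
})

test_that("recombination inference calls maximal solitary clades", {
  tr <- default_catarrhini_tree()
  fake <- function(sol, class = "provirus", full_rest = TRUE) {
    sp <- tr$phylo$tip.label
    st <- tibble::tibble(
      cluster_id = "C0001", species_id = sp,
      state = ifelse(sp %in% sol, "solitary_ltr",
                     if (full_rest) "full" else "empty"),
      start0 = NA_integer_, end0 = NA_integer_, source = "mapped")
    structure(list(states = st,
                   clusters = tibble::tibble(cluster_id = "C0001",
                                             cluster_class = class),
                   tree = tr), class = "erv_ortholog_matrix")
  }
  # full in rhesus only, solitary in all hominoids: one call on the
  # hominoid stem
  calls <- infer_recombination_events(
    fake(c("human", "chimp", "gorilla", "orangutan", "gibbon")))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$branch_id,
               "chimp+gibbon+gorilla+human+orangutan")

  # all full: nothing to call
  none <- infer_recombination_events(fake(character(0)))
  expect_equal(nrow(none), 0L)

  # pseudogene cluster: call suppressed with a warning
  expect_warning(
    sup <- infer_recombination_events(fake("human",
                                           class = "processed_pseudogene")),
    "suppressed")
  expect_equal(nrow(sup), 0L)
})

test_that("formation report conserves every cluster exactly once", {
  res <- mini_pipeline()
  rep <- res$formation_report
  expect_equal(sum(rep$total),
               sum(!is.na(res$matrix$clusters$formation_branch)))
  # one row per branch of the tree (plus stem)
  expect_equal(nrow(rep), nrow(res$tree$branches))
  # seeded per-branch counts match the planted events
  sim <- mini_sim()
  planted <- table(sim$events$branch_id)
  for (br in names(planted)) {
    expect_equal(rep$total[rep$formation_branch == br],
                 as.integer(planted[[br]]), label = br)
  }
})
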