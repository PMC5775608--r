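test_that("zero insertion rate yields substitution-only evolution", {
  tr <- default_catarrhini_tree()
  m <- mini_model()
  cfg <- mini_config()
  rates <- stats::setNames(rep(0, nrow(tr$branches)), tr$branches$branch_id)
  sim <- simulate_erv_history(tr, m, rates, cfg, bg_len = 50000, seed = 3)
  expect_equal(nrow(sim$events), 0L)
  expect_equal(nrow(sim$truth), 0L)
  g <- sim$genomes
  expect_equal(unique(nchar(g$seq)), 50000L)
  # genomes differ only by substitutions: divergence grows with path length
  d_hc <- 1 - ervography:::string_identity(g$seq[g$species_id == "human"],
                                           g$seq[g$species_id == "chimp"])
  d_hr <- 1 - ervography:::string_identity(g$seq[g$species_id == "human"],
                                           g$seq[g$species_id == "rhesus"])
  expect_gt(d_hc, 0)
  expect_gt(d_hr, d_hc)
})

test_that("a single event obeys forward Dollo logic", {
  tr <- default_catarrhini_tree()
  m <- mini_model()
  cfg <- mini_config()
  rates <- stats::setNames(rep(0, nrow(tr$branches)), tr$branches$branch_id)
  rates["chimp+gorilla+human"] <- 40   # expected 40 -> at least one event
  sim <- simulate_erv_history(tr, m, rates, cfg, bg_len = 1e6, seed = 5)
  expect_gt(nrow(sim$events), 0L)
  expect_true(all(sim$events$branch_id == "chimp+gorilla+human"))
  inside <- c("human", "chimp", "gorilla")
  st <- sim$truth
  expect_true(all(st$state[st$species_id %in% inside] == "full"))
  expect_true(all(st$state[!st$species_id %in% inside] == "empty"))
})

test_that("mechanism mix matches the configured 2:1 ratio", {
  tr <- default_catarrhini_tree()
  m <- mini_model()
  cfg <- mini_config()
  sim <- simulate_erv_history(tr, m, default_insertion_rates(tr, 200), cfg,
                              bg_len = 2e6, seed = 8)
  n <- nrow(sim$events)
  frac <- mean(sim$events$mechanism == "processed_pseudogene")
  # binomial 3-sigma band around 2/3 at the realized n
  band <- 3 * sqrt(2 / 9 / n)
  expect_lt(abs(frac - 2 / 3), band)
})

test_that("realized states slice back to the genomes exactly", {
  sim <- mini_sim()
  tt <- sim$truth[sim$truth$state %in% c("full", "solitary_ltr"), ]
  expect_gt(nrow(tt), 0L)
  for (i in seq_len(nrow(tt))) {
    g <- sim$genomes$seq[sim$genomes$species_id == tt$species_id[i]]
    expect_identical(substring(g, tt$start0[i] + 1, tt$end0[i]), tt$seq[i])
  }
  # recombined species carry an LTR-length element
  sol <- tt[tt$state == "solitary_ltr", ]
  expect_gt(nrow(sol), 0L)
  expect_true(all(nchar(sol$seq) == sim$model$ltr_len))
})

test_that("divergence between leaf copies grows linearly with path length", {
  tr <- default_catarrhini_tree()
  m <- mini_model()
  cfg <- mini_config()
  rates <- stats::setNames(rep(0, nrow(tr$branches)), tr$branches$branch_id)
  rates["stem"] <- 100
  sim <- simulate_erv_history(tr, m, rates, cfg, bg_len = 1.5e6, seed = 13)
  tt <- sim$truth[sim$truth$state == "full", ]
  pairs <- list(c("human", "chimp"), c("human", "gorilla"),
                c("human", "orangutan"), c("human", "gibbon"),
                c("human", "rhesus"))
  path_my <- c(14, 20, 34, 40, 60)
  mean_d <- vapply(pairs, function(pr) {
    a <- tt[tt$species_id == pr[1], ]
    b <- tt[tt$species_id == pr[2], ]
    ids <- intersect(a$locus_id, b$locus_id)
    mean(vapply(ids, function(l) {
      1 - ervography:::string_identity(a$seq[a$locus_id == l],
                                       b$seq[b$locus_id == l])
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(mean_d ~ 0 + path_my)
  slope <- unname(stats::coef(fit)[1])
  # within 10% of the substitution rate (divergence = rate x path length)
  expect_lt(abs(slope - cfg$subst_rate) / cfg$subst_rate, 0.10)
})

test_that("infeasible insertion load is refused up front", {
  tr <- default_catarrhini_tree()
  m <- mini_model()
  cfg <- mini_config()
  expect_error(
    simulate_erv_history(tr, m, default_insertion_rates(tr, 500), cfg,
                         bg_len = 1e5, seed = 1),
    "infeasible")
})

test_that("deletions leave clean empty sites recorded as deleted_region", {
  tr <- default_catarrhini_tree()
  m <- mini_model()
  cfg <- mini_config()
  sim <- simulate_erv_history(tr, m, default_insertion_rates(tr, 30), cfg,
                              bg_len = 6e5, p_del = 0.2, seed = 17)
  del <- sim$truth[sim$truth$state == "deleted_region", ]
  expect_gt(nrow(del), 0L)
  expect_true(all(is.na(del$start0)))
  # deleted loci appear in the deletions ledger
  expect_true(all(paste(del$locus_id, del$species_id) %in%
                    paste(sim$deletions$locus_id,
                          sim$deletions$species_id)))
})
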