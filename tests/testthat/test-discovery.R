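test_that("seed index records every k-mer position", {
  idx <- build_seed_index("ACGTACGT", k = 4)
  expect_equal(seed_positions(idx, "ACGT"), c(0L, 4L))
  expect_equal(seed_positions(idx, "CGTA"), 1L)
  expect_equal(seed_positions(idx, "AAAA"), integer(0))
  expect_error(build_seed_index("ACGT", k = 10), "exceeds")

  idxn <- build_seed_index(strrep("N", 100), k = 8)
  expect_equal(nrow(idxn$dt), 0L)
})

test_that("k-mer multiplicity in random sequence matches the Poisson rate", {
  g <- random_seq(1e6, seed = 21)
  idx <- build_seed_index(g, k = 12)
  # mean positions per *distinct observed* k-mer, compared with the
  # conditional expectation E[X | X >= 1] for X ~ Poisson(lambda)
  lam <- (1e6 - 11) / 4^12
  expected <- lam / (1 - exp(-lam))
  tab <- idx$dt[, .N, by = "kmer"]$N
  se <- stats::sd(tab) / sqrt(length(tab))
  expect_lt(abs(mean(tab) - expected), 3 * se + 1e-4)
})

test_that("search finds planted queries exactly, on both strands", {
  cfg <- mini_config()
  q <- random_seq(500, seed = 31)
  bg <- random_seq(50000, seed = 32)
  g <- paste0(substr(bg, 1, 20000), q, substring(bg, 20001))
  h <- search_genome(q, g, cfg)
  expect_equal(nrow(h), 1L)
  expect_equal(h$tstart0, 20000L)
  expect_equal(h$tend0, 20500L)
  expect_equal(h$strand, "+")
  expect_equal(h$identity, 1)

  g2 <- paste0(substr(bg, 1, 20000), ervography:::revcomp(q),
               substring(bg, 20001))
  h2 <- search_genome(q, g2, cfg)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$tstart0, 20000L)
  expect_equal(h2$tend0, 20500L)
  expect_equal(h2$strand, "-")
})

test_that("search tolerates divergence and reports calibrated identity", {
  cfg <- mini_config()
  q <- random_seq(2000, seed = 41)
  qm <- flat_mutate(q, 0.05, seed = 42)
  bg <- random_seq(60000, seed = 43)
  g <- paste0(substr(bg, 1, 30000), qm, substring(bg, 30001))
  h <- search_genome(q, g, cfg)
  expect_equal(nrow(h), 1L)
  covered <- min(h$tend0, 32000) - max(h$tstart0, 30000)
  expect_gte(covered, 0.95 * 2000)
  expect_gte(h$identity, 0.93)
  expect_lte(h$identity, 0.97)
})

test_that("search is strand-symmetric", {
  cfg <- mini_config()
  m <- mini_model()
  bg <- random_seq(40000, seed = 51)
  g <- paste0(substr(bg, 1, 15000), m$query_seq, substring(bg, 15001))
  grc <- ervography:::revcomp(g)
  h <- search_genome(m$query_seq, g, cfg)
  hrc <- search_genome(m$query_seq, grc, cfg)
  # intervals must mirror exactly: [s, e) <-> [L - e, L - s)
  L <- nchar(g)
  expect_equal(sort(L - h$tend0), sort(hrc$tstart0))
  expect_equal(sort(L - h$tstart0), sort(hrc$tend0))
})

test_that("hit merging respects the gap threshold and is idempotent", {
  cfg <- mini_config()  # merge_gap 500
  hit <- function(s, e) tibble::tibble(
    species_id = "sp", contig_id = "c", tstart0 = s, tend0 = e,
    strand = "+", qstart0 = 0L, qend0 = e - s, identity = 0.95,
    aligned_len = e - s, n_seeds = 5L)
  g <- random_seq(20000, seed = 61)

  near <- dplyr::bind_rows(hit(5000L, 5600L), hit(6000L, 6500L))
  one <- merge_hits(near, g, cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(one$start0, 5000L)
  expect_equal(one$end0, 6500L)

  far <- dplyr::bind_rows(hit(5000L, 5600L), hit(11000L, 11500L))
  two <- merge_hits(far, g, cfg)
  expect_equal(nrow(two), 2L)

  # idempotent and order-independent
  again <- merge_hits(far[2:1, ], g, cfg)
  expect_equal(two$start0, again$start0)
  expect_equal(two$locus_id, again$locus_id)
  expect_equal(nchar(two$flank5), rep(cfg$flank_len, 2L))
  expect_equal(two$sequence[1], substring(g, 5001, 5600))
})

test_that("discovery recovers planted loci and stays silent on background", {
  sim <- mini_sim()
  cfg <- sim$config
  truth_h <- subset(sim$truth,
                    species_id == "human" & state != "empty")
  g <- sim$genomes[sim$genomes$species_id == "human", ]
  loci <- discover_loci(g, sim$model, cfg)
  expect_equal(nrow(loci), nrow(truth_h))
  # every planted element recovered with >= 90% overlap
  for (i in seq_len(nrow(truth_h))) {
    ov <- pmin(loci$end0, truth_h$end0[i]) -
      pmax(loci$start0, truth_h$start0[i])
    expect_gte(max(ov) / (truth_h$end0[i] - truth_h$start0[i]), 0.9)
  }
  # insertion-free background of 1 Mb: zero loci at default thresholds
  bg <- random_seq(1e6, seed = 71)
  none <- discover_loci(
    tibble::tibble(species_id = "bg", contig_id = "c", seq = bg),
    sim$model, cfg)
  expect_equal(nrow(none), 0L)
})
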