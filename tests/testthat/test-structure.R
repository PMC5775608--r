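test_that("LTR detection reads the provirus and pseudogene signatures", {
  m <- mini_model()
  cfg <- mini_config()
  pv <- build_provirus(m)
  a <- detect_ltrs(pv, m, cfg)
  expect_equal(a$ltr_identity, 1)
  expect_true(a$has_u3_5prime)
  expect_true(a$has_u5_3prime)
  expect_equal(a$ltr5_start0, 0L)
  expect_equal(a$ltr3_end0, nchar(pv))

  pg <- build_processed_pseudogene(m)
  b <- detect_ltrs(pg, m, cfg)
  expect_false(b$has_u3_5prime)
  expect_false(b$has_u5_3prime)
  expect_true(b$polya)
})

test_that("solitary LTR with a planted TSD is annotated", {
  m <- mini_model()
  cfg <- mini_config()
  f5 <- paste0(random_seq(296, seed = 81), "ACTG")
  f3 <- paste0("ACTG", random_seq(296, seed = 82))
  a <- detect_ltrs(m$ltr_seq, m, cfg, flank5 = f5, flank3 = f3)
  expect_equal(a$tsd, "ACTG")
  expect_gte(a$ltr5_cov, cfg$ltr_min_align)
})

test_that("detection is consistent under reverse complement", {
  m <- mini_model()
  cfg <- mini_config()
  pv <- build_provirus(m)
  fwd <- detect_ltrs(pv, m, cfg)
  # a minus-strand locus, re-oriented as classify_loci does, must yield the
  # same signature
  rc <- ervography:::revcomp(pv)
  back <- detect_ltrs(ervography:::revcomp(rc), m, cfg)
  expect_equal(back, fwd)
})

test_that("classification follows the decision order on clean inputs", {
  m <- mini_model()
  cfg <- mini_config()
  cls <- function(seq, internal_cov) {
    classify_locus(detect_ltrs(seq, m, cfg), internal_cov, cfg)$structure
  }
  expect_equal(cls(build_provirus(m), 600L), "provirus")
  expect_equal(cls(build_processed_pseudogene(m), 600L),
               "processed_pseudogene")
  expect_equal(cls(m$ltr_seq, 0L), "solitary_ltr")
  expect_equal(cls(m$internal_seq, 600L), "undefined")
})

test_that("classification matches the planted mechanism across a simulation", {
  sim <- mini_sim()
  cfg <- sim$config
  for (sp in c("human", "rhesus")) {
    g <- sim$genomes[sim$genomes$species_id == sp, ]
    loci <- classify_loci(discover_loci(g, sim$model, cfg), sim$model, cfg)
    tt <- sim$truth[sim$truth$species_id == sp &
                      sim$truth$state != "empty", ]
    for (i in seq_len(nrow(tt))) {
      ov <- pmin(loci$end0, tt$end0[i]) - pmax(loci$start0, tt$start0[i])
      j <- which.max(ov)
      mech <- sim$events$mechanism[sim$events$locus_id == tt$locus_id[i]]
      want <- if (tt$state[i] == "solitary_ltr") "solitary_ltr" else mech
      expect_equal(loci$structure[j], want,
                   label = paste(sp, tt$locus_id[i], loci$structure[j]))
    }
  }
})

test_that("LTR divergence dating is exact, monotone and guarded", {
  m <- mini_model()
  a0 <- ltr_age(m$ltr_seq, m$ltr_seq, rate = 2.2e-3)
  expect_equal(a0$age_mya, 0)
  expect_true(a0$unreliable)   # 120 aligned nt < 200

  # age = d / (2 rate) with d from the K2P closed form; construct 1000 nt
  # LTRs with exactly 8 transitions and 2 transversions per 100 sites
  ltr <- random_seq(1000, seed = 91)
  v <- strsplit(ltr, "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  # spread the mutations out so the global aligner has no incentive to gap
  ts_pos <- seq(5, 795, by = 10)            # 80 transitions
  tv_pos <- seq(805, 995, by = 10)          # 20 transversions
  v2 <- v
  v2[ts_pos] <- ts_map[v[ts_pos]]
  v2[tv_pos] <- tv_map[v[tv_pos]]
  res <- ltr_age(ltr, paste(v2, collapse = ""), rate = 2.25e-3)
  d_oracle <- -0.5 * log((1 - 2 * 0.08 - 0.02) * sqrt(1 - 2 * 0.02))
  expect_equal(res$d_k2p, d_oracle, tolerance = 1e-9)
  expect_equal(res$age_mya, d_oracle / (2 * 2.25e-3), tolerance = 1e-9)
  expect_false(res$unreliable)
  expect_lt(res$age_lo, res$age_mya)
  expect_gt(res$age_hi, res$age_mya)

  expect_error(ltr_age(NULL, ltr), "required")
  expect_error(ltr_age("", ltr), "required")
})

test_that("putein extraction finds planted ORFs and flags decay", {
  m <- mini_model()
  pv <- build_provirus(m)
  pt <- find_puteins(pv, m)
  expect_setequal(pt$gene, c("gag", "pol", "env"))
  expect_false(any(pt$disrupted))
  # the gag putein is the conceptual translation of the planted gag ORF
  segs <- m$segments
  gag <- substring(pv, segs$start0[segs$segment == "gag"] + 1,
                   segs$end0[segs$segment == "gag"])
  gag_aa <- sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(gag))))
  expect_equal(pt$aa_seq[pt$gene == "gag"], gag_aa)

  # reverse complement: same puteins, strand flipped
  ptr <- find_puteins(ervography:::revcomp(pv), m)
  expect_equal(sort(ptr$aa_seq), sort(pt$aa_seq))
  expect_true(all(ptr$strand == "-"))

  # stop-riddled sequence: everything disrupted
  stops <- paste(rep("TAA", 400), collapse = "")
  ptd <- find_puteins(stops, m)
  expect_true(all(ptd$disrupted))
})
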