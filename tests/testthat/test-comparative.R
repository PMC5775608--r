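test_that("pairwise global alignment handles matches, gaps and symmetry", {
  a <- pairwise_align("ACGT", "ACGT")
  expect_equal(unclass(a)[["a"]], "ACGT")
  expect_equal(unclass(a)[["b"]], "ACGT")

  g <- pairwise_align("ACGT", "AGT")
  rows <- unclass(g)
  expect_equal(nchar(rows[["a"]]), 4L)
  expect_equal(sum(strsplit(rows[["b"]], "")[[1]] == "-"), 1L)
  m <- sum(strsplit(rows[["a"]], "")[[1]] == strsplit(rows[["b"]], "")[[1]])
  expect_equal(m, 3L)

  s1 <- random_seq(300, seed = 1); s2 <- flat_mutate(s1, 0.1, seed = 2)
  expect_equal(attr(pairwise_align(s1, s2), "score"),
               attr(pairwise_align(s2, s1), "score"))
  expect_error(pairwise_align("", "ACGT"), "empty")
})

test_that("progressive MSA is lossless and recovers a planted deletion", {
  base <- random_seq(600, seed = 11)
  del <- paste0(substr(base, 1, 300), substring(base, 311))
  seqs <- c(x = base, y = flat_mutate(base, 0.02, seed = 12), z = del)
  aln <- progressive_msa(seqs)
  expect_s3_class(aln, "erv_alignment")
  expect_equal(gsub("-", "", unclass(aln)), seqs)
  # the deleted row carries a 10-column gap block
  expect_match(unclass(aln)[["z"]], "-{10}")

  one <- progressive_msa(c(solo = "ACGT"))
  expect_equal(unclass(one)[["solo"]], "ACGT")

  same <- progressive_msa(c(p = base, q = base))
  expect_equal(unclass(same)[["p"]], base)   # gap-free identical rows
})

test_that("majority consensus applies the strict-gap and tie rules", {
  cons <- majority_consensus(as_alignment(c("AAA", "AAA", "AAT")))
  expect_equal(cons$seq, "AAA")
  expect_equal(cons$support, c(1, 1, 2 / 3))

  tie <- majority_consensus(as_alignment(c("AT", "TT")))
  expect_equal(substr(tie$seq, 1, 1), "N")

  gappy <- majority_consensus(as_alignment(c("A-C", "A-C", "AGC")))
  expect_equal(gappy$seq, "AC")

  # idempotence: adding the consensus to a gap-free alignment changes
  # nothing
  aln <- c(random_seq(50, seed = 21), random_seq(50, seed = 21),
           flat_mutate(random_seq(50, seed = 21), 0.1, seed = 22))
  c1 <- majority_consensus(as_alignment(aln))
  c2 <- majority_consensus(as_alignment(c(aln, c1$seq)))
  expect_equal(c2$seq, c1$seq)
})

test_that("consensus of diverged copies recovers the master", {
  master <- random_seq(2000, seed = 31)
  copies <- vapply(1:10, function(i) flat_mutate(master, 0.05, seed = 31 + i),
                   character(1))
  names(copies) <- paste0("c", 1:10)
  cons <- majority_consensus(progressive_msa(copies))
  expect_equal(nchar(cons$seq), 2000L)
  agree <- mean(strsplit(cons$seq, "")[[1]] ==
                  strsplit(master, "")[[1]])
  expect_gte(agree, 0.999)
})

test_that("CpG-stripped p-distance follows the stated column rules", {
  expect_equal(p_distance_cpg_stripped("ACGTT", "ACGTT"), 0)
  # CpG in row a removes those two columns; the remaining columns agree
  expect_equal(p_distance_cpg_stripped("ACGTT", "ATGTT"), 0)
  expect_equal(p_distance_cpg_stripped("ACGTT", "ATGTT", strip_cpg = FALSE),
               1 / 5)
  # 10 mismatches over 100 CpG-free gap-free columns
  a <- strrep("AT", 50)
  bv <- strsplit(a, "")[[1]]
  bv[seq(1, 19, 2)] <- "G"   # A -> G at 10 sites; no CG created adjacent?
  b <- paste(bv, collapse = "")
  expect_equal(p_distance_cpg_stripped(a, b, strip_cpg = FALSE), 0.10)
  # pairwise deletion: gapped columns dropped
  expect_equal(p_distance_cpg_stripped("A-TT", "AATT", strip_cpg = FALSE), 0)
  expect_warning(out <- p_distance_cpg_stripped("--", "AA"), "no comparable")
  expect_true(is.na(out))
})

test_that("K2P distance matches the closed form and flags saturation", {
  a <- strrep("A", 100)
  expect_equal(k2p_distance(a, a), 0)

  # 8 transitions + 2 transversions per 100 sites, frozen closed form
  v <- strsplit(random_seq(100, seed = 41), "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  w <- v; w[1:8] <- ts_map[v[1:8]]; w[9:10] <- tv_map[v[9:10]]
  d <- k2p_distance(paste(v, collapse = ""), paste(w, collapse = ""))
  expect_equal(d, 0.1094310, tolerance = 1e-6)
  expect_equal(d, -0.5 * log((1 - 0.16 - 0.02) * sqrt(1 - 0.04)),
               tolerance = 1e-12)

  # P = 0.5, Q = 0: saturated
  x <- strrep("A", 100); y <- paste0(strrep("G", 50), strrep("A", 50))
  expect_warning(ds <- k2p_distance(x, y), "saturated")
  expect_true(is.infinite(ds))
})

test_that("K2P dominates p-distance (correction inequality)", {
  base <- random_seq(1000, seed = 51)
  for (p in c(0.01, 0.05, 0.15, 0.3)) {
    other <- flat_mutate(base, p, seed = round(1000 * p))
    dk <- suppressWarnings(k2p_distance(base, other))
    dp <- p_distance_cpg_stripped(base, other, strip_cpg = FALSE)
    expect_gte(dk, dp)
  }
  expect_equal(suppressWarnings(k2p_distance(base, base)),
               p_distance_cpg_stripped(base, base, strip_cpg = FALSE))
})

test_that("NJ recovers additive matrices and ignores input order", {
  # the generating topology is the oracle: distances from a random
  # ultrametric-free additive tree must reproduce its unrooted shape
  for (seed in 1:5) {
    for (ntax in c(4, 6, 8)) {
      tr <- ervography:::with_seed(seed * 100 + ntax, {
        t0 <- ape::rtree(ntax)
        t0$edge.length <- stats::runif(nrow(t0$edge), 0.05, 1)
        t0
      })
      dm <- ape::cophenetic.phylo(tr)
      est <- nj_tree(dm)
      expect_equal(ape::dist.topo(ape::unroot(tr), est)[[1]], 0)
    }
  }
  # four-point condition on a hand-built additive matrix
  dm <- matrix(c(0, 3, 6, 7,
                 3, 0, 7, 8,
                 6, 7, 0, 5,
                 7, 8, 5, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  # ((A,B),(C,D)): d(AB) + d(CD) < d(AC) + d(BD) = d(AD) + d(BC)
  expect_lt(dm["A", "B"] + dm["C", "D"], dm["A", "C"] + dm["B", "D"])
  est <- nj_tree(dm)
  split <- ape::prop.part(est)
  expect_equal(ape::dist.topo(est, ape::read.tree(
    text = "((A:1,B:2):1,C:3,D:4);"))[[1]], 0)

  perm <- c(3, 1, 4, 2)
  est2 <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(est, est2)[[1]], 0)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("distance matrices are symmetric with zero diagonal", {
  seqs <- c(a = random_seq(400, seed = 61),
            b = flat_mutate(random_seq(400, seed = 61), 0.05, seed = 62),
            c = flat_mutate(random_seq(400, seed = 61), 0.10, seed = 63))
  dm <- distance_matrix(as_alignment(seqs), "k2p")
  expect_equal(unclass(dm), t(unclass(dm)))
  expect_equal(diag(unclass(dm)), c(a = 0, b = 0, c = 0))
  td <- tidy(dm)
  expect_equal(nrow(td), 3L)
})

test_that("bootstrap support is seeded, reproducible and finds true splits", {
  # two 4-taxon clades separated by deep divergence, shallow within
  anc <- random_seq(800, seed = 71)
  cl1 <- flat_mutate(anc, 0.10, seed = 72)
  cl2 <- flat_mutate(anc, 0.10, seed = 73)
  seqs <- c(
    a1 = flat_mutate(cl1, 0.01, seed = 74),
    a2 = flat_mutate(cl1, 0.01, seed = 75),
    a3 = flat_mutate(cl1, 0.01, seed = 76),
    a4 = flat_mutate(cl1, 0.01, seed = 77),
    b1 = flat_mutate(cl2, 0.01, seed = 78),
    b2 = flat_mutate(cl2, 0.01, seed = 79),
    b3 = flat_mutate(cl2, 0.01, seed = 80),
    b4 = flat_mutate(cl2, 0.01, seed = 81))
  aln <- as_alignment(seqs)
  bs <- bootstrap_support(aln, reps = 100, seed = 9)
  bs2 <- bootstrap_support(aln, reps = 100, seed = 9)
  expect_identical(bs$support, bs2$support)
  # the a|b split must be strongly supported
  tr <- bs$tree
  node <- ape::getMRCA(tr, c("a1", "a2", "a3", "a4"))
  sup <- bs$support[node - length(tr$tip.label)]
  expect_gte(sup, 95)
})

test_that("dot-plot highlights diagonals and stays dark on noise", {
  s <- random_seq(2000, seed = 91)
  dp <- dotplot(s, s, window = 100, step = 25)
  diag_cells <- dp$grid[dp$grid$apos0 == dp$grid$bpos0, ]
  expect_true(all(diag_cells$highlight))
  expect_true(all(diag_cells$identity == 1))

  a <- random_seq(2600, seed = 92)
  b <- random_seq(2600, seed = 93)
  dpn <- dotplot(a, b, window = 100, step = 25)
  expect_gte(nrow(dpn$grid), 1e4)
  expect_equal(sum(dpn$grid$highlight), 0L)

  # an internal deletion shifts the diagonal by its length
  big <- random_seq(6000, seed = 94)
  del <- paste0(substr(big, 1, 2000), substring(big, 4001))
  dpd <- dotplot(big, del, window = 100, step = 25)
  hi <- dpd$grid[dpd$grid$highlight, ]
  expect_true(any(hi$apos0 == hi$bpos0 & hi$apos0 < 1900))
  expect_true(any(hi$apos0 == hi$bpos0 + 2000 & hi$apos0 > 4100))
  expect_false(any(hi$apos0 > 2100 & hi$apos0 < 3900))

  # reverse-complement matches appear in minus-strand mode
  dpr <- dotplot(s, ervography:::revcomp(s), window = 100, step = 25,
                 both_strands = TRUE)
  plus_only <- dpr$grid[dpr$grid$strand == "+", ]
  minus <- dpr$grid[dpr$grid$strand == "-", ]
  expect_equal(sum(plus_only$highlight), 0L)
  expect_gt(sum(minus$highlight), 50)

  expect_error(dotplot("ACGT", s, window = 100), "window")
})

test_that("dot-plot objects tidy and plot", {
  s <- random_seq(500, seed = 95)
  dp <- dotplot(s, s, window = 100, step = 50)
  expect_s3_class(tidy(dp), "tbl_df")
  p <- autoplot(dp)
  expect_s3_class(p, "ggplot")
})
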