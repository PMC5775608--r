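# Shared fixtures: a miniature ERV model (short segments, same layout as the
# default) and a small configuration keep per-test simulations fast while
# exercising every code path. Heavier simulations are cached across test
# files within one run.

mini_model <- function(seed = 7) {
  erv_model(
    ltr_len = 120L, u3_len = 70L, r_len = 20L, u5_len = 30L,
    internal_segments = c(pre_gag = 150L, gag = 150L, pol = 201L,
                          env = 99L),
    seed = seed
  )
}

mini_config <- function(...) {
  pipeline_config(flank_len = 300L, merge_gap = 500L,
                  flank_min_match = 200L, ltr_min_align = 80L,
                  internal_min_cov = 100L, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

mini_sim <- function() {
  cached("mini_sim", {
    tr <- default_catarrhini_tree()
    simulate_erv_history(tr, mini_model(),
                         default_insertion_rates(tr, 20), mini_config(),
                         bg_len = 4e5, n_recomb = 2, seed = 11)
  })
}

mini_pipeline <- function() {
  cached("mini_pipeline", {
    sim <- mini_sim()
    suppressWarnings(run_erv_pipeline(sim$genomes, sim$tree, sim$model,
                                      sim$config, seed = 5,
                                      comparative = FALSE))
  })
}

# mutate a sequence with a fixed per-site substitution probability and no
# transition bias — an independent, simple mutator used as a test oracle
# where exact divergence control matters
flat_mutate <- function(seq, p, seed = NULL) {
  ervography:::with_seed(seed, {
    v <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(v)) < p & v %in% c("A", "C", "G", "T"))
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  })
}

random_seq <- function(n, seed = NULL) {
  ervography:::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}
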