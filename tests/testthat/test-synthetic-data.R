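test_that("the generator is deterministic under its seed", {
  s1 <- simulate_aflp(paper_like_config(seed = 5))
  s2 <- simulate_aflp(paper_like_config(seed = 5))
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_aflp(paper_like_config(seed = 6))
  expect_false(identical(s1$peaks, s3$peaks))
})

test_that("the noise-free limit gives identical replicates and idle filters", {
  sim <- simulate_aflp(noise_free_config(seed = 2))
  calls <- score_simulated(sim)
  expect_false(any(calls == "?"))
  er <- replicate_difference_rates(calls, sim$replicates)
  expect_true(all(er$rate == 0))
  filt <- error_filter(calls, sim$replicates)
  expect_length(filt$trace$step1_removed, 0)
  expect_length(filt$trace$step2_removed, 0)
  expect_equal(ncol(filt$calls), ncol(calls))
  # replicate rows are exact copies
  groups <- split(sim$replicates$sample, sim$replicates$group)
  for (g in groups) {
    expect_identical(unname(unclass(calls)[g[1], ]),
                     unname(unclass(calls)[g[2], ]))
  }
})

test_that("scoreable bin counts track the fragment pool size", {
  sim <- simulate_aflp(paper_like_config(seed = 8))
  binned <- bin_channels(filter_raw_peaks(sim$peaks),
                         samples = sim$replicates$sample)
  for (bm in binned) {
    expect_gt(ncol(bm), 0.8 * 500)
    expect_lt(ncol(bm), 1.2 * 500)
  }
})

test_that("replicate discordance grows with size jitter", {
  rate_at <- function(sj) {
    cfg <- paper_like_config()
    cfg$size_jitter_sd <- sj
    rates <- c()
    for (s in 1:4) {
      cfg$seed <- 300 + s
      sim <- simulate_aflp(cfg)
      er <- replicate_difference_rates(score_simulated(sim), sim$replicates)
      rates <- c(rates, er$rate)
    }
    mean(rates)
  }
  r <- vapply(c(0.02, 0.07, 0.2), rate_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("the Monte-Carlo difference-rate oracle is consistent", {
  cfg <- noise_free_config(seed = 1)
  res0 <- expected_replicate_difference(cfg, n_mc = 100, seed = 2)
  expect_equal(res0$rate, 0)

  small <- aflp_sim_config(samples_per_cluster = 2, fragment_pool_size = 120,
                           size_jitter_sd = 0.07, seed = 1)
  ra <- expected_replicate_difference(small, n_mc = 100, seed = 3)
  rb <- expected_replicate_difference(small, n_mc = 300, seed = 4)
  expect_lt(abs(ra$rate - rb$rate), 3 * sqrt(ra$se^2 + rb$se^2))
  expect_warning(expected_replicate_difference(small, n_mc = 50, seed = 5),
                 "n_mc")
})

test_that("a dense fragment pool is rejected as infeasible", {
  cfg <- aflp_sim_config(fragment_pool_size = 700)
  expect_error(simulate_aflp(cfg), "spacing")
})

test_that("sequence simulation honours its degenerate limits and seed", {
  tr <- ape::rtree(6)
  tr0 <- tr
  tr0$edge.length <- rep(0, nrow(tr$edge))
  sim0 <- simulate_alignment(tr0, 100, indel_rate = 0.05, seed = 3)
  expect_equal(length(unique(apply(sim0$alignment, 1, paste, collapse = ""))),
               1)

  simg <- simulate_alignment(tr, 200, indel_rate = 0, seed = 3)
  expect_false(any(simg$alignment == "-"))
  expect_identical(unclass(simulate_alignment(tr, 200, seed = 9)$alignment),
                   unclass(simulate_alignment(tr, 200, seed = 9)$alignment))
  expect_error(simulate_alignment(tr, 0), "length")
})

test_that("between-cluster distances exceed within-cluster distances", {
  sim <- simulate_aflp(paper_like_config(seed = 41))
  calls <- score_simulated(sim)
  filt <- error_filter(calls, sim$replicates)
  pd <- p_distance_matrix(filt$calls)
  cl <- sim$truth$cluster[sub("_r[0-9]+$", "", pd$labels)]
  same <- outer(cl, cl, "==") & upper.tri(pd$d)
  diff <- outer(cl, cl, "!=") & upper.tri(pd$d)
  expect_gt(mean(pd$d[diff]), mean(pd$d[same]))
})

test_that("simulated datasets serialise to the canonical CSV + JSON layout", {
  sim <- simulate_aflp(aflp_sim_config(samples_per_cluster = 2,
                                       fragment_pool_size = 80, seed = 3))
  dir <- tempfile()
  write_simulated(sim, dir)
  expect_true(file.exists(file.path(dir, "peaks.csv")))
  pt <- read_peak_table(file.path(dir, "peaks.csv"))
  expect_equal(nrow(pt), nrow(sim$peaks))
  rm <- read_replicate_map(file.path(dir, "replicates.csv"))
  expect_equal(as.data.frame(rm), as.data.frame(sim$replicates))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$cluster), length(sim$truth$cluster))
})
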