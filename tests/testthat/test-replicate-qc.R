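test_that("replicate difference rates use pairwise-complete comparison", {
  cm <- cm_from_profiles(c(a1 = "0011", a2 = "0011",
                           b1 = "0?11", b2 = "0011",
                           c1 = "0101", c2 = "0011"))
  reps <- replicate_map(rownames(cm), rep(c("a", "b", "c"), each = 2))
  er <- replicate_difference_rates(cm, reps)
  rates <- setNames(er$rate, er$group)
  expect_equal(rates[["a"]], 0)
  expect_equal(rates[["b"]], 0)            # ? excluded pairwise
  expect_equal(er$comparable[er$group == "b"], 3)
  expect_equal(rates[["c"]], 0.5)          # 2 mismatches / 4 comparable
  expect_equal(attr(er, "range"), c(0, 0.5))

  single <- replicate_map(c("a1", "a2", "b1"), c("a", "a", "b"))
  expect_warning(replicate_difference_rates(cm[1:3, ], single), "single")

  allq <- cm_from_profiles(c(x1 = "??", x2 = "01"))
  er2 <- suppressWarnings(
    replicate_difference_rates(allq, replicate_map(c("x1", "x2"), c("x", "x"))))
  expect_true(is.na(er2$rate))
})

test_that("step 1 removes exactly the bins containing ambiguous calls", {
  cm <- cm_from_profiles(c(a = "01?10", b = "1100?"))
  s1 <- drop_ambiguous_bins(cm)
  expect_equal(ncol(s1$calls), 3)
  expect_false(any(s1$calls == "?"))
  expect_setequal(s1$trace$step1_removed, colnames(cm)[c(3, 5)])

  clean <- cm_from_profiles(c(a = "010", b = "101"))
  expect_identical(unclass(drop_ambiguous_bins(clean)$calls)[, ],
                   unclass(clean)[, ])

  allq <- cm_from_profiles(c(a = "??", b = "1?"))
  s <- drop_ambiguous_bins(allq)
  expect_equal(ncol(s$calls), 0)
  expect_equal(nrow(s$calls), 2)
})

test_that("step 2 removes bins discordant within any replicate group", {
  # 2 groups x 2 replicates, 6 bins; bins 1-2 discordant in group a,
  # bin 4 discordant in group b (disjoint) -> 3 bins survive
  cm <- cm_from_profiles(c(a1 = "100110", a2 = "010110",
                           b1 = "110101", b2 = "110001"))
  reps <- replicate_map(rownames(cm), rep(c("a", "b"), each = 2))
  s2 <- drop_irreproducible_bins(cm, reps)
  expect_equal(ncol(s2$calls), 3)
  expect_setequal(s2$trace$step2_removed, colnames(cm)[c(1, 2, 4)])
  # all groups now concordant
  er <- replicate_difference_rates(s2$calls, reps)
  expect_true(all(er$rate == 0))

  dirty <- cm_from_profiles(c(a1 = "0?", a2 = "01"))
  expect_error(drop_irreproducible_bins(dirty,
                                        replicate_map(c("a1", "a2"),
                                                      c("a", "a"))),
               "ambiguous")
})

test_that("the two-step filter leaves replicate pairs identical", {
  set.seed(3)
  sim <- simulate_aflp(paper_like_config(seed = 17))
  calls <- score_simulated(sim)
  filt <- error_filter(calls, sim$replicates)
  expect_false(any(filt$calls == "?"))
  er <- replicate_difference_rates(filt$calls, sim$replicates)
  expect_true(all(er$rate == 0))
  # the trace partitions the input bins and fixes the step order
  expect_setequal(c(filt$trace$step1_removed, filt$trace$step2_removed,
                    filt$trace$retained), colnames(calls))
  expect_length(intersect(filt$trace$step1_removed,
                          filt$trace$retained), 0)
  # step 1 runs first: every bin it removed contains a ?
  has_q <- colnames(calls)[apply(unclass(calls) == "?", 2, any)]
  expect_setequal(filt$trace$step1_removed, has_q)
  expect_length(intersect(filt$trace$step2_removed, has_q), 0)
})

test_that("retained bins are invariant under sample and bin reordering", {
  sim <- simulate_aflp(paper_like_config(seed = 23))
  calls <- score_simulated(sim)
  filt <- error_filter(calls, sim$replicates)
  perm_rows <- sample(nrow(calls))
  perm_cols <- sample(ncol(calls))
  shuffled <- aflpdelimit:::new_call_matrix(
    unclass(calls)[perm_rows, perm_cols],
    channel = attr(calls, "channel")[perm_cols])
  filt2 <- error_filter(shuffled, sim$replicates)
  expect_setequal(filt2$trace$retained, filt$trace$retained)
})

test_that("replicate collapse requires concordant groups", {
  cm <- cm_from_profiles(c(a1 = "0110", a2 = "0110",
                           b1 = "1001", b2 = "1001"))
  reps <- replicate_map(rownames(cm), rep(c("a", "b"), each = 2))
  col <- collapse_replicates(cm, reps)
  expect_equal(rownames(col), c("a", "b"))
  expect_equal(unname(unclass(col)["a", ]), c("0", "1", "1", "0"))

  singles <- replicate_map(c("a1", "b1"), c("ga", "gb"))
  expect_equal(nrow(collapse_replicates(cm[c(1, 3), ], singles)), 2)

  disc <- cm_from_profiles(c(a1 = "01", a2 = "00"))
  expect_error(collapse_replicates(disc, replicate_map(c("a1", "a2"),
                                                       c("a", "a"))),
               "discordant")
})

test_that("replicate maps round-trip through CSV with levels", {
  reps <- replicate_map(c("x1", "x2", "y1"), c("x", "x", "y"),
                        c("extraction", "extraction", "preamp"))
  p <- tempfile(fileext = ".csv")
  write_replicate_map(reps, p)
  back <- read_replicate_map(p)
  expect_equal(as.data.frame(back), as.data.frame(reps))
})
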