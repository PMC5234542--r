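test_that("p-distances count strict disagreements over comparable bins", {
  cm <- cm_from_profiles(c(a = "0101", b = "0101", c = "1010"))
  pd <- p_distance_matrix(cm)
  expect_equal(pd$d["a", "b"], 0)
  expect_equal(pd$d["a", "c"], 1)
  expect_equal(pd$d, t(pd$d))
  expect_true(all(diag(pd$d) == 0))

  cm2 <- cm_from_profiles(c(a = "01?10", b = "11010"))
  pd2 <- p_distance_matrix(cm2)
  expect_equal(pd2$d["a", "b"], 0.25)          # 1 mismatch / 4 comparable
  expect_equal(pd2$comparable["a", "b"], 4)

  cm3 <- cm_from_profiles(c(a = "??10", b = "01??"))
  expect_error(p_distance_matrix(cm3), "a / b|comparable")
})

test_that("p-distance equals normalised Hamming distance when no ? present", {
  set.seed(5)
  m <- matrix(sample(c("0", "1"), 6 * 40, replace = TRUE), 6, 40,
              dimnames = list(letters[1:6], sprintf("b%d", 1:40)))
  pd <- p_distance_matrix(aflpdelimit:::new_call_matrix(m))
  ham <- as.matrix(dist(matrix(as.numeric(m), 6), method = "manhattan")) / 40
  expect_equal(unname(pd$d), unname(ham))
  expect_true(all(pd$comparable == 40))
})

test_that("group extraction cuts single-linkage trees deterministically", {
  # two tight clusters far apart
  cm <- cm_from_profiles(c(a1 = "000000001", a2 = "000000000",
                           b1 = "111111110", b2 = "111111111"))
  pd <- p_distance_matrix(cm)
  g2 <- extract_groups(pd, k = 2)
  expect_equal(unname(g2[c("a1", "a2")]), rep(g2[["a1"]], 2))
  expect_equal(unname(g2[c("b1", "b2")]), rep(g2[["b1"]], 2))
  expect_false(g2[["a1"]] == g2[["b1"]])

  gn <- extract_groups(pd, k = 4)
  expect_equal(length(unique(gn)), 4)
  expect_error(extract_groups(pd, k = 5), "exceeds")
  gt <- extract_groups(pd, threshold = 0.5)
  expect_equal(length(unique(gt)), 2)
  expect_error(extract_groups(pd), "exactly one")
})

test_that("NeighborNet ordering respects quartet and triplet structure", {
  # quartet tree ((A,B),(C,D)): AB and CD must be contiguous in the cycle
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d <- ape::cophenetic.phylo(tr)
  ord <- neighbor_net_ordering(d)
  labs <- attr(ord, "labels")[ord]
  pos <- function(x) which(labs == x)
  circ_adjacent <- function(x, y) {
    dd <- abs(pos(x) - pos(y))
    min(dd, 4 - dd) == 1
  }
  expect_true(circ_adjacent("A", "B"))
  expect_true(circ_adjacent("C", "D"))

  d3 <- matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(as.integer(neighbor_net_ordering(d3)), 1:3)

  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(neighbor_net_ordering(asym), "symmetric")
})

test_that("split weights reproduce tree metrics and known circular systems", {
  set.seed(21)
  for (rep in 1:5) {
    tr <- ape::unroot(ape::rtree(6))
    d <- ape::cophenetic.phylo(tr)
    ss <- neighbor_net(d)
    n <- 6
    nontrivial <- lengths(ss$splits) >= 2 & lengths(ss$splits) <= n - 2
    expect_identical(split_keyset(ss$splits[nontrivial], n),
                     tree_splitset(tr, rownames(d)))
    expect_true(all(ss$weights >= 0))
    expect_gt(ss$fit, 99.999)
  }
  rc <- random_circular_splits(7, 10, seed = 3)
  ss <- neighbor_net(rc$d)
  expect_identical(split_keyset(ss$splits, 7), split_keyset(rc$splits, 7))
  k_true <- vapply(rc$splits, canon_split, character(1), n = 7)
  k_got <- vapply(ss$splits, canon_split, character(1), n = 7)
  expect_equal(ss$weights[order(k_got)], rc$weights[order(k_true)],
               tolerance = 1e-9)

  zero <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_length(neighbor_net(zero)$splits, 0)
})

test_that("the split network agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  sim <- simulate_aflp(paper_like_config(seed = 31))
  calls <- score_simulated(sim)
  filt <- error_filter(calls, sim$replicates)
  pd <- p_distance_matrix(filt$calls)
  ss <- neighbor_net(pd)
  nn <- phangorn::neighborNet(pd$d)
  spl <- nn$splits
  labs <- attr(spl, "labels")
  n <- length(pd$labels)
  to_key <- function(s) canon_split(match(labs[s], pd$labels), n)
  ph_keys <- vapply(seq_along(spl), function(i) to_key(spl[[i]]), character(1))
  ph_w <- attr(spl, "weights")
  mine <- setNames(ss$weights, vapply(ss$splits, canon_split, character(1),
                                      n = n))
  # the three cluster bipartitions must carry matching weight in both systems
  cl <- sim$truth$cluster[sub("_r[0-9]+$", "", pd$labels)]
  for (k in 1:3) {
    key <- canon_split(which(cl == k), n)
    w_mine <- sum(mine[names(mine) == key])
    w_ph <- sum(ph_w[ph_keys == key])
    expect_gt(w_mine, 0.05)
    expect_equal(w_mine, w_ph, tolerance = 0.05)
  }
})

test_that("distance and splits serialisations round-trip / are well formed", {
  cm <- cm_from_profiles(c(a = "010110", b = "010101", c = "111000",
                           d = "001101"))
  pd <- p_distance_matrix(cm)
  p <- tempfile(fileext = ".phy")
  write_phylip_dist(pd, p)
  back <- read_phylip_dist(p)
  expect_equal(back, pd$d, tolerance = 1e-7)

  nx <- tempfile(fileext = ".nex")
  ss <- neighbor_net(pd)
  write_splits_nexus(ss, nx)
  lines <- readLines(nx)
  expect_true(any(grepl("^CYCLE", lines)))
  expect_equal(sum(grepl("^\\[\\d+, size=", lines)), length(ss$splits))

  nd <- tempfile(fileext = ".nex")
  write_nexus_dist(pd, nd)
  expect_true(any(grepl("BEGIN DISTANCES", readLines(nd))))
})
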