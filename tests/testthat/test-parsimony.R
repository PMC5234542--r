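quartet <- ape::read.tree(text = "((A1,A2),(G1,G2));")

test_that("Fitch length reproduces textbook cases", {
  m <- matrix("A", 4, 3, dimnames = list(c("A1", "A2", "G1", "G2"), NULL))
  expect_equal(fitch_length(quartet, m), 0)

  m1 <- cbind(c(A1 = "A", A2 = "A", G1 = "G", G2 = "G"))
  expect_equal(fitch_length(quartet, m1), 1)
  crossed <- ape::read.tree(text = "((A1,G1),(A2,G2));")
  expect_equal(fitch_length(crossed, m1), 2)

  # missing data and ambiguity codes cost nothing extra when uninformative
  m2 <- cbind(c(A1 = "A", A2 = "?", G1 = "G", G2 = "R"))
  expect_equal(fitch_length(quartet, m2), 1)

  expect_error(fitch_length(quartet, cbind(c(x = "A", y = "A", z = "G",
                                             w = "G"))), "match")
})

test_that("Fitch length matches brute-force enumeration on random matrices", {
  set.seed(101)
  for (rep in 1:20) {
    ntax <- sample(4:6, 1)
    m <- random_dna_matrix(ntax, 8, missing_prob = 0.1)
    tr <- ape::unroot(ape::rtree(ntax, tip.label = rownames(m)))
    expect_equal(fitch_length(tr, m), brute_force_length(tr, m))
  }
})

test_that("Fitch length is invariant under consistent relabeling", {
  set.seed(7)
  m <- random_dna_matrix(6, 15)
  tr <- ape::unroot(ape::rtree(6, tip.label = rownames(m)))
  perm <- sample(rownames(m))
  tr2 <- tr
  tr2$tip.label <- perm[match(tr$tip.label, rownames(m))]
  m2 <- m
  rownames(m2) <- perm
  expect_equal(fitch_length(tr, m), fitch_length(tr2, m2))
})

test_that("exact search finds all and only the global optima", {
  # single informative column pairs the As against the Gs
  m1 <- cbind(c(A1 = "A", A2 = "A", G1 = "G", G2 = "G"))
  ts <- search_mp_trees(m1, "exact", collapse = FALSE)
  expect_equal(ts$length, 1)
  key <- aflpdelimit:::.phylo_split_keys(ts$trees[[1]], rownames(m1))
  expect_equal(key, "3,4")   # G1,G2 against A1,A2

  # no informative columns: every topology ties and the consensus is a star
  m0 <- matrix("A", 5, 4, dimnames = list(paste0("t", 1:5), NULL))
  m0[1, 1] <- "C"
  ts0 <- search_mp_trees(m0, "exact", collapse = FALSE)
  expect_equal(ts0$n_trees, 15)          # all unrooted 5-taxon topologies
  expect_equal(ts0$consensus$Nnode, 1)   # star

  # global optimality vs exhaustive enumeration by an independent package
  skip_if_not_installed("phangorn")
  set.seed(55)
  for (rep in 1:5) {
    m <- random_dna_matrix(6, 12)
    ts <- search_mp_trees(m, "exact", collapse = FALSE)
    pd <- phangorn::phyDat(m, type = "DNA")
    all_len <- vapply(phangorn::allTrees(6, tip.label = rownames(m)),
                      function(tr) phangorn::fitch(tr, pd), numeric(1))
    expect_equal(ts$length, min(all_len))
    expect_equal(ts$n_trees, sum(all_len == min(all_len)))
  }
  expect_error(search_mp_trees(random_dna_matrix(15, 4), "exact"),
               "infeasible")
})

test_that("heuristic search reaches the exact optimum almost always", {
  set.seed(77)
  hits <- 0
  runs <- 20
  for (rep in seq_len(runs)) {
    m <- random_dna_matrix(7, 15)
    exact <- search_mp_trees(m, "exact", collapse = FALSE)
    heur <- search_mp_trees(m, "heuristic", seed = rep, nstarts = 10,
                            collapse = FALSE)
    expect_gte(heur$length, exact$length)
    if (heur$length == exact$length) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.95)
})

test_that("zero-minimum-length branches are collapsed in reported trees", {
  # only one informative grouping; the other internal branch has min length 0
  m <- cbind(c(a = "A", b = "A", c = "G", d = "G", e = "G"))
  ts <- search_mp_trees(m, "exact", collapse = TRUE)
  expect_equal(ts$length, 1)
  # every reported tree keeps the a|b split but no resolution within c,d,e
  for (tr in ts$trees) {
    keys <- aflpdelimit:::.phylo_split_keys(tr, letters[1:5])
    expect_equal(keys, "3,4,5")
  }
  expect_equal(ts$n_trees, 1)
})

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  t2 <- ape::read.tree(text = "((a,b),((c,d),e));")
  cons <- strict_consensus(c(t1, t2))
  keys <- aflpdelimit:::.phylo_split_keys(ape::unroot(cons), letters[1:5])
  expect_equal(keys, "3,4,5")
})

test_that("bootstrap gives full support to a decisive split and is seeded", {
  m <- matrix(rep(c("A", "A", "G", "G"), 50), 4,
              dimnames = list(c("A1", "A2", "G1", "G2"), NULL))
  bs <- bootstrap_support(m, replicates = 30, seed = 4)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$support, 100)
  expect_equal(bs$split, "G1|G2")

  bs2 <- bootstrap_support(m, replicates = 30, seed = 4)
  expect_identical(as.data.frame(bs), as.data.frame(bs2))
  expect_error(bootstrap_support(m, replicates = 0), "replicates")
})

test_that("bootstrap recovers strongly supported true clades", {
  set.seed(31)
  tr <- ape::unroot(ape::rtree(8))
  tr$edge.length <- runif(nrow(tr$edge), 0.08, 0.25)
  sim <- simulate_alignment(tr, 600, seed = 12)
  bs <- bootstrap_support(unclass(sim$alignment), replicates = 60, seed = 9)
  ref <- attr(bs, "reference")
  true_keys <- aflpdelimit:::.phylo_split_keys(tr, tr$tip.label)
  ref_keys <- aflpdelimit:::.phylo_split_keys(ref, tr$tip.label)
  expect_setequal(ref_keys, true_keys)        # reference recovers the truth
  expect_true(all(bs$support >= 90))
})
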