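# shared fixture builders and independent oracles

# call matrix straight from a character vector of profiles like "01?1"
cm_from_profiles <- function(profiles, samples = names(profiles),
                             bins = NULL) {
  m <- do.call(rbind, strsplit(profiles, ""))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(bins)) bins <- sprintf("ch1:%0.1f", 100 + 0.5 * seq_len(ncol(m)))
  dimnames(m) <- list(samples, bins)
  aflpdelimit:::new_call_matrix(m)
}

# binned matrix from a plain numeric matrix
bm_from_matrix <- function(m, channel = "ch1") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("%.1f", 100 + 0.5 * (seq_len(ncol(m)) - 1))
  }
  structure(m, channel = channel,
            bin_left = as.numeric(colnames(m)),
            config = binning_config(),
            class = c("binned_matrix", "matrix", "array"))
}

write_peak_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# canonical bipartition key: the side not containing taxon 1
canon_split <- function(side, n) {
  side <- sort(side)
  if (1 %in% side) side <- sort(setdiff(seq_len(n), side))
  paste(side, collapse = ",")
}

split_keyset <- function(splits, n) {
  sort(vapply(splits, canon_split, character(1), n = n))
}

# nontrivial splits (and branch lengths) of an ape tree, keyed canonically
# against a fixed label order -- the independent reading of a tree's splits
tree_splitset <- function(tree, labels) {
  n <- length(labels)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (k in seq_along(pp)) {
    side <- sort(match(attr(pp, "labels")[pp[[k]]], labels))
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, canon_split(side, n))
    }
  }
  sort(out)
}

# brute-force small parsimony: minimise changes over every assignment of
# A/C/G/T (or 0/1) states to internal nodes; the slow independent oracle
brute_force_length <- function(tree, m) {
  states_of <- function(col, j) unique(col)
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  E <- tree$edge
  total <- 0
  alphabet <- c("A", "C", "G", "T", "0", "1")
  for (j in seq_len(ncol(m))) {
    col <- m[tree$tip.label, j]
    obs <- intersect(alphabet, col)
    if (length(obs) == 0) next
    cand <- obs  # a minimal assignment never needs unobserved states
    grids <- rep(list(cand), nnode)
    combos <- expand.grid(grids, stringsAsFactors = FALSE)
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      assign_int <- unlist(combos[r, ])
      state <- c(col, assign_int)
      changes <- 0
      for (e in seq_len(nrow(E))) {
        a <- state[E[e, 1]]; b <- state[E[e, 2]]
        if (a %in% alphabet && b %in% alphabet && a != b) {
          changes <- changes + 1
        } else if (!(a %in% alphabet) || !(b %in% alphabet)) {
          # missing tips: cost 0 regardless (can match parent)
          changes <- changes + 0
        }
      }
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# brute-force recount of variable / parsimony-informative columns
brute_force_counts <- function(m, source = NULL) {
  if (is.null(source)) source <- rep("sequence", ncol(m))
  det <- function(col, src) {
    keep <- if (src == "indel") col %in% c("0", "1")
            else col %in% c("A", "C", "G", "T")
    col[keep]
  }
  variable <- informative <- 0
  for (j in seq_len(ncol(m))) {
    tab <- table(det(m[, j], source[j]))
    if (length(tab) >= 2) {
      variable <- variable + 1
      if (sum(tab >= 2) >= 2) informative <- informative + 1
    }
  }
  list(variable = variable, informative = informative)
}

random_dna_matrix <- function(ntaxa, ncols, missing_prob = 0) {
  m <- matrix(sample(c("A", "C", "G", "T"), ntaxa * ncols, replace = TRUE),
              ntaxa, ncols, dimnames = list(sprintf("t%d", seq_len(ntaxa)),
                                            NULL))
  if (missing_prob > 0) {
    m[matrix(runif(length(m)) < missing_prob, nrow(m))] <- "?"
  }
  m
}
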