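#' Simulate a sequence alignment on a known tree
#'
#' Evolves sites along a rooted binary tree with branch lengths under an
#' equal-rates (Jukes--Cantor) substitution process, then overlays
#' geometric-length deletion events at rate `indel_rate` per site per unit
#' branch length. Deletions mark gap columns in the descendant lineage, so
#' the emitted matrix stays column-aligned to the ancestral coordinate
#' system and shared indels reflect shared history. Deterministic under
#' `seed`.
#'
#' @param tree A `phylo` with positive branch lengths (rooted or unrooted;
#'   unrooted trees are rooted at an internal node for the walk).
#' @param length Number of alignment columns (>= 1).
#' @param indel_rate Deletion events per site per unit branch length.
#' @param mean_indel_length Mean of the geometric indel-length law.
#' @param seed Integer seed.
#' @return A list with `alignment` (an `alignment` matrix) and `tree` (the
#'   generating tree).
#' @export
simulate_alignment <- function(tree, length = 500L, indel_rate = 0,
                               mean_indel_length = 3, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (length < 1) stop("alignment length must be >= 1")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths")
  }
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  bases <- c("A", "C", "G", "T")
  ntip <- base::length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  seqs <- matrix(NA_character_, nnode, length)
  gaps <- matrix(FALSE, nnode, length)
  seqs[root, ] <- sample(bases, length, replace = TRUE)
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    t <- tree$edge.length[k]
    s <- seqs[par, ]
    # equal-rates substitution: site changes with p = 3/4 (1 - e^{-4t/3})
    p <- 0.75 * (1 - exp(-4 * t / 3))
    mut <- stats::runif(length) < p
    if (any(mut)) {
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    }
    g <- gaps[par, ]
    if (indel_rate > 0 && t > 0) {
      n_events <- stats::rpois(1, indel_rate * length * t)
      for (e in seq_len(n_events)) {
        start <- sample.int(length, 1)
        len <- 1L + stats::rgeom(1, 1 / mean_indel_length)
        g[start:min(length, start + len - 1L)] <- TRUE
      }
    }
    seqs[child, ] <- s
    gaps[child, ] <- g
  }
  out <- seqs[seq_len(ntip), , drop = FALSE]
  out[gaps[seq_len(ntip), , drop = FALSE]] <- "-"
  rownames(out) <- tree$tip.label
  list(alignment = new_alignment(out), tree = tree)
}

#' Random circular split system (for forward-construction checks)
#'
#' Draws a random circular taxon ordering and a random subset of its interval
#' splits with positive weights, and returns both the system and the exact
#' distance matrix it induces. Useful as ground truth for split-weight
#' recovery: the induced distances identify the weighted splits exactly.
#'
#' @param n Number of taxa.
#' @param n_splits Number of weighted splits to draw (capped at
#'   n(n-1)/2).
#' @param seed Integer seed.
#' @return A list with `labels`, `order`, `splits`, `weights`, and `d` (the
#'   induced distance matrix).
#' @export
random_circular_splits <- function(n, n_splits = n, seed = 1L) {
  set.seed(seed)
  labels <- sprintf("t%02d", seq_len(n))
  ord <- sample.int(n)
  all_splits <- .interval_splits(ord)
  pick <- sort(sample.int(base::length(all_splits),
                          min(n_splits, base::length(all_splits))))
  splits <- all_splits[pick]
  weights <- stats::runif(base::length(splits), 0.1, 1)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (s in seq_along(splits)) {
    inside <- logical(n)
    inside[splits[[s]]] <- TRUE
    sep <- outer(inside, inside, "!=")
    d <- d + weights[s] * sep
  }
  list(labels = labels, order = ord, splits = splits, weights = weights,
       d = d)
}
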