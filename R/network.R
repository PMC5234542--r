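#' p-distances between three-state AFLP profiles
#'
#' Proportion of comparable bins at which two profiles disagree (one scored
#' absent, the other present). Ambiguous calls are removed pairwise: a bin
#' enters a pair's denominator only when both calls are determinate.
#'
#' @param calls A `call_matrix` with at least 2 samples and 1 bin.
#' @return A `p_distance` object: list with `d` (symmetric matrix in [0,1]),
#'   `comparable` (pairwise-complete bin counts) and `labels`.
#' @export
p_distance_matrix <- function(calls) {
  stopifnot(inherits(calls, "call_matrix") || is.matrix(calls))
  m <- unclass(calls)
  stopifnot(nrow(m) >= 2, ncol(m) >= 1)
  P <- (m == "1") + 0
  A <- (m == "0") + 0
  K <- P + A                       # 1 where determinate
  mismatch <- P %*% t(A) + A %*% t(P)
  comparable <- K %*% t(K)
  off <- comparable[upper.tri(comparable)]
  if (any(off == 0)) {
    ij <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)[1, ]
    stop("no comparable bins for pair ", rownames(m)[ij[1]], " / ",
         rownames(m)[ij[2]])
  }
  d <- mismatch / comparable
  diag(d) <- 0
  dimnames(d) <- dimnames(comparable) <- list(rownames(m), rownames(m))
  structure(list(d = d, comparable = comparable, labels = rownames(m)),
            class = "p_distance")
}

#' @export
print.p_distance <- function(x, ...) {
  cat(sprintf("p-distance matrix: %d taxa, distances %.4f - %.4f\n",
              length(x$labels), min(x$d[upper.tri(x$d)]),
              max(x$d[upper.tri(x$d)])))
  invisible(x)
}

.as_dist_matrix <- function(d) {
  if (inherits(d, "p_distance")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(d < 0) || max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix must be symmetric and non-negative")
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  d
}

# replace the 3-node chain x - y - z by 2 nodes written into slots x and z;
# standard equal-weight linear reduction of the agglomerative network method
.nn_reduce <- function(dn, x, y, z) {
  u <- 2 / 3 * dn[x, ] + dn[y, ] / 3
  v <- 2 / 3 * dn[z, ] + dn[y, ] / 3
  uv <- (dn[x, y] + dn[x, z] + dn[y, z]) / 3
  dn[x, ] <- dn[, x] <- u
  dn[z, ] <- dn[, z] <- v
  dn[x, z] <- dn[z, x] <- uv
  dn[x, x] <- dn[z, z] <- 0
  dn[y, ] <- dn[, y] <- 0
  dn
}

# neighbour-joining style selection on a distance matrix: minimise
# D[i,j] - r[i] - r[j], deterministic first-minimum scan over i < j
.nj_pick <- function(D) {
  l <- nrow(D)
  if (l == 2L) return(c(1L, 2L))
  r <- rowSums(D) / (l - 2)
  Q <- D - outer(r, r, "+")
  best <- c(NA_integer_, NA_integer_)
  bestq <- Inf
  for (i in seq_len(l - 1L)) for (j in seq.int(i + 1L, l)) {
    if (Q[i, j] < bestq) {
      bestq <- Q[i, j]
      best <- c(i, j)
    }
  }
  best
}

#' NeighborNet circular ordering
#'
#' Computes the circular taxon ordering of the agglomerative NeighborNet
#' method: cluster pairs are chosen by the neighbour-joining adjusted-distance
#' criterion on cluster-averaged distances, the node pair linking them by the
#' same criterion with the two clusters expanded into their nodes, and chains
#' of three linked nodes are replaced by two via the equal-weight linear
#' distance reduction. Ties are broken by a deterministic first-minimum scan
#' over the cluster list in creation order, so orderings are reproducible.
#'
#' @param d A `p_distance`, `dist`, or symmetric numeric matrix.
#' @return Integer permutation of taxa (indices into the input labels); the
#'   labels are attached as the `"labels"` attribute.
#' @export
neighbor_net_ordering <- function(d) {
  dm <- .as_dist_matrix(d)
  labels <- rownames(dm)
  n <- nrow(dm)
  if (n <= 3L) return(structure(seq_len(n), labels = labels))
  dn <- unname(dm)
  # each cluster: chain of 1-2 active node ids plus its ordered taxa
  cl <- lapply(seq_len(n), function(i) list(nodes = i, taxa = i))
  ord <- NULL
  repeat {
    m <- length(cl)
    if (m == 1L) break
    DM <- matrix(0, m, m)
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      DM[i, j] <- DM[j, i] <- mean(dn[cl[[i]]$nodes, cl[[j]]$nodes])
    }
    e <- .nj_pick(DM)
    c1 <- cl[[e[1]]]; c2 <- cl[[e[2]]]
    n1 <- length(c1$nodes); n2 <- length(c2$nodes)
    if (n1 == 1L && n2 == 1L) {
      merged <- list(nodes = c(c1$nodes, c2$nodes), taxa = c(c1$taxa, c2$taxa))
    } else {
      # second selection: expand the two clusters into singleton nodes
      nodes <- c(c1$nodes, c2$nodes)
      others <- cl[-e]
      mtmp <- length(nodes) + length(others)
      r <- vapply(nodes, function(x) {
        s <- sum(dn[x, setdiff(nodes, x)])
        if (length(others)) {
          s <- s + sum(vapply(others, function(o) mean(dn[x, o$nodes]),
                              numeric(1)))
        }
        s
      }, numeric(1))
      if (mtmp > 2L) r <- r / (mtmp - 2)
      Q <- dn[nodes, nodes, drop = FALSE] - outer(r, r, "+")
      cross <- Q[seq_len(n1), n1 + seq_len(n2), drop = FALSE]
      pick <- which(cross == min(cross), arr.ind = TRUE)[1, ]
      i1 <- pick[[1]]; i2 <- pick[[2]]
      # orient both chains so the linked nodes are adjacent, then reduce
      # interior nodes until two endpoints remain
      ch1_nodes <- c1$nodes; ch1_taxa <- c1$taxa
      if (n1 == 2L && i1 == 1L) {
        ch1_nodes <- rev(ch1_nodes); ch1_taxa <- rev(ch1_taxa)
      }
      ch2_nodes <- c2$nodes; ch2_taxa <- c2$taxa
      if (n2 == 2L && i2 == 2L) {
        ch2_nodes <- rev(ch2_nodes); ch2_taxa <- rev(ch2_taxa)
      }
      chain <- c(ch1_nodes, ch2_nodes)
      while (length(chain) > 2L) {
        dn <- .nn_reduce(dn, chain[1], chain[2], chain[3])
        chain <- chain[-2]
      }
      merged <- list(nodes = chain, taxa = c(ch1_taxa, ch2_taxa))
    }
    cl[[e[1]]] <- merged
    cl <- cl[-e[2]]
    ord <- merged$taxa
  }
  structure(as.integer(ord), labels = labels)
}

# interval splits of a circular order: arcs of positions 1..n-1 (the side not
# containing the last position), one per (start, end) pair
.interval_splits <- function(order) {
  n <- length(order)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i, n - 1L)) {
    out[[length(out) + 1L]] <- sort(order[i:j])
  }
  out
}

# incidence of splits on taxon pairs: 1 where the split separates the pair
.split_design <- function(splits, n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), length(splits))
  for (s in seq_along(splits)) {
    inside <- logical(n)
    inside[splits[[s]]] <- TRUE
    A[, s] <- inside[pairs[, 1]] != inside[pairs[, 2]]
  }
  list(A = A, pairs = pairs)
}

#' Non-negative least-squares split weights
#'
#' Given a circular ordering, fits weights for all n(n-1)/2 interval splits
#' by least squares on the pairwise distances subject to non-negativity
#' (Lawson--Hanson active set). Splits with weight below `weight_epsilon`
#' (numerical zeros) are dropped.
#'
#' @param d A `p_distance`, `dist`, or symmetric matrix.
#' @param order Integer circular order (as from [neighbor_net_ordering()]);
#'   default recomputes it from `d`.
#' @param weight_epsilon Threshold below which fitted weights are discarded.
#' @return A `split_system`: list with `labels`, `order`, `splits` (list of
#'   integer taxon-index sets), `weights`, and `fit` (percent of squared
#'   distance explained).
#' @export
fit_split_weights <- function(d, order = neighbor_net_ordering(d),
                              weight_epsilon = 1e-9) {
  dm <- .as_dist_matrix(d)
  n <- nrow(dm)
  splits <- .interval_splits(order)
  des <- .split_design(splits, n)
  y <- dm[cbind(des$pairs[, 1], des$pairs[, 2])]
  if (all(y == 0)) {
    return(structure(list(labels = rownames(dm), order = as.integer(order),
                          splits = list(), weights = numeric(), fit = 100),
                     class = "split_system"))
  }
  sol <- pracma::lsqnonneg(des$A, y)
  w <- sol$x
  resid <- sum((des$A %*% w - y)^2)
  fit <- 100 * (1 - resid / sum(y^2))
  keep <- w >= weight_epsilon
  structure(list(labels = rownames(dm), order = as.integer(order),
                 splits = splits[keep], weights = w[keep], fit = fit),
            class = "split_system")
}

#' NeighborNet split network
#'
#' Convenience wrapper: circular ordering ([neighbor_net_ordering()]) plus
#' non-negative least-squares split weights ([fit_split_weights()]).
#'
#' @inheritParams fit_split_weights
#' @return A `split_system`.
#' @export
neighbor_net <- function(d, weight_epsilon = 1e-9) {
  fit_split_weights(d, neighbor_net_ordering(d), weight_epsilon)
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("Split system: %d taxa, %d weighted splits, fit %.2f%%\n",
              length(x$labels), length(x$splits), x$fit))
  invisible(x)
}

#' Delineate genotype groups from a distance matrix
#'
#' Single-linkage agglomeration cut either at a fixed number of groups `k`
#' or at a distance `threshold`. Single linkage respects the neighbourhood
#' structure a split network displays. Tie handling is deterministic:
#' taxa enter the agglomeration in label order.
#'
#' @param d A `p_distance`, `dist` or symmetric matrix.
#' @param k Number of groups (mutually exclusive with `threshold`).
#' @param threshold Cut height in distance units, in (0, 1).
#' @return A `group_assignment`: named integer vector (taxon -> group id)
#'   with a `"method"` attribute describing the cut.
#' @export
extract_groups <- function(d, k = NULL, threshold = NULL) {
  dm <- .as_dist_matrix(d)
  if (is.null(k) == is.null(threshold)) {
    stop("supply exactly one of 'k' or 'threshold'")
  }
  n <- nrow(dm)
  if (!is.null(k)) {
    stopifnot(k >= 1)
    if (k > n) stop("k = ", k, " exceeds the number of taxa (", n, ")")
  } else {
    stopifnot(threshold > 0, threshold < 1)
  }
  o <- order(rownames(dm))
  hc <- stats::hclust(stats::as.dist(dm[o, o]), method = "single")
  grp <- if (!is.null(k)) stats::cutree(hc, k = k)
         else stats::cutree(hc, h = threshold)
  grp <- grp[rownames(dm)]
  structure(grp,
            method = if (!is.null(k)) list(linkage = "single", k = k)
                     else list(linkage = "single", threshold = threshold),
            class = c("group_assignment", "integer"))
}

#' Write a split system as SplitsTree-compatible NEXUS
#'
#' Emits TAXA and SPLITS blocks with a CYCLE statement; each split line is
#' `id weight taxon-indices,` where the indices are the split side drawn
#' from the first taxon's side complement.
#'
#' @param ss A `split_system`.
#' @param path Output path.
#' @export
write_splits_nexus <- function(ss, path) {
  stopifnot(inherits(ss, "split_system"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(ss$labels)
  writeLines(c("#NEXUS", "", "BEGIN Taxa;",
               sprintf("DIMENSIONS ntax=%d;", n), "TAXLABELS"), con)
  writeLines(sprintf("[%d] '%s'", seq_len(n), ss$labels), con)
  writeLines(c(";", "END; [Taxa]", "", "BEGIN Splits;",
               sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, length(ss$splits)),
               "FORMAT labels=no weights=yes confidences=no intervals=no;",
               sprintf("PROPERTIES fit=%.2f;", ss$fit),
               paste0("CYCLE ", paste(ss$order, collapse = " "), ";"),
               "MATRIX"), con)
  for (s in seq_along(ss$splits)) {
    writeLines(sprintf("[%d, size=%d] \t%.10g \t %s,", s,
                       length(ss$splits[[s]]), ss$weights[s],
                       paste(ss$splits[[s]], collapse = " ")), con)
  }
  writeLines(c(";", "END; [Splits]"), con)
  invisible(path)
}

#' Distance matrix I/O
#'
#' `write_phylip_dist` / `read_phylip_dist` use the square PHYLIP format;
#' `write_nexus_dist` emits a NEXUS DISTANCES block.
#'
#' @param d A `p_distance` or symmetric matrix.
#' @param path File path.
#' @export
write_phylip_dist <- function(d, path) {
  dm <- .as_dist_matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(sprintf("%-10s", rownames(dm)[i]),
                       sprintf("%.8f", dm[i, ])), collapse = "  "), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  labels <- vapply(parts, `[`, character(1), 1)
  dm <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(dm) <- list(labels, labels)
  dm
}

#' @rdname write_phylip_dist
#' @export
write_nexus_dist <- function(d, path) {
  dm <- .as_dist_matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN DISTANCES;",
               sprintf("  DIMENSIONS ntax=%d;", nrow(dm)),
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
               "  MATRIX"), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste0("    ", sprintf("%-12s", rownames(dm)[i]),
                      paste(sprintf("%.8f", dm[i, ]), collapse = " ")), con)
  }
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
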