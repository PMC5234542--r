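# Internal tree representation for the searches: leaves 1..n, internal nodes
# n+1.., undirected edge matrix E (rows = edges). Conversion to ape "phylo"
# goes through Newick.

.encode_chars <- function(m) {
  src <- attr(m, "source")
  if (is.null(src)) src <- rep("sequence", ncol(m))
  mm <- unclass(m)
  code <- matrix(15L, nrow(mm), ncol(mm))
  for (j in seq_len(ncol(mm))) {
    col <- mm[, j]
    if (src[j] == "indel") {
      code[, j] <- ifelse(col == "0", 1L, ifelse(col == "1", 2L, 3L))
    } else {
      v <- IUPAC_BITS[col]
      v[is.na(v)] <- 15L
      code[, j] <- v
    }
  }
  # pattern compression: identical columns share one weighted pattern
  key <- apply(code, 2, paste, collapse = ",")
  first <- !duplicated(key)
  weight <- as.numeric(table(factor(key, levels = key[first])))
  list(code = code[, first, drop = FALSE], weight = weight,
       labels = rownames(mm))
}

.adjacency <- function(E, nnodes = max(E)) {
  adj <- vector("list", nnodes)
  for (k in seq_len(nrow(E))) {
    a <- E[k, 1]; b <- E[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# nodes in an order where every child precedes its parent (reversed preorder)
.postorder <- function(adj, root) {
  nn <- length(adj)
  parent <- integer(nn)
  stack <- root
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    for (w in adj[[v]]) if (w != parent[v]) {
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  list(order = rev(visit), parent = parent)
}

.BITS <- c(1L, 2L, 4L, 8L)

# minimal changes over the tree for unordered characters; exact on
# multifurcating nodes too (majority-state generalisation of the Fitch pass)
.tree_length <- function(E, enc) {
  n <- nrow(enc$code)
  nn <- max(E)
  adj <- .adjacency(E, nn)
  po <- .postorder(adj, root = 1L)
  npat <- ncol(enc$code)
  S <- matrix(0L, nn, npat)
  S[seq_len(n), ] <- enc$code
  cost <- 0
  for (v in po$order) {
    if (v <= n) next
    kids <- adj[[v]][adj[[v]] != po$parent[v]]
    if (length(kids) == 1L) {
      S[v, ] <- S[kids, ]
      next
    }
    cnt <- matrix(0L, 4, npat)
    for (ch in kids) {
      sc <- S[ch, ]
      for (b in 1:4) cnt[b, ] <- cnt[b, ] + (bitwAnd(sc, .BITS[b]) > 0L)
    }
    kmax <- pmax(cnt[1, ], cnt[2, ], cnt[3, ], cnt[4, ])
    cost <- cost + sum(enc$weight * (length(kids) - kmax))
    S[v, ] <- (cnt[1, ] == kmax) * 1L + (cnt[2, ] == kmax) * 2L +
      (cnt[3, ] == kmax) * 4L + (cnt[4, ] == kmax) * 8L
  }
  root_child <- adj[[1L]][1L]
  cost + sum(enc$weight * (bitwAnd(S[root_child, ], S[1L, ]) == 0L))
}

.phylo_to_edges <- function(tree, labels) {
  idx <- match(tree$tip.label, labels)
  if (anyNA(idx) || length(labels) != length(tree$tip.label)) {
    stop("tree taxa do not match the character matrix taxa")
  }
  n <- length(labels)
  E <- tree$edge
  remap <- integer(max(E))
  remap[seq_len(n)] <- idx
  internal <- sort(unique(E[E > n]))
  remap[internal] <- n + seq_along(internal)
  cbind(remap[E[, 1]], remap[E[, 2]])
}

.edges_to_newick <- function(E, labels) {
  adj <- .adjacency(E)
  rec <- function(v, p) {
    kids <- adj[[v]][adj[[v]] != p]
    if (!length(kids)) return(labels[v])
    paste0("(", paste(vapply(kids, rec, character(1), p = v),
                      collapse = ","), ")")
  }
  c1 <- adj[[1L]][1L]
  kids <- adj[[c1]][adj[[c1]] != 1L]
  paste0("(", labels[1L], ",",
         paste(vapply(kids, rec, character(1), p = c1), collapse = ","), ");")
}

.edges_to_phylo <- function(E, labels) {
  ape::read.tree(text = .edges_to_newick(E, labels))
}

# canonical key of the unrooted topology: sorted nontrivial bipartitions,
# each written as the sorted leaf set on the side away from leaf 1
.split_keys <- function(E, n) {
  adj <- .adjacency(E)
  po <- .postorder(adj, root = 1L)
  below <- vector("list", length(adj))
  for (v in po$order) {
    if (v <= n) {
      below[[v]] <- v
      next
    }
    kids <- adj[[v]][adj[[v]] != po$parent[v]]
    below[[v]] <- sort(unlist(below[kids]))
  }
  keys <- character(0)
  for (k in seq_len(nrow(E))) {
    a <- E[k, 1]; b <- E[k, 2]
    if (a <= n || b <= n) next
    child <- if (po$parent[b] == a) b else a
    side <- below[[child]]
    if (length(side) >= 2 && length(side) <= n - 2) {
      keys <- c(keys, paste(side, collapse = ","))
    }
  }
  sort(keys)
}

.topology_key <- function(E, n) paste(.split_keys(E, n), collapse = ";")

.insert_leaf <- function(E, edge_row, leaf, newnode) {
  u <- E[edge_row, 1]; v <- E[edge_row, 2]
  rbind(E[-edge_row, , drop = FALSE],
        c(u, newnode), c(newnode, v), c(newnode, leaf))
}

.start_edges <- function(t1, t2, t3, hub) {
  rbind(c(t1, hub), c(t2, hub), c(t3, hub))
}

# greedy stepwise addition in the given taxon order
.greedy_addition <- function(enc, taxon_order) {
  n <- nrow(enc$code)
  E <- .start_edges(taxon_order[1], taxon_order[2], taxon_order[3], n + 1L)
  for (k in seq.int(4L, length.out = n - 3L)) {
    leaf <- taxon_order[k]
    newnode <- n + k - 2L
    best <- NULL; bestlen <- Inf
    for (e in seq_len(nrow(E))) {
      E2 <- .insert_leaf(E, e, leaf, newnode)
      len <- .tree_length(E2, enc)
      if (len < bestlen) {
        bestlen <- len
        best <- E2
      }
    }
    E <- best
  }
  E
}

.nni_moves <- function(E) {
  out <- list()
  n_by_node <- tabulate(E)
  for (k in seq_len(nrow(E))) {
    u <- E[k, 1]; v <- E[k, 2]
    if (n_by_node[u] < 2 || n_by_node[v] < 2) next  # needs both internal
    nb_u <- setdiff(c(E[E[, 1] == u, 2], E[E[, 2] == u, 1]), v)
    nb_v <- setdiff(c(E[E[, 1] == v, 2], E[E[, 2] == v, 1]), u)
    b <- nb_u[1]
    for (cc in nb_v) {
      E2 <- E
      for (r in seq_len(nrow(E2))) {
        if (all(sort(E2[r, ]) == sort(c(u, b)))) E2[r, ] <- c(u, cc)
        else if (all(sort(E2[r, ]) == sort(c(v, cc)))) E2[r, ] <- c(v, b)
      }
      out[[length(out) + 1L]] <- E2
    }
  }
  out
}

.nni_optimize <- function(E, enc) {
  len <- .tree_length(E, enc)
  repeat {
    improved <- FALSE
    for (E2 in .nni_moves(E)) {
      l2 <- .tree_length(E2, enc)
      if (l2 < len) {
        E <- E2; len <- l2; improved <- TRUE
        break
      }
    }
    if (!improved) return(list(E = E, length = len))
  }
}

# widen a set of optimal trees across the equal-length NNI plateau
.plateau <- function(Es, enc, len, n, max_trees) {
  seen <- new.env(parent = emptyenv())
  queue <- list()
  out <- list()
  push <- function(E) {
    key <- .topology_key(E, n)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <<- E
    queue[[length(queue) + 1L]] <<- E
  }
  for (E in Es) push(E)
  while (length(queue) && length(out) < max_trees) {
    E <- queue[[1]]
    queue <- queue[-1]
    for (E2 in .nni_moves(E)) {
      if (length(out) >= max_trees) break
      if (.tree_length(E2, enc) == len) push(E2)
    }
  }
  out
}

.bab_all_optimal <- function(enc) {
  n <- nrow(enc$code)
  greedy <- .greedy_addition(enc, seq_len(n))
  best <- .tree_length(greedy, enc)
  optima <- list()
  recurse <- function(E, k) {
    if (k > n) {
      len <- .tree_length(E, enc)
      if (len < best) {
        best <<- len
        optima <<- list(E)
      } else if (len == best) {
        optima[[length(optima) + 1L]] <<- E
      }
      return(invisible())
    }
    newnode <- n + k - 2L
    for (e in seq_len(nrow(E))) {
      E2 <- .insert_leaf(E, e, k, newnode)
      if (.tree_length(E2, enc) <= best) recurse(E2, k + 1L)
    }
  }
  recurse(.start_edges(1L, 2L, 3L, n + 1L), 4L)
  list(trees = optima, length = best)
}

# collapse internal branches whose minimum length is zero: contracting the
# branch leaves the tree length unchanged
.collapse_zero_edges <- function(E, enc) {
  n <- nrow(enc$code)
  full <- .tree_length(E, enc)
  n_by_node <- tabulate(E)
  drop <- logical(nrow(E))
  for (k in seq_len(nrow(E))) {
    u <- E[k, 1]; v <- E[k, 2]
    if (u <= n || v <= n) next
    Ec <- E[-k, , drop = FALSE]
    Ec[Ec == v] <- u
    if (.tree_length(Ec, enc) == full) drop[k] <- TRUE
  }
  if (!any(drop)) return(E)
  Ec <- E
  for (k in which(drop)) {
    u <- Ec[k, 1]; v <- Ec[k, 2]
    if (u == v) next
    Ec[Ec == v] <- u
  }
  Ec <- Ec[Ec[, 1] != Ec[, 2], , drop = FALSE]
  Ec
}

#' Fitch parsimony length of a tree
#'
#' Minimal number of unordered state changes the character matrix requires on
#' the given topology. IUPAC ambiguity codes enter as polymorphic state sets;
#' `?`, `N` and gaps are fully missing. Multifurcating nodes are handled
#' exactly via the majority-state generalisation of the Fitch pass.
#'
#' @param tree An unrooted `phylo` over exactly the matrix taxa.
#' @param m A `char_matrix`, `alignment`, or character matrix with taxa as
#'   rows.
#' @return The parsimony length (numeric count).
#' @export
fitch_length <- function(tree, m) {
  enc <- .encode_chars(m)
  E <- .phylo_to_edges(ape::unroot(tree), enc$labels)
  .tree_length(E, enc)
}

#' Search for most parsimonious trees
#'
#' `strategy = "exact"` runs a branch-and-bound stepwise-addition search
#' guaranteed to return every minimal-length topology (refused above 14
#' taxa). `strategy = "heuristic"` runs seeded random-addition starts
#' followed by nearest-neighbour-interchange hill climbing, then widens the
#' result across the equal-length NNI plateau. Branches whose minimum length
#' is zero are collapsed in the reported trees; a strict consensus is
#' attached.
#'
#' @param m Character matrix (taxa as rows).
#' @param strategy `"heuristic"` or `"exact"`.
#' @param seed Integer seed for the random-addition orders.
#' @param nstarts Number of random-addition starts (heuristic).
#' @param max_trees Cap on the number of equally parsimonious trees kept.
#' @param collapse Collapse zero-minimum-length branches in reported trees.
#' @return A `tree_set`: list with `trees` (multiPhylo, condensed), `length`,
#'   `consensus` (strict), `strategy` and `n_trees`.
#' @export
search_mp_trees <- function(m, strategy = c("heuristic", "exact"),
                            seed = 1L, nstarts = 10L, max_trees = 1000L,
                            collapse = TRUE) {
  strategy <- match.arg(strategy)
  enc <- .encode_chars(m)
  n <- nrow(enc$code)
  if (n < 4L) stop("need at least 4 taxa")
  if (strategy == "exact") {
    if (n > 14L) {
      stop("exact search is infeasible above 14 taxa; use strategy = 'heuristic'")
    }
    res <- .bab_all_optimal(enc)
    optima <- res$trees
    best <- res$length
    if (length(optima) > max_trees) optima <- optima[seq_len(max_trees)]
  } else {
    set.seed(seed)
    local_opt <- list()
    best <- Inf
    for (s in seq_len(nstarts)) {
      ord <- sample.int(n)
      opt <- .nni_optimize(.greedy_addition(enc, ord), enc)
      if (opt$length < best) {
        best <- opt$length
        local_opt <- list(opt$E)
      } else if (opt$length == best) {
        local_opt[[length(local_opt) + 1L]] <- opt$E
      }
    }
    optima <- .plateau(local_opt, enc, best, n, max_trees)
  }
  # dedupe topologies, then condense zero-length branches for reporting
  keys <- vapply(optima, .topology_key, character(1), n = n)
  optima <- optima[!duplicated(keys)]
  reported <- optima
  if (collapse) reported <- lapply(optima, .collapse_zero_edges, enc = enc)
  keys <- vapply(reported, .topology_key, character(1), n = n)
  reported <- reported[!duplicated(keys)]
  trees <- lapply(reported, .edges_to_phylo, labels = enc$labels)
  class(trees) <- "multiPhylo"
  cons <- if (length(trees) > 1L) ape::consensus(trees, p = 1) else trees[[1]]
  structure(list(trees = trees, length = best, consensus = cons,
                 strategy = strategy, n_trees = length(trees)),
            class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("%d most parsimonious tree(s) of length %g (%s search)\n",
              x$n_trees, x$length, x$strategy))
  invisible(x)
}

#' Strict consensus of a set of trees
#'
#' @param trees A `multiPhylo` or list of `phylo` objects on one taxon set.
#' @return A `phylo` containing exactly the clades shared by all trees.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  if (length(trees) == 1L) return(trees[[1]])
  ape::consensus(trees, p = 1)
}

# bipartitions of a phylo as canonical keys over the supplied label order
.phylo_split_keys <- function(tree, labels) {
  E <- .phylo_to_edges(tree, labels)
  .split_keys(E, length(labels))
}

#' Nonparametric bootstrap support
#'
#' Resamples characters (nucleotide and indel columns jointly) with
#' replacement, reruns the heuristic parsimony search per replicate, and
#' scores each bipartition of the reference consensus by the percentage of
#' replicates whose strict consensus of most parsimonious trees contains it.
#'
#' @param m Character matrix (taxa as rows).
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed (drives resampling and the per-replicate
#'   searches).
#' @param reference Optional `tree_set` or `phylo` whose bipartitions are
#'   scored; default runs [search_mp_trees()] on the full matrix.
#' @param nstarts Random-addition starts per replicate.
#' @param max_trees Cap on trees saved per replicate.
#' @return A `bootstrap_result`: data frame with columns `split` (taxon
#'   labels, `|`-separated) and `support` (percent), plus attribute
#'   `reference` (the scored consensus with node labels set to support).
#' @export
bootstrap_support <- function(m, replicates = 100L, seed = 1L,
                              reference = NULL, nstarts = 2L,
                              max_trees = 1000L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  src <- attr(m, "source")
  if (is.null(src)) src <- rep("sequence", ncol(m))
  labels <- rownames(m)
  if (is.null(reference)) {
    reference <- search_mp_trees(m, "heuristic", seed = seed,
                                 nstarts = max(nstarts, 5L),
                                 max_trees = max_trees)
  }
  ref_tree <- if (inherits(reference, "tree_set")) reference$consensus
              else reference
  ref_keys <- .phylo_split_keys(ref_tree, labels)
  hits <- stats::setNames(numeric(length(ref_keys)), ref_keys)
  set.seed(seed)
  for (r in seq_len(replicates)) {
    idx <- sample.int(ncol(m), replace = TRUE)
    mb <- m[, idx, drop = FALSE]
    attr(mb, "source") <- src[idx]
    ts <- search_mp_trees(mb, "heuristic",
                          seed = sample.int(.Machine$integer.max, 1),
                          nstarts = nstarts, max_trees = max_trees,
                          collapse = FALSE)
    keys <- .phylo_split_keys(ts$consensus, labels)
    common <- intersect(keys, ref_keys)
    hits[common] <- hits[common] + 1
  }
  support <- 100 * hits / replicates
  pretty <- vapply(names(support), function(k) {
    paste(labels[as.integer(strsplit(k, ",")[[1]])], collapse = "|")
  }, character(1))
  out <- data.frame(split = pretty, support = unname(support),
                    stringsAsFactors = FALSE)
  annotated <- .annotate_support(ref_tree, labels, support)
  structure(out, reference = annotated,
            class = c("bootstrap_result", "data.frame"))
}

.annotate_support <- function(tree, labels, support) {
  E <- .phylo_to_edges(tree, labels)
  n <- length(labels)
  adj <- .adjacency(E)
  po <- .postorder(adj, root = 1L)
  below <- vector("list", length(adj))
  for (v in po$order) {
    below[[v]] <- if (v <= n) v
                  else sort(unlist(below[adj[[v]][adj[[v]] != po$parent[v]]]))
  }
  # ape internal node numbering: match by clade content
  lab <- character(tree$Nnode)
  tip_idx <- match(tree$tip.label, labels)
  for (node in seq_len(tree$Nnode) + length(tree$tip.label)) {
    tips <- sort(tip_idx[unlist(.tips_below(tree, node))])
    key <- paste(tips, collapse = ",")
    key2 <- paste(sort(setdiff(seq_len(n), tips)), collapse = ",")
    s <- support[key]
    if (is.na(s)) s <- support[key2]
    lab[node - length(tree$tip.label)] <-
      if (is.na(s)) "" else sprintf("%.0f", s)
  }
  tree$node.label <- lab
  tree
}

# tips descending from a node of an ape tree
.tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) {
    if (k <= ntip) k else .tips_below(tree, k)
  }))
}
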