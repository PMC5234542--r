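#' Replicate map
#'
#' Groups sample entries (rows of a call matrix) into replicate sets, each
#' annotated with the deepest stage from which the replicates were duplicated:
#' DNA extraction, digestion/ligation, or preamplification only.
#'
#' @param sample Character vector of sample entry ids.
#' @param group Character vector of replicate-group ids (same length).
#' @param level Replication level per entry, one of `"extraction"`,
#'   `"digestion_ligation"`, `"preamp"`; recycled if length 1.
#' @return A `replicate_map` data frame.
#' @export
replicate_map <- function(sample, group, level = "preamp") {
  level <- rep(level, length.out = length(sample))
  stopifnot(length(group) == length(sample),
            all(level %in% c("extraction", "digestion_ligation", "preamp")),
            !anyDuplicated(sample))
  df <- data.frame(sample = as.character(sample), group = as.character(group),
                   level = level, stringsAsFactors = FALSE)
  class(df) <- c("replicate_map", "data.frame")
  df
}

#' Read a replicate map from CSV
#'
#' Two columns `sample, group`, optional third column `level`.
#'
#' @param path CSV path.
#' @return A `replicate_map`.
#' @export
read_replicate_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("sample", "group") %in% names(df))) {
    stop("replicate map needs columns 'sample' and 'group'")
  }
  replicate_map(df$sample, df$group,
                if ("level" %in% names(df)) df$level else "preamp")
}

#' @export
write_replicate_map <- function(reps, path) {
  utils::write.csv(as.data.frame(reps), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

rep_groups <- function(reps) split(reps$sample, reps$group)

# pairwise difference rate between two 0/?/1 profiles:
# mismatches are strict 0-vs-1 disagreements, the denominator counts
# positions where both calls are determinate
.pair_rate <- function(a, b) {
  comparable <- a != "?" & b != "?"
  n <- sum(comparable)
  if (n == 0L) return(c(rate = NA_real_, mismatch = NA_real_, comparable = 0))
  mm <- sum(a[comparable] != b[comparable])
  c(rate = mm / n, mismatch = mm, comparable = n)
}

#' Replicate scoring-error rates
#'
#' For every within-group pair of replicate profiles, computes the fraction
#' of comparable bins (both calls determinate) at which one replicate was
#' scored present and the other absent. Ambiguous calls are excluded
#' pairwise from both numerator and denominator.
#'
#' @param calls A `call_matrix`.
#' @param reps A `replicate_map` covering (at least) the rows of `calls`.
#' @return An `error_report`: a data frame of per-pair rates (columns group,
#'   sample_a, sample_b, level, mismatch, comparable, rate) with attributes
#'   `range` (min/max over defined rates) and `by_level` (mean rate per
#'   replication level).
#' @export
replicate_difference_rates <- function(calls, reps) {
  stopifnot(inherits(calls, "call_matrix"), inherits(reps, "replicate_map"))
  groups <- rep_groups(reps)
  level <- stats::setNames(reps$level, reps$sample)
  rows <- list()
  for (g in names(groups)) {
    members <- intersect(groups[[g]], rownames(calls))
    if (length(members) < 2L) {
      if (length(members) == 1L) {
        warning("replicate group '", g, "' has a single member; skipped")
      }
      next
    }
    prs <- utils::combn(members, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      st <- .pair_rate(calls[a, ], calls[b, ])
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, sample_a = a, sample_b = b,
        level = level[[a]], mismatch = st[["mismatch"]],
        comparable = st[["comparable"]], rate = st[["rate"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), sample_a = character(),
               sample_b = character(), level = character(),
               mismatch = numeric(), comparable = numeric(), rate = numeric())
  rownames(out) <- NULL
  ok <- !is.na(out$rate)
  attr(out, "range") <- if (any(ok)) range(out$rate[ok]) else c(NA_real_, NA_real_)
  attr(out, "by_level") <- if (any(ok)) {
    tapply(out$rate[ok], out$level[ok], mean)
  } else NULL
  class(out) <- c("error_report", "data.frame")
  out
}

#' @export
print.error_report <- function(x, ...) {
  rng <- attr(x, "range")
  cat(sprintf("Replicate difference rates: %d pairs, range %.1f%% - %.1f%%\n",
              nrow(x), 100 * rng[1], 100 * rng[2]))
  NextMethod()
}

new_filter_trace <- function(step1, step2, retained) {
  structure(list(step1_removed = step1, step2_removed = step2,
                 retained = retained),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat(sprintf(
    "Filter trace: %d bins removed in step 1 (ambiguous), %d in step 2 (irreproducible), %d retained\n",
    length(x$step1_removed), length(x$step2_removed), length(x$retained)))
  invisible(x)
}

#' Error-elimination step 1: drop ambiguous bins
#'
#' Removes every bin in which any sample was called ambiguous, i.e. any
#' sample's peak fell in the 10--20% band of that bin's maximum intensity
#' (under the scoring boundary convention, exactly the bins containing a
#' `?`). The output contains no ambiguous calls.
#'
#' @param calls A `call_matrix`.
#' @return A list with elements `calls` (the reduced matrix) and `trace`
#'   (a `filter_trace`; step-2 slot empty).
#' @export
drop_ambiguous_bins <- function(calls) {
  stopifnot(inherits(calls, "call_matrix"))
  has_q <- apply(unclass(calls) == "?", 2, any)
  out <- calls[, !has_q, drop = FALSE]
  out <- new_call_matrix(out, attr(calls, "thresholds"),
                         channel = attr(calls, "channel")[!has_q])
  list(calls = out,
       trace = new_filter_trace(colnames(calls)[has_q], character(),
                                colnames(calls)[!has_q]))
}

#' Error-elimination step 2: drop irreproducible bins
#'
#' Removes every remaining bin scored present in one replicate and absent in
#' another replicate of the same sample. Must run after
#' [drop_ambiguous_bins()]; ambiguous calls in the input are an error. In the
#' output every replicate group has identical profiles.
#'
#' @param calls A `call_matrix` without `?` cells.
#' @param reps A `replicate_map`.
#' @return A list with elements `calls` and `trace` (step-1 slot empty).
#' @export
drop_irreproducible_bins <- function(calls, reps) {
  stopifnot(inherits(calls, "call_matrix"), inherits(reps, "replicate_map"))
  if (any(calls == "?")) {
    stop("ambiguous calls present; run drop_ambiguous_bins first")
  }
  groups <- rep_groups(reps)
  bad <- rep(FALSE, ncol(calls))
  for (g in groups) {
    members <- intersect(g, rownames(calls))
    if (length(members) < 2L) next
    sub <- unclass(calls)[members, , drop = FALSE]
    bad <- bad | (apply(sub == "1", 2, any) & apply(sub == "0", 2, any))
  }
  out <- new_call_matrix(calls[, !bad, drop = FALSE],
                         attr(calls, "thresholds"),
                         channel = attr(calls, "channel")[!bad])
  list(calls = out,
       trace = new_filter_trace(character(), colnames(calls)[bad],
                                colnames(calls)[!bad]))
}

#' Two-step scoring-error elimination
#'
#' Applies [drop_ambiguous_bins()] then [drop_irreproducible_bins()] in that
#' fixed order and merges the traces.
#'
#' @inheritParams drop_irreproducible_bins
#' @return A list with elements `calls` and `trace` (both steps recorded).
#' @export
error_filter <- function(calls, reps) {
  s1 <- drop_ambiguous_bins(calls)
  s2 <- drop_irreproducible_bins(s1$calls, reps)
  list(calls = s2$calls,
       trace = new_filter_trace(s1$trace$step1_removed,
                                s2$trace$step2_removed,
                                s2$trace$retained))
}

#' Collapse replicates to one row per group
#'
#' Valid only once replicate profiles are identical within every group (after
#' the two-step filter); the collapsed row carries the group id.
#'
#' @inheritParams drop_irreproducible_bins
#' @return A `call_matrix` with one row per replicate group.
#' @export
collapse_replicates <- function(calls, reps) {
  stopifnot(inherits(calls, "call_matrix"), inherits(reps, "replicate_map"))
  groups <- rep_groups(reps)
  rows <- matrix(NA_character_, length(groups), ncol(calls),
                 dimnames = list(names(groups), colnames(calls)))
  for (g in names(groups)) {
    members <- intersect(groups[[g]], rownames(calls))
    if (!length(members)) stop("replicate group '", g, "' absent from matrix")
    sub <- unclass(calls)[members, , drop = FALSE]
    disc <- which(apply(sub, 2, function(col) length(unique(col)) > 1L))
    if (length(disc)) {
      stop("replicate group '", g, "' is discordant at bin ",
           colnames(calls)[disc[1]], "; run the error filter first")
    }
    rows[g, ] <- sub[1, ]
  }
  new_call_matrix(rows, attr(calls, "thresholds"),
                  channel = attr(calls, "channel"))
}

#' Write a filter trace
#'
#' Machine-readable CSV: columns `bin, fate` with fate in
#' `{retained, step1, step2}`.
#'
#' @param trace A `filter_trace`.
#' @param path Output CSV path.
#' @export
write_filter_trace <- function(trace, path) {
  stopifnot(inherits(trace, "filter_trace"))
  df <- data.frame(
    bin = c(trace$retained, trace$step1_removed, trace$step2_removed),
    fate = c(rep("retained", length(trace$retained)),
             rep("step1", length(trace$step1_removed)),
             rep("step2", length(trace$step2_removed))),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
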