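#' Three-state call thresholds
#'
#' Fractions of the per-bin maximum intensity that separate absent (0),
#' ambiguous (?) and present (1) calls. With the defaults, a peak below 10%
#' of the strongest peak in its bin is absent, between 10% and 20%
#' (inclusive at both ends) ambiguous, and above 20% present.
#'
#' @param ambiguous_low Lower bound of the ambiguous band (fraction of the
#'   per-bin maximum).
#' @param present_low Upper bound of the ambiguous band / lower bound of
#'   present.
#' @return An object of class `call_thresholds`.
#' @export
call_thresholds <- function(ambiguous_low = 0.10, present_low = 0.20) {
  stopifnot(ambiguous_low > 0, ambiguous_low < present_low, present_low < 1)
  structure(list(ambiguous_low = ambiguous_low, present_low = present_low),
            class = "call_thresholds")
}

new_call_matrix <- function(states, thresholds = NULL, channel = NULL) {
  stopifnot(is.matrix(states), all(states %in% c("0", "?", "1")))
  if (is.null(channel)) channel <- rep(NA_character_, ncol(states))
  structure(states, thresholds = thresholds, channel = channel,
            class = c("call_matrix", "matrix", "array"))
}

#' @export
`[.call_matrix` <- function(x, i, j, ..., drop = FALSE) {
  mx <- unclass(x)
  n_index <- nargs() - 1L - !missing(drop)
  if (n_index < 2L) return(mx[i])           # single-index: plain vector
  out <- if (missing(i)) mx[, j, drop = drop]
         else if (missing(j)) mx[i, , drop = drop]
         else mx[i, j, drop = drop]
  if (!is.matrix(out)) return(out)
  ch <- attr(x, "channel")[match(colnames(out), colnames(mx))]
  new_call_matrix(out, attr(x, "thresholds"), channel = ch)
}

#' @export
print.call_matrix <- function(x, ...) {
  tab <- table(factor(x, levels = c("0", "?", "1")))
  cat(sprintf("AFLP call matrix: %d samples x %d bins (0: %d, ?: %d, 1: %d)\n",
              nrow(x), ncol(x), tab[["0"]], tab[["?"]], tab[["1"]]))
  invisible(x)
}

#' Sum-of-signal normalisation
#'
#' Rescales each sample's intensities so all per-sample totals are equal,
#' matching the sum-of-signal normalisation of automated fragment scoring.
#' The common target is the grand mean of the per-sample totals, so the
#' overall signal mass is preserved; downstream calls depend only on
#' within-bin ratios, so any common constant would give identical calls.
#'
#' @param m A `binned_matrix`.
#' @return The normalised `binned_matrix`.
#' @export
normalize_signals <- function(m) {
  stopifnot(inherits(m, "binned_matrix"))
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("cannot normalise sample(s) with zero total intensity: ",
         paste(rownames(m)[totals == 0], collapse = ", "))
  }
  scale <- mean(totals) / totals
  out <- m * scale
  attributes(out) <- attributes(m)
  out
}

#' Call three-state genotypes per bin
#'
#' For each bin, intensities are expressed relative to the maximum intensity
#' any sample shows in that bin; ratios below `ambiguous_low` are called
#' absent ("0"), ratios in `[ambiguous_low, present_low]` ambiguous ("?"),
#' and ratios above `present_low` present ("1"). Both band boundaries fall in
#' the ambiguous class, the conservative convention. Bins whose maximum is 0
#' are dropped. The input should be normalised ([normalize_signals()]).
#'
#' @param m A `binned_matrix` (normalised).
#' @param thresholds A [call_thresholds()].
#' @return A `call_matrix` with bin labels qualified by channel
#'   (`<channel>:<bp>`).
#' @export
call_states <- function(m, thresholds = call_thresholds()) {
  stopifnot(inherits(m, "binned_matrix"), inherits(thresholds, "call_thresholds"))
  maxes <- apply(m, 2, max)
  keep <- maxes > 0
  m2 <- m[, keep, drop = FALSE]
  maxes <- maxes[keep]
  r <- sweep(unclass(m2), 2, maxes, "/")
  states <- matrix("0", nrow(r), ncol(r))
  states[r >= thresholds$ambiguous_low & r <= thresholds$present_low] <- "?"
  states[r > thresholds$present_low] <- "1"
  channel <- attr(m, "channel")
  dimnames(states) <- list(rownames(m2),
                           sprintf("%s:%s", channel, colnames(m2)))
  new_call_matrix(states, thresholds,
                  channel = rep(channel, ncol(states)))
}

#' Combine per-channel call matrices
#'
#' Column-wise concatenation of call matrices scored per primer pair, after
#' aligning sample rows to the order of the first matrix. Sample sets must be
#' identical and channel-qualified bin labels disjoint.
#'
#' @param parts A list of `call_matrix` objects.
#' @return A single combined `call_matrix`.
#' @export
combine_matrices <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1,
            all(vapply(parts, inherits, logical(1), "call_matrix")))
  ref <- rownames(parts[[1]])
  for (p in parts[-1]) {
    extra <- setdiff(rownames(p), ref)
    miss <- setdiff(ref, rownames(p))
    if (length(extra) || length(miss)) {
      stop("sample sets differ between call matrices; not shared: ",
           paste(c(miss, extra), collapse = ", "))
    }
  }
  labs <- unlist(lapply(parts, colnames))
  if (anyDuplicated(labs)) {
    stop("duplicate bin labels after channel qualification: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  states <- do.call(cbind, lapply(parts, function(p) {
    unclass(p)[ref, , drop = FALSE]
  }))
  new_call_matrix(states, attr(parts[[1]], "thresholds"),
                  channel = unlist(lapply(parts, attr, "channel")))
}

#' Score all channels of a binned peak set
#'
#' Convenience wrapper: normalises and calls each per-channel matrix
#' independently, then combines the per-channel call matrices.
#'
#' @param binned A named list of `binned_matrix` objects (see
#'   [bin_channels()]).
#' @param thresholds A [call_thresholds()].
#' @return A combined `call_matrix`.
#' @export
score_channels <- function(binned, thresholds = call_thresholds()) {
  combine_matrices(lapply(binned, function(b) {
    call_states(normalize_signals(b), thresholds)
  }))
}

#' Write / read a call matrix as CSV
#'
#' Cells are `0`, `?` or `1`; rows are samples, columns channel-qualified bin
#' labels.
#'
#' @param calls A `call_matrix`.
#' @param path Output path.
#' @export
write_call_matrix <- function(calls, path) {
  stopifnot(inherits(calls, "call_matrix"))
  df <- data.frame(sample = rownames(calls), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(calls))) df[[colnames(calls)[j]]] <- calls[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_call_matrix
#' @export
read_call_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  channel <- sub(":.*$", "", colnames(m))
  channel[!grepl(":", colnames(m))] <- NA_character_
  new_call_matrix(m, channel = channel)
}

#' Write a call matrix as a NEXUS DATA block
#'
#' `datatype=standard`, `symbols="01"`, `missing=?` -- readable by split
#' network software.
#'
#' @param calls A `call_matrix`.
#' @param path Output path.
#' @export
write_call_nexus <- function(calls, path) {
  stopifnot(inherits(calls, "call_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  safe <- gsub("[^A-Za-z0-9_.]", "_", rownames(calls))
  writeLines(c("#NEXUS", "", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                       nrow(calls), ncol(calls)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
               "  MATRIX"), con)
  pad <- max(nchar(safe))
  for (i in seq_len(nrow(calls))) {
    writeLines(sprintf("    %-*s %s", pad, safe[i],
                       paste(calls[i, ], collapse = "")), con)
  }
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
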