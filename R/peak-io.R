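#' Binning configuration for fragment-analyzer peaks
#'
#' Bundles the raw-peak filters and the fixed-width binning grid used to turn
#' size-called peaks into a sample-by-bin intensity matrix. Defaults follow
#' common automated AFLP genotyping practice: a 100--500 bp scoring window,
#' 0.5 bp bins, a 30 RFU peak threshold and a 1.5 bp maximum peak width.
#'
#' @param window_start Left edge of the scoring window in bp (inclusive).
#' @param window_end Right edge of the scoring window in bp (exclusive).
#' @param bin_width Bin width in bp; bins are half-open intervals
#'   `[left, left + bin_width)` anchored at `window_start`.
#' @param min_intensity Minimum peak intensity in RFU (peaks below are dropped).
#' @param max_peak_width Maximum peak width in bp; applied only to peaks that
#'   report a width.
#' @return An object of class `binning_config`.
#' @export
binning_config <- function(window_start = 100, window_end = 500,
                           bin_width = 0.5, min_intensity = 30,
                           max_peak_width = 1.5) {
  stopifnot(window_start < window_end, bin_width > 0, min_intensity >= 0,
            max_peak_width > 0)
  structure(list(window_start = as.numeric(window_start),
                 window_end = as.numeric(window_end),
                 bin_width = as.numeric(bin_width),
                 min_intensity = as.numeric(min_intensity),
                 max_peak_width = as.numeric(max_peak_width)),
            class = "binning_config")
}

#' @export
print.binning_config <- function(x, ...) {
  cat(sprintf("Binning config: window [%g, %g) bp, bin width %g bp,\n",
              x$window_start, x$window_end, x$bin_width))
  cat(sprintf("  min intensity %g RFU, max peak width %g bp\n",
              x$min_intensity, x$max_peak_width))
  invisible(x)
}

new_aflp_peaks <- function(df) {
  stopifnot(all(c("sample", "channel", "size", "intensity") %in% names(df)))
  if (is.null(df$width)) df$width <- NA_real_
  df <- df[, c("sample", "channel", "size", "intensity", "width")]
  df$sample <- as.character(df$sample)
  df$channel <- as.character(df$channel)
  rownames(df) <- NULL
  class(df) <- c("aflp_peaks", "data.frame")
  df
}

#' @export
print.aflp_peaks <- function(x, ...) {
  cat(sprintf("AFLP peak table: %d peaks, %d samples, %d channel(s)\n",
              nrow(x), length(unique(x$sample)), length(unique(x$channel))))
  NextMethod()
}

# column-name synonyms per supported dialect, matched case-insensitively
.peak_dialects <- list(
  generic = list(sample = c("sample", "sample_id", "sample.name", "sample name"),
                 channel = c("channel", "dye", "primer", "primer_pair", "marker"),
                 size = c("size", "size_bp", "fragment_size"),
                 intensity = c("intensity", "height", "rfu", "peak_height"),
                 width = c("width", "peak_width", "width_bp")),
  genemapper = list(sample = c("sample file name", "sample file", "sample name"),
                    channel = c("dye/sample peak", "dye", "marker"),
                    size = c("size"),
                    intensity = c("height"),
                    width = c("width"))
)

.match_col <- function(header, synonyms) {
  hit <- match(synonyms, tolower(header))
  hit <- hit[!is.na(hit)]
  if (length(hit)) hit[1] else NA_integer_
}

#' Read a fragment-analyzer peak export
#'
#' Parses a long-format CSV of size-called peaks (one row per peak) into an
#' `aflp_peaks` table. Column names are matched case-insensitively;
#' the `generic` dialect expects sample, channel (or dye), size and
#' height/intensity columns, with an optional width column. The
#' `genemapper` dialect maps the column names of a GeneMapper genotypes
#' export onto the same fields.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect One of `"generic"` or `"genemapper"`.
#' @return An `aflp_peaks` data frame (columns sample, channel, size,
#'   intensity, width) preserving input row order.
#' @export
read_peak_table <- function(path, dialect = c("generic", "genemapper")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  syn <- .peak_dialects[[dialect]]
  idx <- vapply(syn, .match_col, integer(1), header = names(df))
  required <- c("sample", "channel", "size", "intensity")
  missing <- required[is.na(idx[required])]
  if (length(missing)) {
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "), " (dialect '", dialect, "')")
  }
  if (nrow(df) == 0L) {
    return(new_aflp_peaks(data.frame(sample = character(), channel = character(),
                                     size = numeric(), intensity = numeric(),
                                     width = numeric())))
  }
  num_field <- function(field) {
    i <- idx[[field]]
    if (is.na(i)) return(rep(NA_real_, nrow(df)))
    raw <- df[[i]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw == "" | toupper(raw) == "NA"))
    if (field %in% c("size", "intensity")) bad <- which(is.na(val))
    if (length(bad)) {
      stop(sprintf("non-numeric %s value '%s' on line %d of %s",
                   field, raw[bad[1]], bad[1] + 1L, path))
    }
    val
  }
  new_aflp_peaks(data.frame(sample = df[[idx[["sample"]]]],
                            channel = df[[idx[["channel"]]]],
                            size = num_field("size"),
                            intensity = num_field("intensity"),
                            width = num_field("width"),
                            stringsAsFactors = FALSE))
}

#' Apply raw-peak quality filters
#'
#' Retains peaks inside the half-open scoring window
#' `[window_start, window_end)` with intensity at or above `min_intensity`;
#' peaks that report a width wider than `max_peak_width` are removed (peaks
#' without a width are never width-filtered).
#'
#' @param peaks An `aflp_peaks` table.
#' @param cfg A [binning_config()].
#' @return The filtered `aflp_peaks` table, with an attribute `"removed"`
#'   giving per-filter removal counts (window, intensity, width).
#' @export
filter_raw_peaks <- function(peaks, cfg = binning_config()) {
  stopifnot(inherits(peaks, "aflp_peaks"), inherits(cfg, "binning_config"))
  in_window <- peaks$size >= cfg$window_start & peaks$size < cfg$window_end
  strong <- peaks$intensity >= cfg$min_intensity
  narrow <- is.na(peaks$width) | peaks$width <= cfg$max_peak_width
  keep <- in_window & strong & narrow
  out <- new_aflp_peaks(peaks[keep, , drop = FALSE])
  attr(out, "removed") <- c(window = sum(!in_window),
                            intensity = sum(in_window & !strong),
                            width = sum(in_window & strong & !narrow))
  out
}

bin_labels <- function(cfg) {
  lefts <- seq(cfg$window_start, cfg$window_end - cfg$bin_width / 2,
               by = cfg$bin_width)
  sprintf("%.1f", lefts)
}

#' Bin filtered peaks onto a fixed-width grid
#'
#' Assigns each peak of one channel to bin
#' `floor((size - window_start) / bin_width)`; when a sample has several peaks
#' in one bin the maximum intensity is kept. Expects peaks that already passed
#' [filter_raw_peaks()].
#'
#' @param peaks An `aflp_peaks` table containing a single channel.
#' @param cfg A [binning_config()].
#' @param samples Optional character vector fixing the sample set and row
#'   order (samples without peaks get all-zero rows).
#' @param drop_empty Drop bins with no peak in any sample (default `TRUE`).
#' @return A `binned_matrix`: numeric samples x bins matrix of RFU with bin
#'   left-edge labels as column names and attributes `channel`, `bin_left`,
#'   and `config`.
#' @export
bin_peaks <- function(peaks, cfg = binning_config(), samples = NULL,
                      drop_empty = TRUE) {
  stopifnot(inherits(peaks, "aflp_peaks"), inherits(cfg, "binning_config"))
  channels <- unique(peaks$channel)
  if (length(channels) > 1L) {
    stop("bin_peaks expects a single channel; got: ",
         paste(channels, collapse = ", "), ". Use bin_channels().")
  }
  channel <- if (length(channels)) channels else NA_character_
  if (nrow(peaks) &&
      (any(peaks$size < cfg$window_start) || any(peaks$size >= cfg$window_end))) {
    stop("internal error: peak outside scoring window; run filter_raw_peaks first")
  }
  labels <- bin_labels(cfg)
  smp <- if (is.null(samples)) unique(peaks$sample) else as.character(samples)
  m <- matrix(0, nrow = length(smp), ncol = length(labels),
              dimnames = list(smp, labels))
  if (nrow(peaks)) {
    bi <- floor((peaks$size - cfg$window_start) / cfg$bin_width) + 1L
    si <- match(peaks$sample, smp)
    if (anyNA(si)) stop("peak sample not in 'samples': ",
                        peaks$sample[which(is.na(si))[1]])
    # max-intensity collapse per (sample, bin) cell
    o <- order(peaks$intensity)  # later assignment wins => max
    idx <- cbind(si[o], bi[o])
    m[idx] <- peaks$intensity[o]
  }
  lefts <- cfg$window_start + (seq_along(labels) - 1L) * cfg$bin_width
  if (drop_empty) {
    keep <- colSums(m) > 0
    m <- m[, keep, drop = FALSE]
    lefts <- lefts[keep]
  }
  structure(m, channel = channel, bin_left = lefts, config = cfg,
            class = c("binned_matrix", "matrix", "array"))
}

#' Bin all channels of a peak table
#'
#' Splits an `aflp_peaks` table by channel and bins each channel separately
#' with [bin_peaks()], using the union of samples as a common row set.
#'
#' @inheritParams bin_peaks
#' @return A named list of `binned_matrix` objects, one per channel.
#' @export
bin_channels <- function(peaks, cfg = binning_config(), samples = NULL,
                         drop_empty = TRUE) {
  if (is.null(samples)) samples <- unique(peaks$sample)
  channels <- sort(unique(peaks$channel))
  out <- lapply(channels, function(ch) {
    bin_peaks(new_aflp_peaks(peaks[peaks$channel == ch, , drop = FALSE]),
              cfg, samples = samples, drop_empty = drop_empty)
  })
  names(out) <- channels
  out
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("Binned AFLP matrix: %d samples x %d bins (channel %s)\n",
              nrow(x), ncol(x), attr(x, "channel")))
  invisible(x)
}

#' Write / read a binned intensity matrix as CSV
#'
#' Rows are samples, columns are bin left-edge labels (1 decimal place). The
#' channel and binning grid travel in a comment-free side-car free form: the
#' channel is stored in the first header cell as `channel=<label>`.
#'
#' @param m A `binned_matrix`.
#' @param path Output CSV path.
#' @return `write_binned_matrix` returns `path` invisibly;
#'   `read_binned_matrix` returns a `binned_matrix`.
#' @export
write_binned_matrix <- function(m, path) {
  stopifnot(inherits(m, "binned_matrix"))
  df <- data.frame(check.names = FALSE,
                   row.names = NULL,
                   stringsAsFactors = FALSE,
                   c1 = rownames(m))
  names(df) <- sprintf("channel=%s", attr(m, "channel"))
  # %.17g so doubles survive the text round trip bit-exactly
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- sprintf("%.17g", m[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binned_matrix
#' @param cfg A [binning_config()] describing the grid the file was written on.
#' @export
read_binned_matrix <- function(path, cfg = binning_config()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  channel <- sub("^channel=", "", names(df)[1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  lefts <- as.numeric(colnames(m))
  colnames(m) <- sprintf("%.1f", lefts)
  structure(m, channel = channel, bin_left = lefts, config = cfg,
            class = c("binned_matrix", "matrix", "array"))
}
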