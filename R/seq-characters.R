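IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
                "?" = 15L, "-" = 15L)

#' Read a multiple sequence alignment
#'
#' FASTA (via [ape::read.FASTA]) or NEXUS (via [ape::read.nexus.data];
#' interleaved and sequential matrices both supported). Sequences are
#' uppercased and gap characters normalised to `-`.
#'
#' @param path File path.
#' @param format `"fasta"` or `"nexus"`; guessed from the extension when
#'   missing.
#' @return An `alignment`: character matrix, rows = taxa, columns = sites.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|nxs)$", tolower(path))) "nexus"
              else "fasta"
  }
  seqs <- if (format == "fasta") {
    lapply(as.character(ape::read.FASTA(path)), paste0, collapse = "")
  } else {
    lapply(ape::read.nexus.data(path), paste0, collapse = "")
  }
  lens <- vapply(seqs, nchar, integer(1))
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[which(lens != lens[1])[1]]
    stop("alignment rows have unequal lengths; first offender: ", bad)
  }
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(toupper(s), "")[[1]]))
  m[m %in% c(".", "~")] <- "-"
  rownames(m) <- names(seqs)
  new_alignment(m)
}

#' Construct an alignment from a character matrix
#'
#' @param m Character matrix, rows = taxa (unique rownames), columns =
#'   aligned sites.
#' @return An `alignment`.
#' @export
new_alignment <- function(m) {
  stopifnot(is.matrix(m), is.character(m), !anyDuplicated(rownames(m)))
  structure(m, class = c("alignment", "matrix", "array"))
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d taxa x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Write an alignment as FASTA
#' @param a An `alignment` or `char_matrix`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(a, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    writeLines(c(paste0(">", rownames(a)[i]),
                 paste(a[i, ], collapse = "")), con)
  }
  invisible(path)
}

# maximal runs of '-' per row as (start, end) pairs
.gap_runs <- function(row) {
  r <- rle(row == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Simple indel coding
#'
#' Codes each positionally distinct internal alignment gap (a maximal run of
#' `-` with a given start and end) as one appended binary character: taxa
#' bearing exactly that gap score 1, taxa with residues across the span
#' score 0, and taxa whose own gap strictly contains the span score `?`
#' (their state is unobservable). Terminal gap runs are treated as missing
#' data, not coded, and are rewritten as `?` in the nucleotide columns.
#'
#' @param a An `alignment`.
#' @return A `char_matrix`: the nucleotide columns (terminal gaps as `?`)
#'   followed by the binary indel characters; attribute `source` marks each
#'   column `"sequence"` or `"indel"`, attribute `indel_spans` records the
#'   coded (start, end) pairs.
#' @export
simple_indel_coding <- function(a) {
  stopifnot(inherits(a, "alignment") || (is.matrix(a) && is.character(a)))
  m <- unclass(a)
  ntax <- nrow(m); L <- ncol(m)
  runs_by_taxon <- lapply(seq_len(ntax), function(i) {
    r <- .gap_runs(m[i, ])
    if (nrow(r)) {
      terminal <- r[, "start"] == 1L | r[, "end"] == L
      # terminal runs become missing data
      for (k in which(terminal)) m[i, r[k, "start"]:r[k, "end"]] <<- "?"
      r <- r[!terminal, , drop = FALSE]
    }
    r
  })
  all_runs <- unique(do.call(rbind, runs_by_taxon))
  if (is.null(all_runs) || nrow(all_runs) == 0L) {
    out <- m
    attr(out, "source") <- rep("sequence", ncol(out))
    attr(out, "indel_spans") <- matrix(integer(), 0, 2)
    class(out) <- c("char_matrix", "matrix", "array")
    return(out)
  }
  all_runs <- all_runs[order(all_runs[, "start"], all_runs[, "end"]), ,
                       drop = FALSE]
  indel <- matrix("0", ntax, nrow(all_runs))
  for (k in seq_len(nrow(all_runs))) {
    s <- all_runs[k, "start"]; e <- all_runs[k, "end"]
    for (i in seq_len(ntax)) {
      ri <- runs_by_taxon[[i]]
      if (nrow(ri) && any(ri[, "start"] == s & ri[, "end"] == e)) {
        indel[i, k] <- "1"
      } else if (any(m[i, s:e] %in% c("-", "?"))) {
        # a longer gap (or missing data) covering part of the span: state
        # unobservable unless the taxon shows residues across the span
        covering <- nrow(ri) && any(ri[, "start"] <= s & ri[, "end"] >= e)
        missing_cover <- all(m[i, s:e] == "?")
        if (covering || missing_cover) indel[i, k] <- "?"
        # partial overlap leaves residues in the span: scored 0
      }
    }
  }
  colnames(indel) <- sprintf("indel_%d_%d", all_runs[, "start"],
                             all_runs[, "end"])
  m[m == "-"] <- "?"  # gap cells become missing: the indel characters carry the signal
  if (is.null(colnames(m))) colnames(m) <- sprintf("site_%d", seq_len(L))
  out <- cbind(m, indel)
  attr(out, "source") <- c(rep("sequence", L), rep("indel", ncol(indel)))
  attr(out, "indel_spans") <- all_runs
  class(out) <- c("char_matrix", "matrix", "array")
  out
}

#' @export
print.char_matrix <- function(x, ...) {
  src <- attr(x, "source")
  cat(sprintf("Character matrix: %d taxa, %d nucleotide + %d indel characters\n",
              nrow(x), sum(src == "sequence"), sum(src == "indel")))
  invisible(x)
}

# determinate states of one column: A/C/G/T for sequence columns, 0/1 for
# binary ones; ambiguity codes, gaps and ? are excluded
.determinate <- function(col, source) {
  if (source == "indel") col[col %in% c("0", "1")]
  else col[col %in% c("A", "C", "G", "T")]
}

#' Constant / variable / parsimony-informative character counts
#'
#' A column is variable when it shows at least two distinct determinate
#' states, and parsimony-informative when at least two states are each borne
#' by at least two taxa. IUPAC ambiguity codes, gaps and `?` are excluded
#' from state counting.
#'
#' @param m A `char_matrix` (or plain character matrix, all columns treated
#'   as sequence unless an attribute `source` is present).
#' @param taxa Optional subset of taxa to restrict the counts to (e.g. the
#'   ingroup).
#' @return A `character_counts` object: list with `n_constant`, `n_variable`,
#'   `n_informative`, total `n`, and a per-source breakdown `by_source`.
#' @export
character_counts <- function(m, taxa = NULL) {
  src <- attr(m, "source")
  if (is.null(src)) src <- rep("sequence", ncol(m))
  mm <- unclass(m)
  if (!is.null(taxa)) {
    if (!length(taxa)) stop("empty taxon subset")
    missing <- setdiff(taxa, rownames(mm))
    if (length(missing)) stop("unknown taxa: ", paste(missing, collapse = ", "))
    mm <- mm[taxa, , drop = FALSE]
  }
  classify <- function(j) {
    st <- table(.determinate(mm[, j], src[j]))
    if (length(st) < 2L) "constant"
    else if (sum(st >= 2L) >= 2L) "informative"
    else "variable"
  }
  cls <- vapply(seq_len(ncol(mm)), classify, character(1))
  count3 <- function(idx) {
    c(n_constant = sum(cls[idx] == "constant"),
      n_variable = sum(cls[idx] != "constant"),
      n_informative = sum(cls[idx] == "informative"),
      n = length(idx))
  }
  structure(list(n_constant = sum(cls == "constant"),
                 n_variable = sum(cls != "constant"),
                 n_informative = sum(cls == "informative"),
                 n = ncol(mm),
                 by_source = rbind(sequence = count3(which(src == "sequence")),
                                   indel = count3(which(src == "indel")))),
            class = "character_counts")
}

#' @export
print.character_counts <- function(x, ...) {
  cat(sprintf("%d characters: %d constant, %d variable (%d parsimony-informative)\n",
              x$n, x$n_constant, x$n_variable, x$n_informative))
  invisible(x)
}

#' Write a character matrix as NEXUS
#'
#' Nucleotide columns go into a DATA block (datatype=dna); coded indel
#' characters, if any, into a second CHARACTERS block (datatype=standard).
#'
#' @param m A `char_matrix`.
#' @param path Output path.
#' @export
write_char_nexus <- function(m, path) {
  src <- attr(m, "source")
  if (is.null(src)) src <- rep("sequence", ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  safe <- gsub("[^A-Za-z0-9_.]", "_", rownames(m))
  pad <- max(nchar(safe))
  seqcols <- which(src == "sequence")
  writeLines(c("#NEXUS", "", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m),
                       length(seqcols)),
               "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
               "  MATRIX"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(sprintf("    %-*s %s", pad, safe[i],
                       paste(m[i, seqcols], collapse = "")), con)
  }
  writeLines(c("  ;", "END;"), con)
  indcols <- which(src == "indel")
  if (length(indcols)) {
    writeLines(c("", "BEGIN CHARACTERS;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m),
                         length(indcols)),
                 "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
                 "  MATRIX"), con)
    for (i in seq_len(nrow(m))) {
      writeLines(sprintf("    %-*s %s", pad, safe[i],
                         paste(m[i, indcols], collapse = "")), con)
    }
    writeLines(c("  ;", "END;"), con)
  }
  invisible(path)
}
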