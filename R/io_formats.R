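#' @useDynLib cistromeqc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor median rnorm rpois runif setNames
#' @importFrom utils head read.table write.table combn
NULL

# All coordinates in this package are 0-based half-open (BED convention).
# The single exception is wiggle output, where fixedStep starts are 1-based
# per the wig standard.

#' Construct a validated genomic interval table
#'
#' Intervals are 0-based half-open spans, the convention used throughout the
#' package. This helper validates and normalises a chrom/start/end triple
#' into the canonical data frame layout shared by all peak operations.
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends; must satisfy `0 <= start < end`.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad))
    stop("invalid interval at row ", bad[1],
         ": require 0 <= start < end, got [", start[bad[1]], ", ", end[bad[1]], ")")
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Read peaks from a BED / narrowPeak file
#'
#' Accepts BED3 to BED6 and ENCODE narrowPeak (BED6+4). For narrowPeak input
#' the 10th column (summit offset relative to `start`) is kept; the ENCODE
#' sentinel `-1` ("no summit called") is mapped to `NA`.
#'
#' @param path Path to a tab-separated BED-like file.
#' @param caller Optional caller label attached to every peak (e.g. `"MACS"`).
#' @param experiment_id,tf Optional provenance labels attached to every peak.
#' @return A peak data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit_offset`, `caller`, `experiment_id`, `tf`.
#' @export
read_bed <- function(path, caller = NA_character_, experiment_id = NA_character_,
                     tf = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  n <- length(lines)
  out <- data.frame(chrom = character(n), start = integer(n), end = integer(n),
                    name = NA_character_, score = NA_real_, strand = NA_character_,
                    summit_offset = NA_integer_, stringsAsFactors = FALSE)
  if (n == 0) {
    out$caller <- character(0); out$experiment_id <- character(0); out$tf <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3)
      stop("malformed BED line ", i, " in ", path, ": fewer than 3 fields")
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e))
      stop("malformed BED line ", i, " in ", path, ": non-integer coordinates")
    if (s < 0 || s >= e)
      stop("invalid interval on line ", i, " in ", path,
           ": require 0 <= start < end, got [", s, ", ", e, ")")
    out$chrom[i] <- f[1]; out$start[i] <- s; out$end[i] <- e
    if (length(f) >= 4) out$name[i] <- f[4]
    if (length(f) >= 5) out$score[i] <- suppressWarnings(as.numeric(f[5]))
    if (length(f) >= 6 && f[6] %in% c("+", "-")) out$strand[i] <- f[6]
    if (length(f) >= 10) {  # narrowPeak: col 10 is the summit offset
      sm <- suppressWarnings(as.integer(f[10]))
      if (!is.na(sm) && sm >= 0) {
        if (sm >= e - s)
          stop("invalid summit offset on line ", i, " in ", path,
               ": ", sm, " outside [0, ", e - s, ")")
        out$summit_offset[i] <- sm
      }
    }
  }
  out$caller <- caller
  out$experiment_id <- experiment_id
  out$tf <- tf
  out
}

#' Write intervals to a BED file
#'
#' Output is sorted by (chrom, start, end) and round-trips through
#' [read_bed()]. Columns beyond the first three are emitted only when the
#' input carries them (name, score, strand).
#'
#' @param intervals Data frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  x <- intervals[order(intervals$chrom, intervals$start, intervals$end), , drop = FALSE]
  ncol_out <- 3L
  has <- function(col) col %in% names(x) && any(!is.na(x[[col]]))
  if (has("strand")) ncol_out <- 6L
  else if (has("score")) ncol_out <- 5L
  else if (has("name")) ncol_out <- 4L
  cols <- list(x$chrom, x$start, x$end)
  if (ncol_out >= 4L) cols[[4]] <- ifelse(is.na(x$name), ".", x$name)
  if (ncol_out >= 5L) cols[[5]] <- ifelse(is.na(x$score), 0, x$score)
  if (ncol_out >= 6L) cols[[6]] <- ifelse(is.na(x$strand), ".", x$strand)
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write per-chromosome numeric tracks as fixedStep wiggle
#'
#' One `fixedStep chrom=<chrom> start=1 step=1 span=1` declaration per
#' chromosome, in input order. Internal 0-based coordinates become 1-based
#' wig starts. The MUL sentinel `-1` is emitted literally.
#'
#' @param values Named list, one numeric vector per chromosome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wig_fixedstep <- function(values, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (length(v) == 0) {
      warning("skipping zero-length chromosome ", chrom)
      next
    }
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1 span=1", chrom), con)
    writeLines(format(v, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased; record order is preserved; headers are
#' truncated at the first whitespace.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) stop("duplicate sequence names in ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read deduplicated tag alignments
#'
#' Tags are 5'-start records standing for filtered, deduplicated alignments:
#' a minimal 3-column TSV (`chrom`, `pos5`, `strand`) is the native format;
#' BED6 is also accepted, in which case `pos5` is taken as `start` for `+`
#' tags and `end - 1` for `-` tags.
#'
#' @param path Input path.
#' @return Data frame with columns `chrom`, `pos5`, `strand`.
#' @export
read_tags <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  nf <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (nf >= 6) {  # BED6
    strand <- x[[6]]
    pos5 <- ifelse(strand == "+", x[[2]], x[[3]] - 1L)
    out <- data.frame(chrom = x[[1]], pos5 = as.integer(pos5),
                      strand = strand, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = x[[1]], pos5 = as.integer(x[[2]]),
                      strand = x[[3]], stringsAsFactors = FALSE)
  }
  validate_tags(out)
  out
}

#' Write tags as 3-column TSV
#' @param tags Tag data frame (`chrom`, `pos5`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  validate_tags(tags)
  write.table(tags[, c("chrom", "pos5", "strand")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_tags <- function(tags) {
  stopifnot(all(c("chrom", "pos5", "strand") %in% names(tags)))
  if (nrow(tags) > 0) {
    if (any(tags$pos5 < 0)) stop("tag pos5 must be >= 0")
    if (!all(tags$strand %in% c("+", "-")))
      stop("tag strand must be '+' or '-'")
  }
  invisible(tags)
}
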