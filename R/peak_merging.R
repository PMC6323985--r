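# Union-of-overlaps (single-linkage) merging of peak sets across callers and
# experiments. Overlap means >= 1 shared base under half-open coordinates;
# abutting intervals do not merge. The merged-peak "frequency" counts
# constituent peaks, not distinct callers: two overlapping peaks from the
# same caller contribute 2. A per-caller presence matrix is kept alongside
# for the two-source Chapman estimator.

as_peak_df <- function(peaks, caller = NULL) {
  stopifnot(is.data.frame(peaks), all(c("chrom", "start", "end") %in% names(peaks)))
  x <- peaks
  if (!is.null(caller)) x$caller <- caller
  for (col in c("caller", "experiment_id", "tf"))
    if (!col %in% names(x)) x[[col]] <- rep(NA_character_, nrow(x))
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad)) stop("invalid peak interval at row ", bad[1])
  x
}

peaks_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' Merge peak sets from several callers into merged peaks
#'
#' Single-linkage union of overlapping intervals: any chain of pairwise
#' overlapping peaks collapses into one merged peak spanning their union.
#' Strand is ignored.
#'
#' @param peak_sets Either a named list of peak data frames (names are
#'   caller labels) or a single data frame with a `caller` column.
#' @return A merged-peak data frame, sorted, with columns `chrom`, `start`,
#'   `end`, `frequency` (number of constituent peaks), `n_callers`, and
#'   list-columns `callers`, `experiments`, `constituents` (row indices into
#'   the pooled input). The pooled input is attached as attribute `"peaks"`.
#' @export
merge_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) {
    pooled <- as_peak_df(peak_sets)
  } else {
    stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
    labs <- names(peak_sets)
    if (is.null(labs)) labs <- paste0("caller", seq_along(peak_sets))
    sets <- lapply(seq_along(peak_sets), function(i) {
      p <- as_peak_df(peak_sets[[i]])
      if (all(is.na(p$caller))) p$caller <- labs[i]
      p
    })
    pooled <- do.call(rbind, sets)
  }
  if (nrow(pooled) == 0)
    return(empty_merged(pooled))
  gr <- peaks_to_granges(pooled)
  # min.gapwidth = 0 merges overlapping ranges only; abutting stay apart
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  red <- GenomicRanges::sort(red)
  hits <- GenomicRanges::findOverlaps(gr, red, minoverlap = 1L)
  grp <- integer(nrow(pooled))
  grp[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  members <- split(seq_len(nrow(pooled)), grp)
  members <- members[as.character(seq_along(red))]
  callers <- lapply(members, function(ix) sort(unique(pooled$caller[ix])))
  expers <- lapply(members, function(ix)
    sort(unique(pooled$experiment_id[ix][!is.na(pooled$experiment_id[ix])])))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    frequency = lengths(members),
    n_callers = lengths(callers),
    stringsAsFactors = FALSE)
  out$callers <- unname(callers)
  out$experiments <- unname(expers)
  out$constituents <- unname(members)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "peaks") <- pooled
  class(out) <- c("merged_peaks", class(out))
  out
}

empty_merged <- function(pooled) {
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    frequency = integer(0), n_callers = integer(0))
  out$callers <- list(); out$experiments <- list(); out$constituents <- list()
  attr(out, "peaks") <- pooled
  class(out) <- c("merged_peaks", class(out))
  out
}

#' Frequency spectrum of merged peaks
#'
#' `f[k]` is the number of merged peaks built from exactly `k` constituent
#' peaks; the spectrum (`f1`, `f2`, `f3`, ...) is the input to every
#' capture-recapture estimator.
#'
#' @param merged A `merged_peaks` data frame from [merge_peaks()].
#' @return List of class `freq_spectrum`: `S` (number of merged peaks),
#'   `f` (named integer vector, names are frequencies), `total` (sum of
#'   `k * f_k`, i.e. the number of input peaks).
#' @export
frequency_spectrum <- function(merged) {
  if (nrow(merged) == 0)
    return(structure(list(S = 0L, f = setNames(integer(0), character(0)),
                          total = 0L), class = "freq_spectrum"))
  tab <- table(merged$frequency)
  f <- setNames(as.integer(tab), names(tab))
  structure(list(S = nrow(merged), f = f,
                 total = sum(as.integer(names(f)) * f)),
            class = "freq_spectrum")
}

#' Build a frequency spectrum directly from counts
#' @param f Named integer vector mapping frequency k to the count `f_k`.
#' @return A `freq_spectrum` object.
#' @export
spectrum_from_counts <- function(f) {
  k <- as.integer(names(f))
  stopifnot(!any(is.na(k)), all(k >= 1), all(f >= 0))
  f <- setNames(as.integer(f), names(f))
  structure(list(S = sum(f), f = f, total = sum(k * f)), class = "freq_spectrum")
}

spectrum_f <- function(spectrum, k) {
  v <- unname(spectrum$f[as.character(k)])
  ifelse(is.na(v), 0L, as.integer(v))
}

#' Per-caller presence matrix of merged peaks
#'
#' @param merged A `merged_peaks` data frame.
#' @return Logical matrix, merged peaks x callers: does a caller contribute
#'   at least one constituent peak to the merged peak.
#' @export
caller_presence <- function(merged) {
  callers <- sort(unique(unlist(merged$callers)))
  m <- matrix(FALSE, nrow = nrow(merged), ncol = length(callers),
              dimnames = list(NULL, callers))
  for (i in seq_len(nrow(merged))) m[i, merged$callers[[i]]] <- TRUE
  m
}

#' Build clusters: merged peaks for one TF and one caller across experiments
#'
#' @param peaks Peak data frame; all rows must share `tf` and `caller`.
#' @return A `merged_peaks` data frame whose `experiments` list-column
#'   records the contributing experiment ids.
#' @export
build_clusters <- function(peaks) {
  peaks <- as_peak_df(peaks)
  if (length(unique(peaks$caller[!is.na(peaks$caller)])) > 1)
    stop("build_clusters requires peaks from a single caller")
  if (length(unique(peaks$tf[!is.na(peaks$tf)])) > 1)
    stop("build_clusters requires peaks for a single TF")
  merge_peaks(peaks)
}

#' Build meta-clusters: clusters merged across callers for one TF
#'
#' Meta-clusters are the non-redundant binding-site set: the union of
#' overlapping clusters coming from different peak-calling methods,
#' optionally filtered to those supported by at least `min_callers`
#' distinct callers.
#'
#' @param cluster_sets Named list (caller -> `merged_peaks` from
#'   [build_clusters()]) for one TF.
#' @param min_callers Minimum number of supporting callers to retain
#'   (default 1).
#' @return A `merged_peaks`-style data frame with `n_callers`, `callers`
#'   and `experiments` columns describing support.
#' @export
build_metaclusters <- function(cluster_sets, min_callers = 1L) {
  stopifnot(is.list(cluster_sets))
  if (length(cluster_sets) == 0) return(empty_merged(as_peak_df(
    data.frame(chrom = character(0), start = integer(0), end = integer(0)))))
  labs <- names(cluster_sets)
  if (is.null(labs)) labs <- paste0("caller", seq_along(cluster_sets))
  flat <- lapply(seq_along(cluster_sets), function(i) {
    cl <- cluster_sets[[i]]
    data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
               caller = labs[i],
               experiment_id = vapply(cl$experiments, function(e)
                 paste(e, collapse = ","), character(1)),
               tf = NA_character_, stringsAsFactors = FALSE)
  })
  flat <- do.call(rbind, flat)
  flat$experiment_id[!nzchar(flat$experiment_id)] <- NA_character_
  mc <- merge_peaks(flat)
  mc$experiments <- lapply(mc$experiments, function(e)
    sort(unique(unlist(strsplit(e, ",", fixed = TRUE)))))
  mc[mc$n_callers >= min_callers, , drop = FALSE]
}

#' Write merged peaks as BED
#'
#' The caller list goes in the name column (comma-separated) and the
#' frequency in the score column.
#'
#' @param merged A `merged_peaks` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merged_bed <- function(merged, path) {
  x <- data.frame(chrom = merged$chrom, start = merged$start, end = merged$end,
                  name = vapply(merged$callers, paste, character(1), collapse = ","),
                  score = merged$frequency, stringsAsFactors = FALSE)
  write_bed(x, path)
}
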