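#' @importFrom IRanges IRanges reduce findOverlaps pintersect width start end
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All coordinates in this package are 0-based half-open: an interval covers
# [start, end) and its length is end - start. BED files are native; GFF3 is
# shifted by -1 on start at the I/O boundary.

#' Validate an interval data frame
#'
#' Checks the package-wide coordinate invariants (0 <= start < end <= length
#' of the chromosome the feature sits on) for a data frame of intervals.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param what label used in error messages (e.g. "gene", "repeat").
#' @return `x`, invisibly, if all intervals validate.
#' @keywords internal
validate_intervals <- function(x, chrom_lengths, what = "feature") {
  if (nrow(x) == 0L) return(invisible(x))
  unknown <- setdiff(unique(x$chrom), names(chrom_lengths))
  if (length(unknown) > 0L) {
    stop(sprintf("%s(s) on unknown chromosome(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  bad <- x$start < 0 | x$end <= x$start
  if (any(bad)) {
    stop(sprintf("invalid %s interval (need 0 <= start < end): row %d",
                 what, which(bad)[1L]), call. = FALSE)
  }
  over <- x$end > chrom_lengths[as.character(x$chrom)]
  if (any(over)) {
    i <- which(over)[1L]
    id <- if ("gene_id" %in% names(x)) x$gene_id[i] else
      sprintf("%s:%d-%d", x$chrom[i], x$start[i], x$end[i])
    stop(sprintf("%s '%s' extends beyond the end of chromosome %s",
                 what, id, x$chrom[i]), call. = FALSE)
  }
  invisible(x)
}

#' Merge overlapping intervals
#'
#' Collapses overlapping or bookended intervals into their union, per
#' chromosome and optionally per grouping column (e.g. repeat family), so
#' that summed widths count each masked base once.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @param by optional name of a column to merge within (e.g. `"family"`).
#' @return data.frame of disjoint intervals with the same columns
#'   (`chrom`, `start`, `end`, and `by` if given), sorted by chromosome and
#'   start.
#' @export
merge_intervals <- function(x, by = NULL) {
  cols <- c("chrom", "start", "end", by)
  if (nrow(x) == 0L) {
    out <- x[, cols, drop = FALSE]
    return(out)
  }
  key <- if (is.null(by)) as.character(x$chrom) else
    paste(x$chrom, x[[by]], sep = "\r")
  pieces <- lapply(split(seq_len(nrow(x)), key), function(idx) {
    ir <- IRanges::reduce(IRanges(start = x$start[idx] + 1L, end = x$end[idx]))
    out <- data.frame(chrom = x$chrom[idx[1L]],
                      start = IRanges::start(ir) - 1L,
                      end = IRanges::end(ir))
    if (!is.null(by)) out[[by]] <- x[[by]][idx[1L]]
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), cols, drop = FALSE]
}

# Total bp of (merged) intervals overlapping each of a set of windows.
# windows and feats are 0-based half-open data.frames on a single chromosome.
overlap_bp_per_window <- function(win_start, win_end, feat_start, feat_end) {
  bp <- numeric(length(win_start))
  if (length(feat_start) == 0L) return(bp)
  w <- IRanges(start = win_start + 1L, end = win_end)
  f <- IRanges(start = feat_start + 1L, end = feat_end)
  hits <- IRanges::findOverlaps(w, f)
  if (length(hits) == 0L) return(bp)
  ov <- IRanges::width(IRanges::pintersect(w[S4Vectors::queryHits(hits)],
                                           f[S4Vectors::subjectHits(hits)]))
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  bp[as.integer(names(agg))] <- as.numeric(agg)
  bp
}

# Complement of a set of merged intervals within [0, len).
complement_intervals <- function(merged_start, merged_end, len) {
  if (length(merged_start) == 0L) {
    return(data.frame(start = 0, end = len))
  }
  o <- order(merged_start)
  s <- merged_start[o]; e <- merged_end[o]
  gaps_start <- c(0, e)
  gaps_end <- c(s, len)
  keep <- gaps_end > gaps_start
  data.frame(start = gaps_start[keep], end = gaps_end[keep])
}
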