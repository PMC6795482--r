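#' Call a pericentromere from a repeat-fraction track
#'
#' Starting at the centromere anchor, windows are scanned outward (in both
#' directions for an interior anchor) and the pericentromere boundary is set
#' at the start of the first run of `min_below` consecutive windows whose
#' repeat fraction falls below `cutoff`. The run requirement keeps a single
#' euchromatic gap from truncating the call.
#'
#' @param repeat_track a [window_track] of repeat fractions for a single
#'   chromosome.
#' @param anchor centromere anchor as `c(start, end)` in bp (0-based
#'   half-open). An anchor touching position 0 or the chromosome end is
#'   treated as terminal.
#' @param cutoff repeat fraction defining pericentromeric windows (e.g. 0.2
#'   for a compact repeat-poor genome, 0.4 otherwise).
#' @param min_below number of consecutive sub-cutoff windows that terminate
#'   the scan.
#' @param element optional element label carried into the call.
#' @return object of class `pericentromere_call`: list with `element`,
#'   `chrom`, `start`, `end`, `size_bp`, `mean_repeat_fraction`,
#'   `anchor_side` ("left_end", "right_end" or "interior") and `note`
#'   ("ok", "whole_chromosome" or "empty"). An anchor window already below
#'   the cutoff yields an empty call with a diagnostic note.
#' @export
call_pericentromere <- function(repeat_track, anchor, cutoff, min_below = 3L,
                                element = NA_character_) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  ch <- unique(repeat_track$chrom)
  if (length(ch) != 1L) stop("repeat_track must cover a single chromosome")
  ord <- order(repeat_track$start)
  v <- repeat_track$value[ord]
  ws <- repeat_track$start[ord]
  we <- repeat_track$end[ord]
  chrom_len <- max(we)
  if (anchor[1] < 0 || anchor[2] > chrom_len) {
    stop("anchor outside the chromosome")
  }
  side <- anchor_side(anchor[1], anchor[2], chrom_len)

  # windows overlapping the anchor interval
  a_win <- which(ws < anchor[2] & we > anchor[1])
  if (all(v[a_win] < cutoff)) {
    warning("anchor window(s) below cutoff; empty pericentromere call")
    return(new_peri_call(element, ch, NA, NA, 0, NA, side, "empty"))
  }

  # first index of a run of min_below consecutive sub-cutoff values in x,
  # or NA when no such run exists
  first_run <- function(x) {
    r <- rle(x < cutoff)
    pos <- cumsum(c(1L, r$lengths))
    hit <- which(r$values & r$lengths >= min_below)
    if (!length(hit)) NA_integer_ else pos[hit[1L]]
  }

  if (side == "left_end") {
    b <- first_run(v)
    if (is.na(b)) {
      warning("no euchromatic boundary found; whole-chromosome call")
      return(new_peri_call(element, ch, 0, chrom_len,
                           chrom_len, mean(v), side, "whole_chromosome"))
    }
    s <- 0; e <- ws[b]
    sel <- seq_len(b - 1L)
  } else if (side == "right_end") {
    b <- first_run(rev(v))
    if (is.na(b)) {
      warning("no euchromatic boundary found; whole-chromosome call")
      return(new_peri_call(element, ch, 0, chrom_len,
                           chrom_len, mean(v), side, "whole_chromosome"))
    }
    n <- length(v)
    s <- we[n - b + 1L]; e <- chrom_len
    sel <- seq.int(n - b + 2L, n)
  } else {
    iL <- min(a_win); iR <- max(a_win)
    bR <- first_run(v[seq.int(iR, length(v))])
    bL <- first_run(rev(v[seq_len(iL)]))
    e <- if (is.na(bR)) chrom_len else ws[iR + bR - 1L]
    s <- if (is.na(bL)) 0 else we[iL - bL + 1L]
    if (is.na(bR) && is.na(bL)) {
      warning("no euchromatic boundary found; whole-chromosome call")
      return(new_peri_call(element, ch, 0, chrom_len, chrom_len, mean(v),
                           side, "whole_chromosome"))
    }
    sel <- which(ws >= s & we <= e)
  }
  new_peri_call(element, ch, s, e, e - s,
                if (length(sel)) mean(v[sel]) else NA_real_, side, "ok")
}

new_peri_call <- function(element, chrom, start, end, size_bp, mean_rf,
                          side, note) {
  structure(list(element = element, chrom = chrom, start = start, end = end,
                 size_bp = size_bp, mean_repeat_fraction = mean_rf,
                 anchor_side = side, note = note),
            class = "pericentromere_call")
}

#' @export
print.pericentromere_call <- function(x, ...) {
  cat(sprintf("<pericentromere_call> %s %s:%s-%s (%.2f Mb, mean rf %.2f, %s, %s)\n",
              x$element, x$chrom, format(x$start), format(x$end),
              x$size_bp / 1e6, x$mean_repeat_fraction, x$anchor_side, x$note))
  invisible(x)
}

#' Detect paleocentromere islands
#'
#' Interior islands retaining the repeat and heterochromatin signature of a
#' former pericentromere: maximal runs of windows whose repeat fraction is
#' at least `repeat_factor` times the euchromatic background (the mean
#' repeat fraction outside the called pericentromere), spanning at least
#' `min_span` bp, lying at least `exclusion_bp` from the called
#' pericentromere, and (when a chromatin track is supplied) with mean
#' H3K9me3 enrichment above the chromosome median.
#'
#' @param repeat_track single-chromosome [window_track] of repeat fractions.
#' @param h3k9me3_track optional [window_track] of H3K9me3 enrichment on the
#'   same chromosome (any window size); `NULL` flags calls "repeat-only".
#' @param pericentromere_call the [call_pericentromere] result for this
#'   chromosome.
#' @param min_span minimum island span in bp.
#' @param repeat_factor fold-enrichment over euchromatic background.
#' @param exclusion_bp minimum distance from the called pericentromere.
#' @param genes optional gene data.frame to count resident genes (midpoint
#'   inside the island).
#' @return data.frame with one row per island: `chrom`, `start`, `end`,
#'   `mean_repeat_fraction`, `mean_h3k9me3`, `n_resident_genes`, `flag`.
#' @export
detect_paleocentromeres <- function(repeat_track, h3k9me3_track = NULL,
                                    pericentromere_call,
                                    min_span = 250000L, repeat_factor = 2.5,
                                    exclusion_bp = 1000000L, genes = NULL) {
  ord <- order(repeat_track$start)
  v <- repeat_track$value[ord]
  ws <- repeat_track$start[ord]
  we <- repeat_track$end[ord]
  ch <- unique(repeat_track$chrom)

  peri <- pericentromere_call
  outside <- if (is.na(peri$start)) rep(TRUE, length(v)) else
    we <= peri$start | ws >= peri$end
  background <- mean(v[outside])
  far <- if (is.na(peri$start)) rep(TRUE, length(v)) else
    we <= peri$start - exclusion_bp | ws >= peri$end + exclusion_bp
  qual <- v >= repeat_factor * background & far

  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      mean_repeat_fraction = numeric(),
                      mean_h3k9me3 = numeric(), n_resident_genes = integer(),
                      flag = character())
  r <- rle(qual)
  pos <- cumsum(c(1L, r$lengths))
  runs <- which(r$values)
  if (!length(runs)) return(empty)

  h3_med <- if (!is.null(h3k9me3_track)) {
    stats::median(h3k9me3_track$value, na.rm = TRUE)
  } else NA_real_

  rows <- lapply(runs, function(k) {
    i <- pos[k]; j <- pos[k + 1L] - 1L
    s <- ws[i]; e <- we[j]
    if (e - s < min_span) return(NULL)
    h3 <- NA_real_
    if (!is.null(h3k9me3_track)) {
      hi <- h3k9me3_track$start < e & h3k9me3_track$end > s
      h3 <- mean(h3k9me3_track$value[hi], na.rm = TRUE)
      if (!is.na(h3) && h3 <= h3_med) return(NULL)
    }
    ng <- 0L
    if (!is.null(genes)) {
      mid <- floor((genes$start + genes$end) / 2)
      ng <- sum(genes$chrom == ch & mid >= s & mid < e)
    }
    data.frame(chrom = ch, start = s, end = e,
               mean_repeat_fraction = mean(v[i:j]), mean_h3k9me3 = h3,
               n_resident_genes = ng,
               flag = if (is.null(h3k9me3_track)) "repeat-only" else "ok")
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
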