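#' Construct a window track
#'
#' A window track is a bedGraph-like data.frame (`chrom`, `start`, `end`,
#' `value`) carrying the windowing parameters and the statistic label as
#' attributes. Windows tile each chromosome (`step = window` by default);
#' the trailing window is truncated at the chromosome end and a chromosome
#' shorter than one window yields a single window.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param window window size in bp.
#' @param step step between window starts in bp.
#' @param statistic label of the windowed statistic.
#' @return data.frame of class `window_track`.
#' @export
window_track <- function(df, window, step = window, statistic = "value") {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  structure(df, window = window, step = step, statistic = statistic,
            class = c("window_track", "data.frame"))
}

#' Window starts for one chromosome
#'
#' `ceiling((len - window)/step) + 1` windows for `len >= window`, else one.
#' @keywords internal
window_starts <- function(len, window, step = window) {
  if (window <= 0) stop("window must be positive")
  if (step <= 0) stop("step must be positive")
  n <- if (len >= window) ceiling((len - window) / step) + 1 else 1
  (seq_len(n) - 1) * step
}

make_windows <- function(assembly_or_lengths, window, step = window) {
  lens <- if (inherits(assembly_or_lengths, "assembly_model")) {
    chrom_lengths(assembly_or_lengths)
  } else assembly_or_lengths
  pieces <- lapply(names(lens), function(ch) {
    s <- window_starts(lens[[ch]], window, step)
    data.frame(chrom = ch, start = s, end = pmin(s + window, lens[[ch]]))
  })
  do.call(rbind, pieces)
}

#' Repeat-masked fraction per window
#'
#' The fraction of repeat-masked bases in fixed windows along each
#' chromosome, the quantity pericentromere boundaries are called on.
#' Repeats are merged per chromosome first so overlapping annotations do not
#' double-count; trailing partial windows are normalised by their actual
#' length.
#'
#' @param assembly an [assembly_model].
#' @param window window size in bp (100 kb by default).
#' @param step step in bp (defaults to `window`, i.e. non-overlapping tiles).
#' @param repeat_class restrict to these repeat classes (default: all).
#' @return a [window_track] with values in `[0, 1]`.
#' @export
repeat_fraction_track <- function(assembly, window = 100000L, step = window,
                                  repeat_class = NULL) {
  reps <- assembly$repeats
  if (!is.null(repeat_class)) {
    reps <- reps[reps$repeat_class %in% repeat_class, , drop = FALSE]
  }
  merged <- merge_intervals(reps)
  win <- make_windows(assembly, window, step)
  win$value <- 0
  for (ch in unique(win$chrom)) {
    wi <- win$chrom == ch
    f <- merged[merged$chrom == ch, , drop = FALSE]
    bp <- overlap_bp_per_window(win$start[wi], win$end[wi], f$start, f$end)
    win$value[wi] <- bp / (win$end[wi] - win$start[wi])
  }
  window_track(win, window, step, "repeat_fraction")
}

#' Gene density per window
#'
#' Counts genes per window; a gene is assigned to the window containing its
#' midpoint (ties to the lower window).
#'
#' @inheritParams repeat_fraction_track
#' @return a [window_track] of gene counts.
#' @export
gene_density_track <- function(assembly, window = 100000L, step = window) {
  win <- make_windows(assembly, window, step)
  win$value <- 0
  g <- assembly$genes
  if (nrow(g)) {
    mid <- floor((g$start + g$end) / 2)
    for (ch in unique(win$chrom)) {
      wi <- which(win$chrom == ch)
      m <- mid[g$chrom == ch]
      if (!length(m)) next
      # midpoint-containing window; with tiling this is floor(mid/step),
      # clamped into the trailing window
      idx <- pmin(floor(m / step) + 1L, length(wi))
      tab <- table(idx)
      win$value[wi[as.integer(names(tab))]] <- as.numeric(tab)
    }
  }
  window_track(win, window, step, "gene_density")
}

#' GC content per window
#'
#' GC = (G+C)/(A+C+G+T); ambiguous bases are excluded from the denominator
#' and windows containing only ambiguous bases are flagged missing (`NA`).
#'
#' @inheritParams repeat_fraction_track
#' @return a [window_track] with values in `[0, 1]` or `NA`.
#' @export
gc_track <- function(assembly, window = 100000L, step = window) {
  if (is.null(assembly$sequences)) stop("assembly carries no sequence")
  win <- make_windows(assembly, window, step)
  win$value <- NA_real_
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    seq <- Biostrings::DNAString(assembly$sequences[[ch]])
    for (i in wi) {
      v <- Biostrings::letterFrequency(
        Biostrings::subseq(seq, win$start[i] + 1L, win$end[i]),
        letters = c("A", "C", "G", "T"))
      denom <- sum(v)
      win$value[i] <- if (denom == 0) NA_real_ else (v["C"] + v["G"]) / denom
    }
  }
  window_track(win, window, step, "gc")
}

#' AT content of a set of intervals
#'
#' @param assembly an [assembly_model] with sequence.
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return single AT fraction over all unambiguous bases in the intervals.
#' @export
at_content <- function(assembly, intervals) {
  if (is.null(assembly$sequences)) stop("assembly carries no sequence")
  tot <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_len(nrow(intervals))) {
    seq <- Biostrings::DNAString(assembly$sequences[[intervals$chrom[i]]])
    v <- Biostrings::letterFrequency(
      Biostrings::subseq(seq, intervals$start[i] + 1L, intervals$end[i]),
      letters = c("A", "C", "G", "T"))
    tot <- tot + as.numeric(v)
  }
  if (sum(tot) == 0) return(NA_real_)
  unname((tot["A"] + tot["T"]) / sum(tot))
}

#' Library-size-normalised enrichment track
#'
#' Per-window `(signal/signal_total) / (input/input_total)`; windows with
#' zero input are flagged missing.
#'
#' @param signal_track,input_track [window_track]s of raw counts on
#'   identical windows.
#' @return a [window_track] of enrichment ratios.
#' @export
enrichment_track <- function(signal_track, input_track) {
  if (!identical(signal_track$chrom, input_track$chrom) ||
      !identical(signal_track$start, input_track$start)) {
    stop("signal and input tracks must share the same windows")
  }
  s <- signal_track$value / sum(signal_track$value)
  i <- input_track$value / sum(input_track$value)
  out <- signal_track
  out$value <- ifelse(input_track$value == 0, NA_real_, s / i)
  window_track(as.data.frame(out), attr(signal_track, "window"),
               attr(signal_track, "step"), "enrichment")
}

#' Y-linkage call from male/female coverage
#'
#' Labels a contig putatively Y-linked when its male/female mean coverage
#' ratio exceeds the cutoff (zero female coverage counts as infinite ratio).
#'
#' @param contig_coverages_male,contig_coverages_female named numeric
#'   vectors of mean coverage per contig (same names).
#' @param ratio_cutoff male/female ratio above which a contig is Y-linked.
#' @return data.frame with `contig`, `ratio`, `label` ("Y-linked" or
#'   "unassigned").
#' @export
sex_linkage_call <- function(contig_coverages_male, contig_coverages_female,
                             ratio_cutoff = 1.5) {
  stopifnot(identical(names(contig_coverages_male),
                      names(contig_coverages_female)))
  if (any(contig_coverages_male < 0) || any(contig_coverages_female < 0)) {
    stop("coverages must be non-negative")
  }
  ratio <- ifelse(contig_coverages_female == 0, Inf,
                  contig_coverages_male / contig_coverages_female)
  data.frame(contig = names(contig_coverages_male), ratio = as.numeric(ratio),
             label = ifelse(ratio > ratio_cutoff, "Y-linked", "unassigned"))
}

#' Metagene profile of a 100-bp signal track
#'
#' Averages a fine-grained enrichment signal over genes: gene bodies are
#' length-scaled into `n_body_bins`, flanks kept in fixed 100-bp bins, and
#' minus-strand genes are reversed before averaging, so the profile reads
#' upstream flank, TSS, body, TES, downstream flank.
#'
#' @param genes data.frame (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param track a [window_track] at 100-bp resolution.
#' @param flank_bp flank size in bp on each side (multiple of 100).
#' @param n_body_bins number of length-scaled bins across the gene body.
#' @return numeric vector of per-bin means of length
#'   `2 * flank_bp/100 + n_body_bins`, with attributes `n_genes` and
#'   `n_skipped` (genes shorter than `n_body_bins` bp are skipped).
#' @export
metagene_profile <- function(genes, track, flank_bp = 2000L, n_body_bins = 40L) {
  bin <- attr(track, "window")
  n_flank <- as.integer(flank_bp / bin)
  prof <- matrix(NA_real_, nrow = nrow(genes),
                 ncol = 2L * n_flank + n_body_bins)
  skipped <- 0L
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    ti <- by_chrom[[g$chrom]]
    if (is.null(ti)) next
    vals <- track$value[ti]
    starts <- track$start[ti]
    if (g$end - g$start < n_body_bins) { skipped <- skipped + 1L; next }
    at <- function(pos) { # signal at bp position via its containing bin
      idx <- floor(pos / bin) + 1L
      idx <- pmax(1L, pmin(idx, length(vals)))
      vals[idx]
    }
    up <- at(seq(g$start - flank_bp, g$start - 1, by = bin))
    body_edges <- seq(g$start, g$end, length.out = n_body_bins + 1L)
    body <- vapply(seq_len(n_body_bins), function(b) {
      mean(at(seq(body_edges[b], body_edges[b + 1L] - 1, by = bin)),
           na.rm = TRUE)
    }, 0)
    down <- at(seq(g$end, g$end + flank_bp - 1, by = bin))
    row <- c(up, body, down)
    if (identical(g$strand, "-")) row <- rev(row)
    prof[gi, ] <- row
  }
  out <- colMeans(prof, na.rm = TRUE)
  structure(out, n_genes = nrow(genes) - skipped, n_skipped = skipped,
            n_flank_bins = n_flank, n_body_bins = n_body_bins)
}

#' Write / read a bedGraph-like track
#'
#' @param track a [window_track] (or bedGraph-like data.frame).
#' @param path file path.
#' @return `read_track` returns a [window_track].
#' @export
write_track <- function(track, path) {
  df <- as.data.frame(track)[, c("chrom", "start", "end", "value")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_track
#' @param window,step,statistic windowing metadata to attach on read.
#' @export
read_track <- function(path, window = NULL, step = window,
                       statistic = "value") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (is.null(window)) window <- df$end[1L] - df$start[1L]
  if (is.null(step)) step <- window
  window_track(df, window, step, statistic)
}
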