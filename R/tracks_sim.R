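#' Simulate coverage, chromatin and expression tracks
#'
#' Emits the evidence tracks downstream callers consume, with all planted
#' quantities recoverable: windowed male/female read coverage (negative
#' binomial around the configured mean; Y contigs get near-zero female
#' coverage, collapsed-satellite contigs are inflated by their true copy
#' ratio), H3K9me3 signal/input counts in coarse windows (elevated over
#' heterochromatic regions), a fine 100-bp H3K9me3 enrichment track shaped
#' per gene class (dot-like genes: body-enriched, TSS-depleted;
#' neo-pericentromere genes: flank-enriched, body-depleted), and a
#' log-normal expression table in which pericentromeric orthologs run
#' higher than arm genes.
#'
#' @param sim a `karyo_sim`.
#' @param config the [sim_config].
#' @return list with [window_track]s `coverage_male`, `coverage_female`,
#'   `h3_signal`, `h3_input` (counts), `h3_100bp` (enrichment), and the
#'   data.frame `expression` (`gene_id`, `fpkm`, `class`).
#' @export
simulate_tracks <- function(sim, config) {
  cfg <- config
  a <- sim$assembly
  truth <- sim$truth
  with_seed(cfg$rng_seed + 104729L, {
    lens <- chrom_lengths(a)

    ## read coverage in fine windows
    win <- make_windows(lens, cfg$coverage_window)
    male_f <- rep(1, nrow(win)); female_f <- rep(1, nrow(win))
    if (!is.null(truth$unplaced)) {
      for (i in seq_len(nrow(truth$unplaced))) {
        u <- truth$unplaced[i, ]
        sel <- win$chrom == u$name
        if (u$class == "Y") {
          male_f[sel] <- 0.5
          female_f[sel] <- 0.02
        } else {
          male_f[sel] <- u$copy_ratio
          female_f[sel] <- u$copy_ratio
        }
      }
    }
    nb <- function(f) stats::rnbinom(length(f), mu = cfg$coverage_mean * f,
                                     size = cfg$coverage_dispersion)
    cov_m <- window_track(transform(win, value = nb(male_f)),
                          cfg$coverage_window, statistic = "coverage_male")
    cov_f <- window_track(transform(win, value = nb(female_f)),
                          cfg$coverage_window, statistic = "coverage_female")

    ## coarse H3K9me3 counts: enrichment follows heterochromatin truth
    hwin <- make_windows(lens, cfg$h3k9me3_window)
    het_frac <- rep(0, nrow(hwin))
    het <- merge_intervals(truth$het)
    for (ch in unique(hwin$chrom)) {
      sel <- hwin$chrom == ch
      h <- het[het$chrom == ch, , drop = FALSE]
      het_frac[sel] <- overlap_bp_per_window(hwin$start[sel], hwin$end[sel],
                                             h$start, h$end) /
        (hwin$end[sel] - hwin$start[sel])
    }
    e <- 1 + 3 * het_frac
    h3_sig <- window_track(
      transform(hwin, value = stats::rnbinom(length(e), mu = 200 * e,
                                             size = 50)),
      cfg$h3k9me3_window, statistic = "h3k9me3_signal")
    h3_inp <- window_track(
      transform(hwin, value = stats::rnbinom(length(e), mu = 200,
                                             size = 50)),
      cfg$h3k9me3_window, statistic = "h3k9me3_input")

    ## fine 100-bp enrichment with per-gene-class shapes
    fwin <- make_windows(lens, 100L)
    base <- rep(1, nrow(fwin))
    for (ch in unique(fwin$chrom)) {
      sel <- fwin$chrom == ch
      h <- het[het$chrom == ch, , drop = FALSE]
      fr <- overlap_bp_per_window(fwin$start[sel], fwin$end[sel],
                                  h$start, h$end) /
        (fwin$end[sel] - fwin$start[sel])
      base[sel] <- 1 + 4 * fr
    }
    g <- a$genes
    cls <- unname(truth$gene_class[g$gene_id])
    for (k in seq_len(nrow(g))) {
      sel <- which(fwin$chrom == g$chrom[k])
      if (!length(sel)) next
      tss <- if (g$strand[k] == "+") g$start[k] else g$end[k]
      body <- sel[fwin$start[sel] >= g$start[k] & fwin$end[sel] <= g$end[k]]
      near_tss <- sel[fwin$start[sel] >= tss - 300 & fwin$end[sel] <=
                        tss + 300]
      if (identical(cls[k], "dot")) {
        base[body] <- base[body] * 3
        base[near_tss] <- base[near_tss] * 0.1
      } else if (cls[k] %in% c("neo_peri", "peri")) {
        base[body] <- pmin(base[body], 1.2)  # body depleted vs flanks
        base[near_tss] <- pmin(base[near_tss], 0.8)
      }
    }
    h3_fine <- window_track(
      transform(fwin, value = base * stats::runif(length(base), 0.92, 1.08)),
      100L, statistic = "h3k9me3_enrichment")

    ## expression: log-normal, pericentromeric genes run ~2x higher
    mu <- ifelse(cls %in% c("neo_peri", "peri"), 4, 3)
    lf <- stats::rnorm(nrow(g), mean = mu, sd = 1)
    expression <- data.frame(gene_id = g$gene_id, fpkm = 2^lf - 1 + 1e-9,
                             class = unname(cls))

    list(coverage_male = cov_m, coverage_female = cov_f,
         h3_signal = h3_sig, h3_input = h3_inp, h3_100bp = h3_fine,
         expression = expression)
  })
}

#' Mean coverage per contig from a coverage track
#'
#' @param track a coverage [window_track].
#' @return named numeric vector of per-contig means.
#' @export
contig_mean_coverage <- function(track) {
  vapply(split(track$value, track$chrom), mean, 0)
}
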