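#' Partition a chromosome into functional interval classes
#'
#' Splits every chromosome exactly once into exonic, genic-non-exonic
#' (introns; overlapping genes merged) and intergenic intervals, the unit
#' sets used for category-wise base-composition comparisons.
#'
#' @param assembly an [assembly_model].
#' @return named list of three interval data.frames (`exonic`,
#'   `genic_nonexonic`, `intergenic`); per chromosome the three sets are
#'   disjoint and cover `[0, length)`.
#' @export
partition_functional <- function(assembly) {
  lens <- chrom_lengths(assembly)
  ex <- merge_intervals(assembly$exons[, c("chrom", "start", "end")])
  gn <- merge_intervals(assembly$genes[, c("chrom", "start", "end")])
  exonic <- list(); genic <- list(); inter <- list()
  for (ch in names(lens)) {
    e <- ex[ex$chrom == ch, , drop = FALSE]
    g <- gn[gn$chrom == ch, , drop = FALSE]
    exonic[[ch]] <- e
    # genic minus exonic
    if (nrow(g)) {
      pieces <- lapply(seq_len(nrow(g)), function(i) {
        inside <- e[e$start < g$end[i] & e$end > g$start[i], , drop = FALSE]
        gaps <- complement_intervals(inside$start, inside$end, g$end[i])
        gaps <- gaps[gaps$end > g$start[i], , drop = FALSE]
        gaps$start <- pmax(gaps$start, g$start[i])
        if (nrow(gaps)) data.frame(chrom = ch, gaps) else NULL
      })
      genic[[ch]] <- do.call(rbind, pieces)
    }
    gaps <- complement_intervals(g$start, g$end, lens[[ch]])
    if (nrow(gaps)) inter[[ch]] <- data.frame(chrom = ch, gaps)
  }
  bind <- function(l) {
    out <- do.call(rbind, l)
    if (is.null(out)) out <- data.frame(chrom = character(),
                                        start = numeric(), end = numeric())
    rownames(out) <- NULL
    out[out$end > out$start, , drop = FALSE]
  }
  list(exonic = bind(exonic), genic_nonexonic = bind(genic),
       intergenic = bind(inter))
}

# Mann-Whitney U with normal approximation and tie correction (via
# wilcox.test); all-tied data take p = 1 by convention
mann_whitney <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Compare a statistic between region and background values
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie
#' correction) of region values against background values, reporting
#' medians and the direction of the shift. With fewer than 3 values per
#' group the test is skipped and only the medians reported.
#'
#' @param values_in_region,values_in_background numeric vectors (e.g. GC
#'   per 10-kb sub-window).
#' @param statistic_name label of the compared quantity.
#' @param category functional category label (`"all"`, `"intergenic"`,
#'   `"genic"`, `"exonic"`).
#' @return object of class `region_comparison`: list with the vectors,
#'   medians, `direction` (`"lower"`, `"higher"`, `"none"`), and `test`
#'   (`method`, `U`, `p`; `NULL` when skipped).
#' @export
compare_regions <- function(values_in_region, values_in_background,
                            statistic_name = "value", category = "all") {
  x <- values_in_region[!is.na(values_in_region)]
  y <- values_in_background[!is.na(values_in_background)]
  med <- c(region = stats::median(x), background = stats::median(y))
  dir <- if (isTRUE(med[1L] < med[2L])) "lower"
  else if (isTRUE(med[1L] > med[2L])) "higher" else "none"
  test <- NULL
  if (length(x) >= 3L && length(y) >= 3L) {
    mw <- mann_whitney(x, y)
    test <- list(method = "Mann-Whitney U (two-sided, normal approximation)",
                 U = mw$U, p = mw$p)
  }
  structure(list(statistic_name = statistic_name, category = category,
                 region_values = x, background_values = y,
                 medians = med, direction = dir, test = test),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("<region_comparison> %s [%s]: medians %.4g (region) vs %.4g (background), %s",
              x$statistic_name, x$category, x$medians[1L], x$medians[2L],
              x$direction))
  if (!is.null(x$test)) {
    cat(sprintf("; U = %.1f, p = %.3g", x$test$U, x$test$p))
  } else cat(" (test skipped: < 3 values in a group)")
  cat("\n")
  invisible(x)
}

#' Compare expression between gene classes
#'
#' Pairwise two-sided Mann-Whitney U tests on `log2(FPKM + 1)` between
#' gene classes (e.g. pericentromeric vs non-pericentromeric vs seed
#' orthologs). Ranks are transform-invariant, so U and p match tests on
#' raw FPKM; the log scale only affects the reported medians.
#'
#' @param expression_table data.frame (`gene_id`, `fpkm`).
#' @param gene_classes named character vector mapping gene ids to class
#'   labels.
#' @return named list of [compare_regions] results, one per class pair
#'   (`"A_vs_B"`); classes with fewer than 3 genes are skipped.
#' @export
expression_compare <- function(expression_table, gene_classes) {
  lf <- log2(expression_table$fpkm + 1)
  cls <- gene_classes[expression_table$gene_id]
  keep <- !is.na(cls)
  lf <- lf[keep]; cls <- cls[keep]
  classes <- names(which(table(cls) >= 3L))
  out <- list()
  if (length(classes) >= 2L) {
    for (i in seq_len(length(classes) - 1L)) {
      for (j in seq.int(i + 1L, length(classes))) {
        key <- paste(classes[i], classes[j], sep = "_vs_")
        out[[key]] <- compare_regions(
          lf[cls == classes[i]], lf[cls == classes[j]],
          statistic_name = "log2(FPKM+1)", category = key)
      }
    }
  }
  out
}
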