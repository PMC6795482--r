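#' Per-Muller-element karyotype summary table
#'
#' Summarises assembled length, contig count and pericentromere size per
#' Muller element, with an exact-sum totals row — the per-species accounting
#' used to compare assemblies across a clade.
#'
#' Two input forms are accepted: an [assembly_model] (lengths are summed per
#' Muller label; contigs counted per label), or a pre-summarised data.frame
#' with columns `element`, `length_bp`, `n_contigs` (e.g. transcribed from a
#' published table).
#'
#' @param x an `assembly_model` or a data.frame (see Details).
#' @param pericentromere_calls optional named numeric vector of
#'   pericentromere sizes in bp, keyed by Muller element, or a list of
#'   `pericentromere_call` objects.
#' @return data.frame with columns `element`, `length_bp`, `n_contigs`,
#'   `pericentromere_mb` (1 decimal) and a final `total` row whose entries
#'   are exact column sums.
#' @export
karyotype_table <- function(x, pericentromere_calls = NULL) {
  if (inherits(x, "assembly_model")) {
    ch <- x$chromosomes[x$chromosomes$muller != "unplaced", , drop = FALSE]
    el <- unique(ch$muller)
    rows <- data.frame(
      element = el,
      length_bp = vapply(el, function(m) sum(ch$length[ch$muller == m]), 0),
      n_contigs = vapply(el, function(m) sum(ch$muller == m), 0L))
  } else {
    rows <- data.frame(element = as.character(x$element),
                       length_bp = as.numeric(x$length_bp),
                       n_contigs = as.integer(x$n_contigs))
  }
  peri_bp <- rep(NA_real_, nrow(rows))
  if (!is.null(pericentromere_calls)) {
    if (is.list(pericentromere_calls) && !is.data.frame(pericentromere_calls) &&
        !is.numeric(pericentromere_calls)) {
      pericentromere_calls <- vapply(
        pericentromere_calls, function(p) as.numeric(p$size_bp), 0)
    }
    extra <- setdiff(names(pericentromere_calls), rows$element)
    if (length(extra)) {
      stop("pericentromere call for element absent from assembly: ",
           paste(extra, collapse = ", "))
    }
    m <- match(rows$element, names(pericentromere_calls))
    peri_bp <- as.numeric(pericentromere_calls)[m]
  }
  rows$pericentromere_mb <- round(peri_bp / 1e6, 1)
  total <- data.frame(element = "total",
                      length_bp = sum(rows$length_bp),
                      n_contigs = sum(rows$n_contigs),
                      pericentromere_mb =
                        if (all(is.na(rows$pericentromere_mb))) NA_real_
                        else sum(rows$pericentromere_mb, na.rm = TRUE))
  out <- rbind(rows, total)
  rownames(out) <- NULL
  out
}

#' Transposable-element composition table
#'
#' Per-family masked-bp accounting in the style of genome-paper TE tables:
#' overlapping annotations are merged within each family before summing
#' (RepeatMasker "bases masked" semantics), families are sorted by masked bp
#' descending, and the top `top_n` are reported above a total row.
#'
#' @param repeats data.frame of repeat features (`chrom`, `start`, `end`,
#'   `family`, `repeat_class`; only `repeat_class == "TE"` rows are used), or
#'   a named numeric vector of pre-merged masked bp per family.
#' @param assembly_total_bp total assembly length in bp.
#' @param top_n number of families to report individually.
#' @return data.frame with columns `family`, `masked_bp`, `pct_of_genome`
#'   (1 decimal), `pct_of_te` (nearest integer); first row is the total over
#'   all TE families.
#' @export
te_composition_table <- function(repeats, assembly_total_bp, top_n = 5L) {
  if (!is.numeric(assembly_total_bp) || assembly_total_bp <= 0) {
    stop("assembly_total_bp must be a positive number")
  }
  if (is.numeric(repeats) && !is.null(names(repeats))) {
    fam_bp <- sort(repeats, decreasing = TRUE)
  } else {
    te <- repeats[repeats$repeat_class == "TE", , drop = FALSE]
    if (nrow(te) == 0L) {
      return(data.frame(family = "total_TE", masked_bp = 0,
                        pct_of_genome = 0, pct_of_te = NA_real_))
    }
    merged <- merge_intervals(te, by = "family")
    fam_bp <- tapply(merged$end - merged$start, merged$family, sum)
    fam_bp <- sort(stats::setNames(as.numeric(fam_bp), names(fam_bp)),
                   decreasing = TRUE)
  }
  total_bp <- sum(fam_bp)
  keep <- utils::head(fam_bp, top_n)
  out <- data.frame(
    family = c("total_TE", names(keep)),
    masked_bp = c(total_bp, as.numeric(keep)))
  out$pct_of_genome <- round(100 * out$masked_bp / assembly_total_bp, 1)
  out$pct_of_te <- c(NA_real_, round(100 * as.numeric(keep) / total_bp))
  rownames(out) <- NULL
  out
}

#' Pericentromere vs seed-region size accounting
#'
#' Contrasts the size of derived pericentromeres with the ancestral seed
#' regions they grew from, per element and combined (components summed
#' before dividing).
#'
#' @param pericentromere_bp named numeric vector of pericentromere sizes,
#'   keyed by element.
#' @param seed_bp named numeric vector of total seed-region sizes for the
#'   same elements (same units as `pericentromere_bp`).
#' @return data.frame with columns `element`, `pericentromere_bp`,
#'   `seed_bp`, `fold_change`, plus a `combined` row; a zero seed size
#'   yields `fold_change = Inf` and a `degenerate` flag.
#' @export
size_accounting <- function(pericentromere_bp, seed_bp) {
  el <- names(pericentromere_bp)
  if (is.null(el) || !setequal(el, names(seed_bp))) {
    stop("pericentromere_bp and seed_bp must be named by the same elements")
  }
  seed_bp <- seed_bp[el]
  out <- data.frame(element = c(el, "combined"),
                    pericentromere_bp = c(as.numeric(pericentromere_bp),
                                          sum(pericentromere_bp)),
                    seed_bp = c(as.numeric(seed_bp), sum(seed_bp)))
  out$fold_change <- ifelse(out$seed_bp == 0, Inf,
                            out$pericentromere_bp / out$seed_bp)
  out$degenerate <- out$seed_bp == 0
  rownames(out) <- NULL
  out
}
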