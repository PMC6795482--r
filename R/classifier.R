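#' Per-element karyotype state for transition classification
#'
#' Bundles what the classifier needs to know about one Muller element in
#' one species: the chromosome, its centromere anchor, the called
#' pericentromere, and the genes inside it.
#'
#' @param assembly an [assembly_model].
#' @param element Muller label.
#' @param pericentromere_call the [call_pericentromere] result for the
#'   element's chromosome.
#' @return object of class `element_state`.
#' @export
element_state <- function(assembly, element, pericentromere_call) {
  ch <- assembly$chromosomes[assembly$chromosomes$muller == element, ,
                             drop = FALSE]
  if (nrow(ch) == 0L) stop("no chromosome with Muller label ", element)
  ch <- ch[1L, ]
  g <- assembly$genes[assembly$genes$chrom == ch$name, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  peri <- pericentromere_call
  if (is.null(peri) || is.na(peri$start)) {
    stop("element ", element, " has no pericentromere call")
  }
  mid <- (g$start + g$end) / 2
  structure(list(
    species = assembly$species, element = element, chrom = ch$name,
    chrom_length = ch$length,
    anchor = c(ch$cen_start, ch$cen_end),
    anchor_side = anchor_side(ch$cen_start, ch$cen_end, ch$length),
    peri = c(peri$start, peri$end),
    peri_genes = g$gene_id[mid >= peri$start & mid < peri$end],
    genes = g), class = "element_state")
}

map_lookup <- function(ortholog_map, ids, reverse = FALSE) {
  pr <- ortholog_map$pairs
  if (reverse) stats::setNames(pr$gene_a, pr$gene_b)[ids]
  else stats::setNames(pr$gene_b, pr$gene_a)[ids]
}

#' Classify the centromere transition between two karyotype states
#'
#' Decision rules on pericentromeric gene-set overlap and the placement of
#' centromere-flanking orthologs:
#' \itemize{
#'   \item \strong{conserved} — the orthologs of A's centromere-flanking
#'     genes are pericentric and adjacent in B and the anchor sides agree;
#'   \item \strong{pericentric_inversion} — at least `min_shared` orthologs
#'     are pericentric in both species (part of the old pericentromere
#'     travelled with the centromere);
#'   \item \strong{repositioning} — essentially no shared pericentric
#'     orthologs, and A's pericentric genes map far from B's centromere
#'     (at least `far_bp` and `far_frac` of the chromosome);
#'   \item \strong{ambiguous} — anything else (complex histories).
#' }
#'
#' @param state_a,state_b [element_state]s of the same Muller element in
#'   two species.
#' @param ortholog_map ortholog map with A's genes on the A side.
#' @param min_shared shared-ortholog count that signals an inversion.
#' @param far_bp,far_frac distance defining "far from the centromere".
#' @param n_flank number of centromere-flanking genes examined for the
#'   conserved rule.
#' @param adjacency_gap maximum intervening genes for flanking orthologs to
#'   count as adjacent in B.
#' @return object of class `transition_call`: list with `element`, `call`,
#'   and `evidence` (`n_shared_pericentric_orthologs`, `flank_distance_bp`,
#'   `flank_distance_fraction_of_chrom`).
#' @export
classify_transition <- function(state_a, state_b, ortholog_map,
                                min_shared = 3L, far_bp = 2e6,
                                far_frac = 0.10, n_flank = 10L,
                                adjacency_gap = 2L) {
  a <- state_a; b <- state_b
  orth_of_a_peri <- map_lookup(ortholog_map, a$peri_genes)
  orth_of_a_peri <- orth_of_a_peri[!is.na(orth_of_a_peri)]
  shared <- intersect(orth_of_a_peri, b$peri_genes)
  n_shared <- length(shared)

  b_mid <- stats::setNames((b$genes$start + b$genes$end) / 2, b$genes$gene_id)
  b_anchor_mid <- mean(b$anchor)
  dist_to_anchor <- function(ids) {
    pos <- b_mid[ids[ids %in% names(b_mid)]]
    if (!length(pos)) return(NA_real_)
    abs(stats::median(pos) - b_anchor_mid)
  }

  # flanking-gene evidence
  a_mid <- (a$genes$start + a$genes$end) / 2
  flank_a <- a$genes$gene_id[order(abs(a_mid - mean(a$anchor)))]
  flank_a <- flank_a[seq_len(min(n_flank, length(flank_a)))]
  flank_orth <- map_lookup(ortholog_map, flank_a)
  flank_orth <- flank_orth[!is.na(flank_orth)]
  flank_dist <- dist_to_anchor(flank_orth)

  flank_conserved <- FALSE
  if (length(flank_orth) >= 2L) {
    idx <- match(flank_orth, b$genes$gene_id)
    idx <- sort(idx[!is.na(idx)])
    adjacent <- length(idx) >= 2L && all(diff(idx) <= adjacency_gap + 1L)
    pericentric <- mean(flank_orth %in% b$peri_genes) >= 0.5
    flank_conserved <- adjacent && pericentric &&
      identical(a$anchor_side, b$anchor_side)
  }

  peri_dist <- dist_to_anchor(orth_of_a_peri)
  call <- if (flank_conserved) {
    "conserved"
  } else if (n_shared >= min_shared) {
    "pericentric_inversion"
  } else if (!is.na(peri_dist) && peri_dist >= far_bp &&
             peri_dist >= far_frac * b$chrom_length) {
    "repositioning"
  } else {
    "ambiguous"
  }
  structure(list(element = a$element, call = call,
                 evidence = list(
                   n_shared_pericentric_orthologs = n_shared,
                   flank_distance_bp = flank_dist,
                   flank_distance_fraction_of_chrom =
                     flank_dist / b$chrom_length)),
            class = "transition_call")
}

#' @export
print.transition_call <- function(x, ...) {
  cat(sprintf("<transition_call> Muller %s: %s (shared peri orthologs %d, flank distance %.2f Mb = %.0f%% of chrom)\n",
              x$element, x$call,
              x$evidence$n_shared_pericentric_orthologs,
              x$evidence$flank_distance_bp / 1e6,
              100 * x$evidence$flank_distance_fraction_of_chrom))
  invisible(x)
}

#' Detect element fusions between two assemblies
#'
#' Reports a fusion when orthologs of two distinct Muller elements of
#' species A co-locate on a single chromosome of species B, together with
#' the junction neighbourhood (the innermost gene of each block). Three-way
#' co-locations produce one pair per element couple, with a warning.
#'
#' @param assembly_a,assembly_b the two assemblies.
#' @param ortholog_map map with A's genes on the A side.
#' @param min_genes minimum orthologs per element on the shared chromosome.
#' @return data.frame (`element_1`, `element_2`, `chrom_b`,
#'   `junction_gene_1`, `junction_gene_2`, `n_genes_1`, `n_genes_2`).
#' @export
detect_fusion <- function(assembly_a, assembly_b, ortholog_map,
                          min_genes = 5L) {
  empty <- data.frame(element_1 = character(), element_2 = character(),
                      chrom_b = character(), junction_gene_1 = character(),
                      junction_gene_2 = character(), n_genes_1 = integer(),
                      n_genes_2 = integer())
  pr <- ortholog_map$pairs
  if (!nrow(pr)) return(empty)
  ga <- assembly_a$genes
  gb <- assembly_b$genes
  el_a <- stats::setNames(
    assembly_a$chromosomes$muller[match(ga$chrom,
                                        assembly_a$chromosomes$name)],
    ga$gene_id)
  df <- data.frame(element = el_a[pr$gene_a],
                   gene_b = pr$gene_b,
                   chrom_b = gb$chrom[match(pr$gene_b, gb$gene_id)],
                   pos_b = gb$start[match(pr$gene_b, gb$gene_id)])
  df <- df[!is.na(df$element) & !is.na(df$chrom_b), , drop = FALSE]
  rows <- list()
  for (ch in unique(df$chrom_b)) {
    d <- df[df$chrom_b == ch, , drop = FALSE]
    counts <- table(d$element)
    els <- names(counts)[counts >= min_genes]
    if (length(els) < 2L) next
    if (length(els) > 2L) {
      warning("more than two elements co-locate on ", ch)
    }
    for (i in seq_len(length(els) - 1L)) {
      for (j in seq.int(i + 1L, length(els))) {
        b1 <- d[d$element == els[i], ]
        b2 <- d[d$element == els[j], ]
        # innermost gene of each block: the one facing the other block
        if (stats::median(b1$pos_b) <= stats::median(b2$pos_b)) {
          j1 <- b1$gene_b[which.max(b1$pos_b)]
          j2 <- b2$gene_b[which.min(b2$pos_b)]
        } else {
          j1 <- b1$gene_b[which.min(b1$pos_b)]
          j2 <- b2$gene_b[which.max(b2$pos_b)]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          element_1 = els[i], element_2 = els[j], chrom_b = ch,
          junction_gene_1 = j1, junction_gene_2 = j2,
          n_genes_1 = as.integer(counts[els[i]]),
          n_genes_2 = as.integer(counts[els[j]]))
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match ancestral pericentromere genes to paleocentromere islands
#'
#' Counts, per island, the orthologs of an ancestral pericentromeric gene
#' set that reside inside the island — the expected signature of a
#' deactivated pericentromere retaining its gene complement.
#'
#' @param islands island data.frame from [detect_paleocentromeres].
#' @param ancestral_pericentromere_genes character vector of ancestral
#'   (species A) gene ids.
#' @param ortholog_map map with ancestral genes on the A side.
#' @param genes_b gene data.frame of the derived species.
#' @return data.frame with one row per island (`chrom`, `start`, `end`,
#'   `n_matched`, `fraction_of_ancestral_set`). The fraction is over
#'   ancestral genes that have an ortholog.
#' @export
paleocentromere_gene_match <- function(islands,
                                       ancestral_pericentromere_genes,
                                       ortholog_map, genes_b) {
  if (nrow(islands) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_matched = integer(),
                      fraction_of_ancestral_set = numeric()))
  }
  orth <- map_lookup(ortholog_map, ancestral_pericentromere_genes)
  orth <- orth[!is.na(orth)]
  m <- match(orth, genes_b$gene_id)
  pos_chrom <- genes_b$chrom[m]
  pos_mid <- (genes_b$start[m] + genes_b$end[m]) / 2
  out <- islands[, c("chrom", "start", "end")]
  out$n_matched <- vapply(seq_len(nrow(islands)), function(i) {
    sum(pos_chrom == islands$chrom[i] & pos_mid >= islands$start[i] &
          pos_mid < islands$end[i], na.rm = TRUE)
  }, 0L)
  out$fraction_of_ancestral_set <-
    if (length(orth)) out$n_matched / length(orth) else NA_real_
  out
}
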