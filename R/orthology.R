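#' k-mer containment scores between two gene sets
#'
#' A light-weight stand-in for protein-alignment bit scores: the score of a
#' gene pair is the number of shared canonical k-mers between their coding
#' sequences, normalised by the k-mer count of the shorter sequence, hence
#' in `[0, 1]`. A precomputed score table may be supplied to
#' [reciprocal_best_hits] instead, preserving fidelity for users who run a
#' real aligner.
#'
#' @param cds_a,cds_b named character vectors of coding sequences.
#' @param k k-mer size; a gene shorter than `k` scores 0 against everything
#'   (with a warning).
#' @return data.frame (`gene_a`, `gene_b`, `score`) holding all pairs with
#'   a positive score (a sparse score table).
#' @export
score_gene_pairs <- function(cds_a, cds_b, k = 12L) {
  kmer_set <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    km <- substring(s, seq_len(n - k + 1L), seq.int(k, n))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km)))
    unique(pmin(km, rc))
  }
  sets_a <- lapply(cds_a, kmer_set)
  sets_b <- lapply(cds_b, kmer_set)
  short <- c(names(cds_a)[lengths(sets_a) == 0L],
             names(cds_b)[lengths(sets_b) == 0L])
  if (length(short)) {
    warning("gene(s) shorter than k scored 0: ",
            paste(short, collapse = ", "))
  }
  # invert B for sparse intersection counting
  tab_b <- data.frame(
    kmer = unlist(sets_b, use.names = FALSE),
    gene_b = rep(names(cds_b), lengths(sets_b)))
  rows <- lapply(names(cds_a), function(ga) {
    sa <- sets_a[[ga]]
    if (!length(sa)) return(NULL)
    hit <- tab_b[tab_b$kmer %in% sa, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    shared <- table(hit$gene_b)
    gb <- names(shared)
    denom <- pmin(length(sa), lengths(sets_b[gb]))
    data.frame(gene_a = ga, gene_b = gb,
               score = as.numeric(shared) / denom)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Reciprocal-best-hit ortholog map
#'
#' Keeps a pair `(a, b)` iff `b` is the unique best-scoring partner of `a`
#' and `a` the unique best-scoring partner of `b`. A tie for the top score
#' drops the gene from pairing (deterministically), and such genes are
#' reported as unmatched.
#'
#' @param score_table data.frame (`gene_a`, `gene_b`, `score`) with
#'   non-negative scores; absent pairs score 0.
#' @return object of class `ortholog_map`: list with `pairs` (data.frame
#'   `gene_a`, `gene_b`, `score`), `unmatched_a`, `unmatched_b`.
#' @export
reciprocal_best_hits <- function(score_table) {
  all_a <- unique(as.character(score_table$gene_a))
  all_b <- unique(as.character(score_table$gene_b))
  empty <- function() {
    structure(list(pairs = data.frame(gene_a = character(),
                                      gene_b = character(),
                                      score = numeric()),
                   unmatched_a = all_a, unmatched_b = all_b),
              class = "ortholog_map")
  }
  st <- score_table[score_table$score > 0, , drop = FALSE]
  if (nrow(st) == 0L) return(empty())
  if (any(st$score < 0)) stop("scores must be non-negative")

  best_of <- function(keys, scores) {
    # unique argmax per key, NA on ties
    sp <- split(seq_along(keys), keys)
    vapply(sp, function(idx) {
      s <- scores[idx]
      top <- idx[s == max(s)]
      if (length(top) == 1L) top else NA_integer_
    }, 0L)
  }
  ba <- best_of(as.character(st$gene_a), st$score)  # row index per gene_a
  bb <- best_of(as.character(st$gene_b), st$score)  # row index per gene_b
  keep <- intersect(ba[!is.na(ba)], bb[!is.na(bb)])
  pairs <- st[keep, c("gene_a", "gene_b", "score"), drop = FALSE]
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(all_a, pairs$gene_a),
                 unmatched_b = setdiff(all_b, pairs$gene_b)),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d pairs, %d/%d unmatched\n",
              nrow(x$pairs), length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Detect pericentromere seed regions in a reference gene order
#'
#' Projects the pericentromeric genes of a query species through an
#' ortholog map onto the gene order of a reference chromosome and finds
#' maximal runs of projected genes in which consecutive members are
#' separated by at most `max_gap` intervening non-projected genes. Runs
#' with more than two members delimit the ancestral regions in which a new
#' pericentromere was founded.
#'
#' @param ortholog_map an [reciprocal_best_hits] map with query genes on
#'   the A side and reference genes on the B side.
#' @param query_pericentromere_genes character vector of query gene ids
#'   inside the query pericentromere.
#' @param reference_gene_order data.frame of the reference chromosome's
#'   genes in positional order (`gene_id`, `chrom`, `start`, `end`).
#' @param max_gap allowed intervening non-projected genes within a run.
#' @param min_run minimum genes per reported seed (default, "more than
#'   two").
#' @return data.frame with one row per seed: `chrom`, `start`, `end`,
#'   `n_genes`, `size_bp`, and `genes` (list column of member ids in
#'   reference order); seeds are disjoint and sorted.
#' @export
detect_seed_regions <- function(ortholog_map, query_pericentromere_genes,
                                reference_gene_order, max_gap = 2L,
                                min_run = 3L) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_genes = integer(),
                      size_bp = numeric())
  empty$genes <- list()
  pr <- ortholog_map$pairs
  mapped <- pr$gene_b[pr$gene_a %in% query_pericentromere_genes]
  pos <- sort(match(mapped, reference_gene_order$gene_id))
  pos <- pos[!is.na(pos)]
  if (!length(pos)) return(empty)
  gap <- diff(pos)
  run_id <- cumsum(c(1L, as.integer(gap > max_gap + 1L)))
  rows <- lapply(split(pos, run_id), function(run) {
    if (length(run) < min_run) return(NULL)
    g <- reference_gene_order[run, , drop = FALSE]
    out <- data.frame(chrom = g$chrom[1L], start = min(g$start),
                      end = max(g$end), n_genes = length(run),
                      size_bp = max(g$end) - min(g$start))
    out$genes <- list(g$gene_id)
    out
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes flanking the centromere anchor
#'
#' The `n` genes of an element nearest its centromere anchor, returned in
#' chromosomal order — the marker set used to compare centromere-adjacent
#' synteny between karyotypes.
#'
#' @param assembly an [assembly_model].
#' @param element Muller label.
#' @param n number of genes.
#' @return character vector of gene ids in chromosomal order (all genes,
#'   with a warning, if the element has fewer than `n`).
#' @export
flanking_genes <- function(assembly, element, n = 30L) {
  ch <- assembly$chromosomes[assembly$chromosomes$muller == element, ,
                             drop = FALSE]
  if (nrow(ch) == 0L) stop("no chromosome with Muller label ", element)
  ch <- ch[1L, ]
  g <- assembly$genes[assembly$genes$chrom == ch$name, , drop = FALSE]
  if (nrow(g) < n) {
    warning("element ", element, " has fewer than ", n, " genes")
    n <- nrow(g)
  }
  anchor_mid <- (ch$cen_start + ch$cen_end) / 2
  mid <- (g$start + g$end) / 2
  nearest <- order(abs(mid - anchor_mid))[seq_len(n)]
  g$gene_id[nearest][order(g$start[nearest])]
}

#' Ortholog midpoint pairs for synteny dot plots
#'
#' @param ortholog_map an ortholog map.
#' @param genes_a,genes_b gene data.frames of the two species.
#' @return data.frame (`gene_a`, `gene_b`, `chrom_a`, `x_a`, `chrom_b`,
#'   `x_b`) of midpoint coordinates, one row per ortholog pair.
#' @export
synteny_pairs <- function(ortholog_map, genes_a, genes_b) {
  pr <- ortholog_map$pairs
  ma <- match(pr$gene_a, genes_a$gene_id)
  mb <- match(pr$gene_b, genes_b$gene_id)
  keep <- !is.na(ma) & !is.na(mb)
  data.frame(gene_a = pr$gene_a[keep], gene_b = pr$gene_b[keep],
             chrom_a = genes_a$chrom[ma[keep]],
             x_a = (genes_a$start[ma[keep]] + genes_a$end[ma[keep]]) / 2,
             chrom_b = genes_b$chrom[mb[keep]],
             x_b = (genes_b$start[mb[keep]] + genes_b$end[mb[keep]]) / 2)
}
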