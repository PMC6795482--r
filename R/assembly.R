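#' Construct an assembly model
#'
#' The central container for one species: chromosome records (with Muller
#' labels and centromere anchors), gene and exon annotations, repeat
#' annotations, optional sequences, and optional coding sequences. All
#' coordinates are 0-based half-open.
#'
#' @param species species label.
#' @param chromosomes data.frame with columns `name`, `length`, `muller`
#'   (one of A-F, fused labels such as "A-D", or "unplaced"), `cen_start`,
#'   `cen_end` (centromere anchor interval; `NA` for no anchor). A
#'   chromosome is telocentric when its anchor touches position 0 or its
#'   length.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#'   Exons must nest within their gene, be sorted and non-overlapping.
#' @param repeats data.frame with columns `chrom`, `start`, `end`, `family`,
#'   `repeat_class` (one of "TE", "satellite", "other").
#' @param sequences optional named character vector (or
#'   [Biostrings::DNAStringSet]) of chromosome sequences.
#' @param cds optional named character vector of per-gene coding sequences.
#' @return object of class `assembly_model`.
#' @export
assembly_model <- function(species, chromosomes, genes = empty_genes(),
                           exons = empty_exons(), repeats = empty_repeats(),
                           sequences = NULL, cds = NULL) {
  chromosomes$name <- as.character(chromosomes$name)
  stopifnot(!anyDuplicated(chromosomes$name))
  lens <- stats::setNames(as.numeric(chromosomes$length), chromosomes$name)
  if (any(lens <= 0)) stop("chromosome lengths must be positive")

  genes$chrom <- as.character(genes$chrom)
  repeats$chrom <- as.character(repeats$chrom)
  if (nrow(exons)) exons$chrom <- as.character(exons$chrom)
  validate_intervals(genes, lens, "gene")
  validate_intervals(repeats, lens, "repeat")
  validate_intervals(exons, lens, "exon")
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  if (nrow(repeats) && any(!nzchar(repeats$family))) {
    stop("repeat family labels must be non-empty")
  }
  if (nrow(exons)) {
    m <- match(exons$gene_id, genes$gene_id)
    if (anyNA(m)) stop("exon references unknown gene_id: ",
                       exons$gene_id[which(is.na(m))[1L]])
    bad <- exons$start < genes$start[m] | exons$end > genes$end[m] |
      exons$chrom != genes$chrom[m]
    if (any(bad)) stop("exon outside its gene: gene ",
                       exons$gene_id[which(bad)[1L]])
    ord <- order(match(exons$gene_id, genes$gene_id), exons$start)
    exons <- exons[ord, , drop = FALSE]
    sp <- split(seq_len(nrow(exons)), exons$gene_id)
    for (idx in sp) {
      if (length(idx) > 1L &&
          any(exons$start[idx][-1L] < exons$end[idx][-length(idx)])) {
        stop("overlapping exons in gene ", exons$gene_id[idx[1L]])
      }
    }
  }
  anc <- !is.na(chromosomes$cen_start)
  if (any(anc)) {
    bad <- chromosomes$cen_start[anc] < 0 |
      chromosomes$cen_end[anc] > chromosomes$length[anc] |
      chromosomes$cen_end[anc] <= chromosomes$cen_start[anc]
    if (any(bad)) stop("centromere anchor outside [0, length] on chromosome ",
                       chromosomes$name[anc][which(bad)[1L]])
  }
  if (!is.null(sequences)) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
    miss <- setdiff(names(sequences), chromosomes$name)
    if (length(miss)) stop("sequence for unknown chromosome: ", miss[1L])
    nc <- nchar(sequences)
    if (any(nc != lens[names(sequences)])) {
      stop("sequence length disagrees with chromosome record for ",
           names(sequences)[which(nc != lens[names(sequences)])[1L]])
    }
  }
  rownames(chromosomes) <- rownames(genes) <- rownames(repeats) <- NULL
  structure(list(species = species, chromosomes = chromosomes, genes = genes,
                 exons = exons, repeats = repeats, sequences = sequences,
                 cds = cds),
            class = "assembly_model")
}

empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(), start = numeric(),
             end = numeric(), strand = character())
}
empty_exons <- function() {
  data.frame(gene_id = character(), chrom = character(), start = numeric(),
             end = numeric())
}
empty_repeats <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             family = character(), repeat_class = character())
}

#' @export
print.assembly_model <- function(x, ...) {
  placed <- x$chromosomes$muller != "unplaced"
  cat(sprintf("<assembly_model> %s\n", x$species))
  cat(sprintf("  %d placed chromosome(s), %d unplaced contig(s), %.1f Mb total\n",
              sum(placed), sum(!placed), sum(x$chromosomes$length) / 1e6))
  cat(sprintf("  %d genes, %d exons, %d repeat features%s\n",
              nrow(x$genes), nrow(x$exons), nrow(x$repeats),
              if (is.null(x$sequences)) "" else " (+sequence)"))
  invisible(x)
}

#' Chromosome length lookup
#' @param assembly an `assembly_model`.
#' @return named numeric vector of lengths.
#' @export
chrom_lengths <- function(assembly) {
  stats::setNames(as.numeric(assembly$chromosomes$length),
                  assembly$chromosomes$name)
}

# side of the centromere anchor: "left_end", "right_end" or "interior"
anchor_side <- function(cen_start, cen_end, length) {
  if (is.na(cen_start)) return(NA_character_)
  if (cen_start <= 0) "left_end"
  else if (cen_end >= length) "right_end"
  else "interior"
}

#' Read an assembly model from FASTA plus annotation files
#'
#' Sequences are read with [Biostrings::readDNAStringSet]; gene models from
#' GFF3 (1-based inclusive; shifted by -1 on start) or BED (already 0-based
#' half-open); repeats from BED6 where the name column is `family` or
#' `family;repeat_class`. Every feature is validated against the chromosome
#' lengths taken from the FASTA.
#'
#' @param fasta_path path to the genome FASTA.
#' @param gene_annotation_path path to a GFF3 (`gene`/`exon` records, exons
#'   carrying `Parent`) or BED file of genes; `NULL` for none.
#' @param repeat_annotation_path path to a BED file of repeats; `NULL` for
#'   none.
#' @param species species label (defaults to the FASTA basename).
#' @return an [assembly_model].
#' @export
read_assembly <- function(fasta_path, gene_annotation_path = NULL,
                          repeat_annotation_path = NULL,
                          species = sub("\\.[^.]*$", "", basename(fasta_path))) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chromosomes <- data.frame(name = names(seqs),
                            length = Biostrings::width(seqs),
                            muller = "unplaced",
                            cen_start = NA_real_, cen_end = NA_real_)
  genes <- empty_genes(); exons <- empty_exons()
  if (!is.null(gene_annotation_path) && file.size(gene_annotation_path) > 0) {
    if (grepl("\\.bed$", gene_annotation_path, ignore.case = TRUE)) {
      gr <- rtracklayer::import(gene_annotation_path, format = "BED")
      genes <- data.frame(
        gene_id = if (!is.null(gr$name)) as.character(gr$name) else
          paste0("g", seq_along(gr)),
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1,
        end = as.numeric(GenomicRanges::end(gr)),
        strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"))
    } else {
      gr <- rtracklayer::import(gene_annotation_path, format = "GFF3")
      ty <- as.character(gr$type)
      g <- gr[ty == "gene"]
      genes <- data.frame(
        gene_id = as.character(g$ID),
        chrom = as.character(GenomicRanges::seqnames(g)),
        start = GenomicRanges::start(g) - 1,
        end = as.numeric(GenomicRanges::end(g)),
        strand = ifelse(as.character(GenomicRanges::strand(g)) == "-", "-", "+"))
      e <- gr[ty == "exon"]
      if (length(e)) {
        exons <- data.frame(
          gene_id = vapply(e$Parent, function(p) as.character(p)[1L], ""),
          chrom = as.character(GenomicRanges::seqnames(e)),
          start = GenomicRanges::start(e) - 1,
          end = as.numeric(GenomicRanges::end(e)))
      }
    }
  }
  repeats <- empty_repeats()
  if (!is.null(repeat_annotation_path) && file.size(repeat_annotation_path) > 0) {
    gr <- rtracklayer::import(repeat_annotation_path, format = "BED")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else
      rep("repeat", length(gr))
    parts <- strsplit(nm, ";", fixed = TRUE)
    repeats <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = as.numeric(GenomicRanges::end(gr)),
      family = vapply(parts, `[`, "", 1L),
      repeat_class = vapply(parts, function(p)
        if (length(p) > 1L) p[2L] else "TE", ""))
  }
  assembly_model(species, chromosomes, genes, exons, repeats,
                 sequences = as.character(seqs))
}

#' Write an assembly model to FASTA / GFF3 / BED
#'
#' Emits `<species>.fa` (if sequences are present), `<species>.genes.gff3`,
#' and `<species>.repeats.bed`, the formats [read_assembly] accepts.
#'
#' @param assembly an [assembly_model].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_assembly <- function(assembly, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  if (!is.null(assembly$sequences)) {
    fa <- file.path(dir, paste0(assembly$species, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(assembly$sequences), fa, width = 80L)
    files["fasta"] <- fa
  }
  gff <- file.path(dir, paste0(assembly$species, ".genes.gff3"))
  g <- assembly$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  gr$type <- "gene"; gr$ID <- g$gene_id
  if (nrow(assembly$exons)) {
    e <- assembly$exons
    er <- GenomicRanges::GRanges(
      seqnames = e$chrom,
      ranges = IRanges(start = e$start + 1L, end = e$end),
      strand = g$strand[match(e$gene_id, g$gene_id)])
    er$type <- "exon"; er$ID <- NA_character_
    er$Parent <- as.character(e$gene_id)
    gr$Parent <- NA_character_
    gr <- c(gr, er)
  }
  rtracklayer::export(gr, gff, format = "GFF3")
  files["genes"] <- gff
  bed <- file.path(dir, paste0(assembly$species, ".repeats.bed"))
  r <- assembly$repeats
  if (nrow(r)) {
    br <- GenomicRanges::GRanges(
      seqnames = r$chrom,
      ranges = IRanges(start = r$start + 1L, end = r$end))
    br$name <- paste(r$family, r$repeat_class, sep = ";")
    br$score <- 0L
    rtracklayer::export(br, bed, format = "BED")
  } else {
    file.create(bed)
  }
  files["repeats"] <- bed
  invisible(files)
}
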