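test_that("read_assembly parses FASTA + GFF3/BED with coordinate conversion", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "toy.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    c(chr1 = strrep("ACGT", 2500))), fa)

  # empty annotations -> one chromosome, no features
  empty_gff <- file.path(dir, "empty.gff3")
  writeLines("##gff-version 3", empty_gff)
  a0 <- read_assembly(fa, empty_gff, NULL)
  expect_s3_class(a0, "assembly_model")
  expect_equal(nrow(a0$chromosomes), 1L)
  expect_equal(nrow(a0$genes), 0L)

  # GFF3 is 1-based inclusive: start=1,end=100 becomes [0,100), length 100
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t1\t100\t.\t+\t.\tID=gA",
               "chr1\ttoy\texon\t1\t40\t.\t+\t.\tParent=gA",
               "chr1\ttoy\tgene\t201\t300\t.\t-\t.\tID=gB"), gff)
  a1 <- read_assembly(fa, gff, NULL)
  expect_equal(a1$genes$start[a1$genes$gene_id == "gA"], 0)
  expect_equal(a1$genes$end[a1$genes$gene_id == "gA"], 100)
  expect_equal(a1$genes$strand[a1$genes$gene_id == "gB"], "-")
  expect_equal(a1$exons$start, 0)
  expect_equal(a1$exons$end, 40)

  # BED genes are native half-open; lengths equal end - start
  bed <- file.path(dir, "genes.bed")
  writeLines(c("chr1\t0\t500\tg1\t0\t+",
               "chr1\t1000\t1600\tg2\t0\t-",
               "chr1\t9000\t9900\tg3\t0\t+"), bed)
  a2 <- read_assembly(fa, bed, NULL)
  expect_equal(a2$genes$end - a2$genes$start, c(500, 600, 900))
})

test_that("read_assembly rejects out-of-range and unknown-chromosome features", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "toy.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    c(chr1 = strrep("ACGT", 25))), fa)
  bad <- file.path(dir, "bad.bed")
  writeLines("chr1\t50\t200\tgX\t0\t+", bad)
  expect_error(read_assembly(fa, bad, NULL), "beyond the end")
  unk <- file.path(dir, "unk.bed")
  writeLines("chr9\t0\t10\tgX\t0\t+", unk)
  expect_error(read_assembly(fa, unk, NULL), "unknown chromosome")
})

test_that("write/read round-trip preserves intervals and sequences", {
  set.seed(71)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(100, 3000), end = c(1100, 4200),
                      strand = c("+", "-"))
  exons <- data.frame(gene_id = c("g1", "g1", "g2"), chrom = "chr1",
                      start = c(100, 700, 3000), end = c(400, 1100, 4200))
  reps <- data.frame(chrom = "chr1", start = c(2000, 5000),
                     end = c(2600, 5800), family = c("famA", "satX"),
                     repeat_class = c("TE", "satellite"))
  a <- toy_assembly(len = 10000, genes = genes, repeats = reps,
                    exons = exons, sequence = rand_dna(10000))
  dir <- withr::local_tempdir()
  files <- write_assembly(a, dir)
  b <- read_assembly(files["fasta"], files["genes"], files["repeats"],
                     species = "toy")
  expect_equal(b$genes[order(b$genes$gene_id), names(genes)],
               genes, ignore_attr = TRUE)
  ord <- order(b$exons$gene_id, b$exons$start)
  expect_equal(b$exons[ord, names(exons)], exons, ignore_attr = TRUE)
  expect_equal(b$repeats[order(b$repeats$start), names(reps)],
               reps, ignore_attr = TRUE)
  expect_identical(unname(b$sequences["chr1"]), unname(a$sequences["chr1"]))
})

test_that("assembly_model enforces its invariants", {
  chroms <- data.frame(name = "chr1", length = 1000, muller = "A",
                       cen_start = 0, cen_end = 50)
  g <- data.frame(gene_id = c("g1", "g1"), chrom = "chr1",
                  start = c(0, 100), end = c(50, 150), strand = "+")
  expect_error(assembly_model("x", chroms, genes = g), "duplicate gene_id")
  e <- data.frame(gene_id = "g1", chrom = "chr1", start = 60, end = 90)
  g2 <- g[1, ]
  expect_error(assembly_model("x", chroms, genes = g2, exons = e),
               "exon outside its gene")
})

test_that("karyotype_table reproduces published per-element accounting", {
  # printed per-element assembly lengths and contig counts of the species
  # with the ancestral karyotype
  rows <- data.frame(
    element = c("A", "D", "B", "C", "E", "F"),
    length_bp = c(24182865, 23815339, 25941769, 20343353, 30159154,
                  1505893),
    n_contigs = c(9, 8, 5, 1, 3, 4))
  tab <- karyotype_table(rows)
  tot <- tab[tab$element == "total", ]
  expect_identical(tot$length_bp, 125948373)
  expect_identical(tot$n_contigs, 30L)
  # totals equal naive summation
  expect_equal(tot$length_bp, sum(rows$length_bp))
  expect_equal(tot$n_contigs, sum(rows$n_contigs))
})

test_that("karyotype_table handles assemblies, calls and errors", {
  a <- toy_assembly(len = 12345)
  tab <- karyotype_table(a)
  expect_equal(tab$length_bp[tab$element == "total"], 12345)
  tab2 <- karyotype_table(a, c(A = 2.5e3))
  expect_equal(tab2$pericentromere_mb[tab2$element == "A"], 0.0)
  expect_error(karyotype_table(a, c(Z = 1e6)), "absent from assembly")
})

test_that("te_composition_table reproduces published percentages", {
  fams <- c(Dpse_Gypsy_6 = 1319782, CR1_1_DPer = 449484,
            Gypsy8_I_Dpse = 424330, LOA_1_DPer = 331166,
            T213_X.Unknown = 323480)
  # remaining TE bp folded into one family so the total matches the
  # printed genome-wide figure
  fams <- c(fams, other = 7572806 - sum(fams))
  tab <- te_composition_table(fams, assembly_total_bp = 125948373,
                              top_n = length(fams))
  expect_equal(tab$masked_bp[tab$family == "total_TE"], 7572806)
  expect_equal(tab$pct_of_genome[tab$family == "total_TE"], 6.0)
  expect_equal(tab$pct_of_te[tab$family == "Dpse_Gypsy_6"], 17)
  # single family covering all TE bp
  tab1 <- te_composition_table(c(only = 1000), 10000)
  expect_equal(tab1$pct_of_te[tab1$family == "only"], 100)
  expect_error(te_composition_table(fams, 0), "positive")
})

test_that("te_composition_table merges overlaps per family and conserves bp", {
  set.seed(5)
  reps <- data.frame(chrom = "chr1",
                     start = c(0, 50, 200, 400, 390),
                     end = c(100, 150, 300, 500, 450),
                     family = c("f1", "f1", "f2", "f2", "f2"),
                     repeat_class = "TE")
  tab <- te_composition_table(reps, 1000, top_n = 10)
  expect_equal(tab$masked_bp[tab$family == "f1"], 150)  # 0-150 merged
  expect_equal(tab$masked_bp[tab$family == "f2"], 210)  # 200-300 + 390-500
  # unrounded family shares sum to one
  fam <- tab[tab$family != "total_TE", ]
  expect_equal(sum(fam$masked_bp) / tab$masked_bp[1], 1, tolerance = 1e-9)
})

test_that("merged interval accounting matches a per-base bitmap", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 30
    s <- sample(0:900, n)
    feats <- data.frame(chrom = "chr1", start = s,
                        end = s + sample(10:120, n, replace = TRUE))
    feats$end <- pmin(feats$end, 1000)
    merged <- merge_intervals(feats)
    bitmap <- logical(1000)
    for (i in seq_len(n)) bitmap[(feats$start[i] + 1):feats$end[i]] <- TRUE
    expect_equal(sum(merged$end - merged$start), sum(bitmap))
    # merged intervals are disjoint and sorted
    expect_true(all(diff(merged$start) > 0))
    expect_true(all(merged$start[-1] >= merged$end[-nrow(merged)]))
  }
})
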