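test_that("k-mer containment scores behave like similarity scores", {
  cds <- c(g1 = rand_dna(300))
  st <- score_gene_pairs(cds, c(h1 = cds[["g1"]]))
  expect_equal(st$score, 1)

  # disjoint alphabets share no k-mers
  st2 <- score_gene_pairs(c(a = strrep("A", 50)), c(b = strrep("C", 50)),
                          k = 3)
  expect_equal(nrow(st2), 0L)  # sparse table keeps positive scores only

  # too-short gene scores zero with a warning
  expect_warning(score_gene_pairs(c(a = "ACGT"), c(b = rand_dna(100)),
                                  k = 12), "shorter than k")

  # random pairs equal a brute-force set-intersection oracle
  set.seed(61)
  kmers <- function(s, k = 12) {
    km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km)))
    unique(pmin(km, rc))
  }
  a <- setNames(replicate(5, rand_dna(150)), paste0("a", 1:5))
  base <- rand_dna(150)
  b <- setNames(c(vapply(1:3, function(i) paste0(
    substr(base, 1, 100), rand_dna(50)), ""), replicate(2, rand_dna(150))),
    paste0("b", 1:5))
  st3 <- score_gene_pairs(a, b)
  for (ga in names(a)) for (gb in names(b)) {
    got <- st3$score[st3$gene_a == ga & st3$gene_b == gb]
    want <- length(intersect(kmers(a[[ga]]), kmers(b[[gb]]))) /
      min(length(kmers(a[[ga]])), length(kmers(b[[gb]])))
    if (want > 0) expect_equal(got, want) else expect_length(got, 0L)
  }
})

test_that("reciprocal best hits keep mutual unique argmaxes only", {
  st <- data.frame(gene_a = "a", gene_b = "b", score = 0.5)
  expect_equal(nrow(reciprocal_best_hits(st)$pairs), 1L)

  # a tie for a's best drops a from pairing
  st2 <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
                    score = c(0.9, 0.9))
  m2 <- reciprocal_best_hits(st2)
  expect_equal(nrow(m2$pairs), 0L)
  expect_true("a" %in% m2$unmatched_a)

  expect_equal(nrow(reciprocal_best_hits(
    data.frame(gene_a = character(), gene_b = character(),
               score = numeric()))$pairs), 0L)

  # random score tables equal the exhaustive double-argmax oracle, and the
  # pair set is symmetric in the two species
  set.seed(77)
  for (rep in 1:5) {
    n <- 30
    st3 <- expand.grid(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                       stringsAsFactors = FALSE)
    st3$score <- round(runif(nrow(st3)), 2)  # rounding induces real ties
    st3 <- st3[st3$score > 0.2, ]
    got <- reciprocal_best_hits(st3)$pairs
    want <- oracle_rbh(st3)
    expect_equal(got$gene_a, want$gene_a)
    expect_equal(got$gene_b, want$gene_b)
    swapped <- data.frame(gene_a = st3$gene_b, gene_b = st3$gene_a,
                          score = st3$score)
    back <- reciprocal_best_hits(swapped)$pairs
    expect_equal(sort(paste(back$gene_b, back$gene_a)),
                 sort(paste(got$gene_a, got$gene_b)))
  }
})

test_that("seed regions are maximal gap-tolerant ortholog runs", {
  ref <- data.frame(gene_id = paste0("r", 1:50), chrom = "chrR",
                    start = (1:50) * 1000, end = (1:50) * 1000 + 500)
  mk_map <- function(ref_idx) {
    structure(list(pairs = data.frame(
      gene_a = paste0("q", seq_along(ref_idx)),
      gene_b = paste0("r", ref_idx), score = 1),
      unmatched_a = character(), unmatched_b = character()),
      class = "ortholog_map")
  }
  # 10 consecutive projected genes form one seed
  m <- mk_map(11:20)
  s <- detect_seed_regions(m, paste0("q", 1:10), ref)
  expect_equal(nrow(s), 1L)
  expect_equal(s$n_genes, 10L)
  expect_equal(s$start, 11000)
  expect_equal(s$end, 20500)
  expect_equal(s$size_bp, 9500)

  # positions {1,2,3, 40,41,42,43} with max_gap 2 split into two seeds
  m2 <- mk_map(c(1, 2, 3, 40, 41, 42, 43))
  s2 <- detect_seed_regions(m2, paste0("q", 1:7), ref, max_gap = 2)
  expect_equal(s2$n_genes, c(3L, 4L))
  # intervals disjoint and sorted
  expect_true(all(s2$start[-1] >= s2$end[-nrow(s2)]))

  # runs of <= 2 genes are dropped ("> 2 sequential genes")
  m3 <- mk_map(c(1, 2, 30, 31, 32))
  s3 <- detect_seed_regions(m3, paste0("q", 1:5), ref)
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$n_genes, 3L)

  # no projected genes -> empty
  expect_equal(nrow(detect_seed_regions(m, "nope", ref)), 0L)

  # gaps within tolerance are bridged
  m4 <- mk_map(c(5, 7, 9, 11))
  s4 <- detect_seed_regions(m4, paste0("q", 1:4), ref, max_gap = 2)
  expect_equal(s4$n_genes, 4L)
})

test_that("flanking genes are the nearest to the anchor, in order", {
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                      start = (0:9) * 1000 + 100, end = (0:9) * 1000 + 600,
                      strand = "+")
  chroms <- data.frame(name = "chr1", length = 10000, muller = "A",
                       cen_start = 0, cen_end = 50)
  a <- assembly_model("t", chroms, genes = genes)
  expect_equal(flanking_genes(a, "A", 3), c("g1", "g2", "g3"))
  expect_warning(all_g <- flanking_genes(a, "A", 99), "fewer than")
  expect_equal(all_g, paste0("g", 1:10))

  # interior anchor: nearest genes straddle it (distance-sort oracle)
  chroms2 <- transform(chroms, cen_start = 4500, cen_end = 4600)
  a2 <- assembly_model("t", chroms2, genes = genes)
  got <- flanking_genes(a2, "A", 4)
  mid <- (genes$start + genes$end) / 2
  want <- genes$gene_id[order(abs(mid - 4550))[1:4]]
  expect_setequal(got, want)
  expect_false(is.unsorted(match(got, genes$gene_id)))
})

test_that("synteny pairs put orthologs at their midpoints", {
  genes_a <- data.frame(gene_id = c("a1", "a2"), chrom = "c1",
                        start = c(0, 1000), end = c(100, 1100),
                        strand = "+")
  genes_b <- genes_a; genes_b$gene_id <- c("b1", "b2")
  m <- structure(list(pairs = data.frame(gene_a = c("a1", "a2"),
                                         gene_b = c("b1", "b2"),
                                         score = 1)), class = "ortholog_map")
  sp <- synteny_pairs(m, genes_a, genes_b)
  expect_equal(sp$x_a, sp$x_b)  # identity genome: points on the diagonal
  expect_equal(sp$x_a, c(50, 1050))
  m0 <- structure(list(pairs = data.frame(gene_a = character(),
                                          gene_b = character(),
                                          score = numeric())),
                  class = "ortholog_map")
  expect_equal(nrow(synteny_pairs(m0, genes_a, genes_b)), 0L)
})
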