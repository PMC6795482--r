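test_that("the ancestor has the expected telocentric structure", {
  cfg <- sim_config(n_elements = 5, include_dot = TRUE,
                    emit_sequence = FALSE, rng_seed = 2)
  anc <- build_ancestor(cfg)
  ch <- anc$assembly$chromosomes
  placed <- ch[ch$muller != "unplaced", ]
  expect_equal(sort(placed$muller), c("A", "B", "C", "D", "E", "F"))
  # every element is telocentric: anchor touches an end
  expect_true(all(placed$cen_start == 0))
  # config validation
  expect_error(sim_config(element_length = 1e5, peri_length = 4e5),
               "shorter than its pericentromere")
  expect_error(sim_config(background_gc = 1.2))
  expect_error(sim_config(nonsense = 1), "unused argument")
})

test_that("same seed gives byte-identical output, different seed differs", {
  cfg <- sim_config(n_elements = 1, include_dot = FALSE,
                    element_length = 1e6, rng_seed = 5)
  a1 <- build_ancestor(cfg)
  a2 <- build_ancestor(cfg)
  expect_identical(a1$assembly$sequences, a2$assembly$sequences)
  expect_identical(a1$assembly$genes, a2$assembly$genes)
  cfg2 <- cfg; cfg2$rng_seed <- 6
  a3 <- build_ancestor(cfg2)
  expect_false(identical(a1$assembly$sequences, a3$assembly$sequences))
})

test_that("seed windows carry the planted GC deficit", {
  cfg <- sim_config(n_elements = 2, include_dot = FALSE, rng_seed = 8)
  anc <- build_ancestor(cfg)
  gt <- gc_track(anc$assembly, 1e4)
  seeds <- anc$truth$seeds
  inseed <- rep(FALSE, nrow(gt))
  for (i in seq_len(nrow(seeds))) {
    inseed <- inseed | (gt$chrom == seeds$chrom[i] &
                          gt$start >= seeds$start[i] &
                          gt$end <= seeds$end[i])
  }
  expect_gte(sum(inseed), 40)
  expect_lt(mean(gt$value[inseed], na.rm = TRUE),
            mean(gt$value[!inseed], na.rm = TRUE))
})

test_that("an empty event log reproduces the ancestor", {
  cfg <- sim_config(n_elements = 1, include_dot = FALSE,
                    emit_sequence = FALSE, rng_seed = 3)
  anc <- build_ancestor(cfg)
  der <- evolve(anc, list(), cfg)
  expect_identical(der$assembly$genes, anc$assembly$genes)
  expect_identical(der$assembly$repeats, anc$assembly$repeats)
  expect_identical(der$assembly$chromosomes, anc$assembly$chromosomes)
})

test_that("replaying the same log is a pure function of (ancestor, seed)", {
  cfg <- sim_config(n_elements = 1, include_dot = FALSE, rng_seed = 9,
                    element_length = 1.5e6)
  anc <- build_ancestor(cfg)
  ev <- list(sim_event("reposition", "A"))
  d1 <- evolve(anc, ev, cfg)
  d2 <- evolve(anc, ev, cfg)
  expect_identical(d1$assembly$sequences, d2$assembly$sequences)
  expect_identical(d1$assembly$repeats, d2$assembly$repeats)
  expect_identical(d1$truth$peri, d2$truth$peri)
})

test_that("a pericentric inversion exactly reverses the gene order", {
  cfg <- sim_config(n_elements = 1, include_dot = FALSE,
                    emit_sequence = FALSE, rng_seed = 13)
  anc <- build_ancestor(cfg)
  b2 <- 1.6e6
  der <- evolve(anc, list(sim_event("pericentric_inversion", "A",
                                    b1 = 0, b2 = b2)), cfg)
  g0 <- anc$assembly$genes[order(anc$assembly$genes$start), ]
  g1 <- der$assembly$genes[order(der$assembly$genes$start), ]
  inside0 <- g0$gene_id[g0$end <= b2]
  inside1 <- g1$gene_id[g1$end <= b2]
  expect_equal(inside1, rev(inside0))
  # gene set unchanged, strands flipped inside the segment
  expect_setequal(g1$gene_id, g0$gene_id)
  s0 <- setNames(g0$strand, g0$gene_id)
  s1 <- setNames(g1$strand, g1$gene_id)
  expect_true(all(s1[inside0] != s0[inside0]))
  outside <- setdiff(g0$gene_id, inside0)
  expect_true(all(s1[outside] == s0[outside]))
  # centromere anchor moved to the interior
  ci <- der$assembly$chromosomes[1, ]
  expect_gt(ci$cen_start, 0)
  expect_lt(ci$cen_end, ci$length)
})

test_that("repositioning deactivates the old pericentromere", {
  sc <- simulate_scenario("reposition", seed = 17)
  der <- sc$derived
  pal <- der$truth$paleo
  r <- der$assembly$repeats
  in_pal <- r$chrom == pal$chrom & r$start >= pal$start & r$end <= pal$end
  # satellite bp in the old pericentromere is zero
  expect_equal(sum(in_pal & r$repeat_class == "satellite"), 0L)
  # TE fraction >= 2x euchromatic background but far below the active state
  te_bp <- sum((r$end - r$start)[in_pal & r$repeat_class == "TE"])
  frac <- te_bp / (pal$end - pal$start)
  expect_gte(frac, 2 * sc$config$background_te_fraction)
  expect_lt(frac, 0.5)
  # gene content preserved
  expect_setequal(der$assembly$genes$gene_id,
                  sc$ancestor$assembly$genes$gene_id)
})

test_that("fusion concatenates elements and keeps every gene", {
  sc <- simulate_scenario("fusion", seed = 23)
  der <- sc$derived
  ch <- der$assembly$chromosomes
  fused <- ch[ch$muller == "A-B", ]
  expect_equal(nrow(fused), 1L)
  expect_false(any(ch$muller %in% c("A", "B")))
  expect_setequal(der$assembly$genes$gene_id,
                  sc$ancestor$assembly$genes$gene_id)
  # the surviving centromere is interior (at the junction)
  expect_gt(fused$cen_start, 0)
  expect_lt(fused$cen_end, fused$length)
  # one pericentromere active, the other deactivated
  expect_equal(nrow(der$truth$peri), 1L)
  expect_equal(nrow(der$truth$paleo), 1L)
})

test_that("expansion and contraction change pericentromere size only", {
  cfg <- sim_config(n_elements = 1, include_dot = FALSE,
                    emit_sequence = FALSE, rng_seed = 31,
                    element_length = 1.5e6)
  anc <- build_ancestor(cfg)
  ex <- evolve(anc, list(sim_event("pericentromere_expansion", "A",
                                   extra_bp = 1e5)), cfg)
  expect_equal(ex$assembly$chromosomes$length[1],
               anc$assembly$chromosomes$length[1] + 1e5)
  expect_setequal(ex$assembly$genes$gene_id, anc$assembly$genes$gene_id)
  expect_equal(ex$truth$peri$end - ex$truth$peri$start,
               anc$truth$peri$end - anc$truth$peri$start + 1e5)

  rep_ev <- evolve(anc, list(sim_event("reposition", "A")), cfg)
  con <- evolve(rep_ev, list(sim_event("paleocentromere_contraction", "A",
                                       remove_fraction = 0.5)), cfg)
  expect_lt(con$assembly$chromosomes$length[1],
            rep_ev$assembly$chromosomes$length[1])
  expect_setequal(con$assembly$genes$gene_id, anc$assembly$genes$gene_id)
})

test_that("breakpoints inside genes are rejected with a placement error", {
  cfg <- sim_config(n_elements = 1, include_dot = FALSE,
                    emit_sequence = FALSE, rng_seed = 37)
  anc <- build_ancestor(cfg)
  g <- anc$assembly$genes[10, ]
  expect_error(evolve(anc, list(sim_event("pericentric_inversion", "A",
                                          b1 = 0,
                                          b2 = floor((g$start + g$end) / 2))),
                      cfg),
               "breakpoint inside a gene")
})

test_that("simulated tracks expose the planted coverage structure", {
  cfg <- sim_config(n_elements = 1, include_dot = FALSE, rng_seed = 3,
                    element_length = 1.5e6, collapsed_copy_ratio = 5)
  anc <- build_ancestor(cfg)
  tr <- simulate_tracks(anc, cfg)
  cm <- contig_mean_coverage(tr$coverage_male)
  cf <- contig_mean_coverage(tr$coverage_female)
  # collapsed contig at 5x the genome mean within sampling error
  expect_gt(cm["contig_sat12"] / cm["chrA"], 4.5)
  expect_lt(cm["contig_sat12"] / cm["chrA"], 5.5)
  # Y contigs cross the 1.5 male/female ratio; autosomal contigs do not
  sl <- sex_linkage_call(cm, cf)
  expect_equal(sl$label[sl$contig %in% c("contig_Y1", "contig_Y2")],
               c("Y-linked", "Y-linked"))
  expect_equal(sl$label[sl$contig == "contig_u1"], "unassigned")
  # without planted enrichment the signal/input ratio sits near one:
  # input against itself over arm windows
  h3 <- enrichment_track(tr$h3_input, tr$h3_input)
  expect_true(all(abs(h3$value - 1) < 1e-12))
  # arm windows of the real signal are depleted relative to pericentromere
  e <- enrichment_track(tr$h3_signal, tr$h3_input)
  arm <- e$chrom == "chrA" & e$start >= 5e5 & e$end <= 1.4e6
  peri <- e$chrom == "chrA" & e$end <= 4e5
  expect_gt(mean(e$value[peri], na.rm = TRUE),
            2 * mean(e$value[arm], na.rm = TRUE))
})

test_that("metagene shapes follow the planted gene classes", {
  cfg <- sim_config(n_elements = 1, include_dot = TRUE, rng_seed = 41,
                    element_length = 1.2e6)
  anc <- build_ancestor(cfg)
  tr <- simulate_tracks(anc, cfg)
  g <- anc$assembly$genes
  # dot-like genes: body-enriched, TSS-depleted
  dotg <- g[grepl("_dot_", g$gene_id), ]
  pd <- metagene_profile(dotg, tr$h3_100bp, flank_bp = 1000,
                         n_body_bins = 20)
  nf <- attr(pd, "n_flank_bins")
  body <- seq(nf + 1, nf + 20)
  flank <- c(seq_len(nf), seq(nf + 21, length(pd)))
  expect_gt(mean(pd[body]), mean(pd[flank]))
  # TSS neighbourhood holds the profile minimum
  tss_nb <- seq(nf - 4, nf + 5)
  expect_lte(min(pd[tss_nb]), min(pd[-tss_nb]))
  # pericentromeric genes: flank-enriched, body-depleted
  perig <- g[grepl("_peri_", g$gene_id), ]
  pp <- metagene_profile(perig, tr$h3_100bp, flank_bp = 1000,
                         n_body_bins = 20)
  expect_gt(mean(pp[flank]), mean(pp[body]))
})
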