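# Shared simulation shortcuts for the test suite.

# pericentromere call for one element of a simulated species
peri_call_for <- function(sim, element, window = 1e5, cutoff = 0.4) {
  ci <- sim$assembly$chromosomes[
    sim$assembly$chromosomes$muller == element, ]
  rt <- repeat_fraction_track(sim$assembly, window)
  trc <- window_track(rt[rt$chrom == ci$name, ], window)
  suppressWarnings(call_pericentromere(
    trc, c(ci$cen_start, ci$cen_end), cutoff, element = element))
}

# full detection-and-classification chain for one scenario
classify_chain <- function(type, seed) {
  sc <- simulate_scenario(type, seed = seed)
  st_d <- element_state(sc$derived$assembly, "A",
                        peri_call_for(sc$derived, "A"))
  st_a <- element_state(sc$ancestor$assembly, "A",
                        peri_call_for(sc$ancestor, "A"))
  omap <- reciprocal_best_hits(
    score_gene_pairs(sc$derived$assembly$cds, sc$ancestor$assembly$cds))
  classify_transition(st_d, st_a, omap)
}

# minimal hand-made assembly for window/partition tests
toy_assembly <- function(len = 10000, genes = NULL, repeats = NULL,
                         sequence = NULL, exons = NULL) {
  chroms <- data.frame(name = "chr1", length = len, muller = "A",
                       cen_start = 0, cen_end = min(100, len))
  assembly_model("toy", chroms,
                 genes = genes %||% centrokaryo:::empty_genes(),
                 exons = exons %||% centrokaryo:::empty_exons(),
                 repeats = repeats %||% centrokaryo:::empty_repeats(),
                 sequences = if (is.null(sequence)) NULL else
                   c(chr1 = sequence))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_windows_for_test <- function(len, window) {
  s <- seq(0, len - window, by = window)
  data.frame(chrom = "chr1", start = s, end = s + window)
}
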