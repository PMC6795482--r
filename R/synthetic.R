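#' Simulation configuration
#'
#' Study conditions for the synthetic karyotype generator. Defaults emulate
#' a compact obscura-group-like genome scaled to desk size: five large
#' telocentric elements plus a dot, terminal satellite-plus-TE
#' pericentromeres, a 6% euchromatic TE background, AT-rich candidate seed
#' windows (GC 0.38 vs 0.45 background), and a centromeric satellite whose
#' monomer is a higher-order repeat (four diverged copies of a 21-bp
#' motif). Unknown arguments are rejected.
#'
#' @param n_elements number of large telocentric elements.
#' @param include_dot add a small dot element (Muller F).
#' @param element_length,dot_length chromosome lengths in bp.
#' @param genes_per_element,dot_genes,peri_genes gene counts (arm, dot, and
#'   inside the pericentromere).
#' @param gene_length,cds_length gene span and coding-sequence length in bp.
#' @param peri_length,cen_length pericentromere span and central satellite
#'   array length in bp (the array is the centromere anchor).
#' @param background_gc,seed_region_gc GC fractions of bulk sequence and of
#'   seed windows.
#' @param seed_region_length seed window length in bp; seed windows sit at
#'   fixed fractional positions along each arm.
#' @param background_te_fraction euchromatic TE fraction of arm bp.
#' @param peri_repeat_fraction approximate repeat fraction inside the
#'   pericentromere (realised by block sizing).
#' @param satellite_monomer_length,hor_subunits,hor_divergence centromeric
#'   satellite structure: the monomer is `hor_subunits` copies of a random
#'   `satellite_monomer_length`-bp motif, each copy carrying
#'   `ceiling(hor_divergence * satellite_monomer_length)` substitutions.
#' @param array_copy_divergence per-copy divergence within satellite
#'   arrays.
#' @param te_families number of TE families in the library.
#' @param neo_block_bp repeat bp inserted when a centromere repositions.
#' @param neo_seed_genes arm genes engulfed by a new pericentromere.
#' @param neo_seed_index which seed window (1-based) a repositioning
#'   targets.
#' @param paleo_te_fraction TE fraction retained in a deactivated
#'   pericentromere (above background, far below the active state).
#' @param coverage_mean,coverage_dispersion,coverage_window negative
#'   binomial read-coverage model (window in bp).
#' @param collapsed_copy_ratio coverage inflation of the collapsed
#'   satellite contig.
#' @param h3k9me3_window chromatin track window in bp.
#' @param emit_sequence generate nucleotide sequence (annotations and
#'   coding sequences are always generated).
#' @param rng_seed integer seed; fixed seed implies full determinism.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_elements = 5L, include_dot = TRUE,
                       element_length = 3e6, dot_length = 4e5,
                       genes_per_element = 80L, dot_genes = 20L,
                       peri_genes = 8L, gene_length = 6000L,
                       cds_length = 450L,
                       peri_length = 4e5, cen_length = 5e4,
                       background_gc = 0.45, seed_region_gc = 0.38,
                       seed_region_length = 8e4,
                       background_te_fraction = 0.06,
                       peri_repeat_fraction = 0.8,
                       satellite_monomer_length = 21L, hor_subunits = 4L,
                       hor_divergence = 0.14,
                       array_copy_divergence = 0.02,
                       te_families = 5L,
                       neo_block_bp = 4.5e5, neo_seed_genes = 8L,
                       neo_seed_index = 3L,
                       paleo_te_fraction = 0.30,
                       coverage_mean = 40, coverage_dispersion = 20,
                       coverage_window = 1000,
                       collapsed_copy_ratio = 5.5,
                       h3k9me3_window = 5e4,
                       emit_sequence = TRUE, rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_elements >= 1L,
            background_gc > 0, background_gc < 1,
            seed_region_gc > 0, seed_region_gc < 1,
            background_te_fraction > 0, background_te_fraction < 1,
            paleo_te_fraction > background_te_fraction,
            peri_repeat_fraction > 0.4, peri_repeat_fraction < 1)
  if (element_length <= peri_length) {
    stop("element shorter than its pericentromere")
  }
  structure(cfg, class = "sim_config")
}

# run code under a derived, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

rand_seq <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# substitute exactly k (or rate-derived) positions to a different base
mutate_seq <- function(s, rate = NULL, k = NULL) {
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  if (is.null(k)) k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sample.int(n, min(k, n))
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# tile a consensus to a target length
tile_seq <- function(consensus, len) {
  substr(strrep(consensus, ceiling(len / nchar(consensus))), 1L, len)
}

# tandem array of a unit, each copy lightly diverged, truncated to len
array_seq <- function(unit, len, copy_divergence) {
  n_cop <- ceiling(len / nchar(unit))
  copies <- vapply(seq_len(n_cop), function(i)
    mutate_seq(unit, rate = copy_divergence), "")
  substr(paste(copies, collapse = ""), 1L, len)
}

# higher-order satellite monomer: hor_subunits diverged copies of a motif
make_hor_unit <- function(cfg) {
  base <- rand_seq(cfg$satellite_monomer_length, 0.5)
  k <- ceiling(cfg$hor_divergence * cfg$satellite_monomer_length)
  paste(vapply(seq_len(cfg$hor_subunits), function(i)
    mutate_seq(base, k = k), ""), collapse = "")
}

seg <- function(kind, len, family = NA_character_, gc = NA_real_,
                gene_id = NA_character_) {
  list(kind = kind, len = as.integer(round(len)), family = family, gc = gc,
       gene_id = gene_id)
}

# materialise a segment list into annotation rows (+ sequence)
build_chromosome <- function(name, segs, cfg, sat_units, te_lib) {
  pos <- 0L
  genes <- list(); exons <- list(); reps <- list(); pieces <- character()
  seed_rows <- list()
  for (sg in segs) {
    if (sg$len <= 0L) next
    s0 <- pos; e0 <- pos + sg$len
    if (sg$kind == "gene") {
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sg$gene_id, chrom = name, start = s0, end = e0,
        strand = if (stats::runif(1) < 0.5) "+" else "-")
      third <- sg$len %/% 3L
      exons[[length(exons) + 1L]] <- data.frame(
        gene_id = rep(sg$gene_id, 2L), chrom = name,
        start = c(s0, s0 + 2L * third),
        end = c(s0 + third, e0))
    } else if (sg$kind == "te") {
      reps[[length(reps) + 1L]] <- data.frame(
        chrom = name, start = s0, end = e0, family = sg$family,
        repeat_class = "TE")
    } else if (sg$kind == "satellite") {
      reps[[length(reps) + 1L]] <- data.frame(
        chrom = name, start = s0, end = e0, family = sg$family,
        repeat_class = "satellite")
    } else if (sg$kind == "seed") {
      seed_rows[[length(seed_rows) + 1L]] <- data.frame(
        chrom = name, start = s0, end = e0)
    }
    if (cfg$emit_sequence) {
      pieces[[length(pieces) + 1L]] <- switch(
        sg$kind,
        gene = rand_seq(sg$len, cfg$background_gc),
        te = mutate_seq(tile_seq(te_lib[[sg$family]], sg$len), rate = 0.05),
        satellite = array_seq(sat_units[[sg$family]], sg$len,
                              cfg$array_copy_divergence),
        seed = rand_seq(sg$len, cfg$seed_region_gc),
        rand_seq(sg$len, sg$gc %||% cfg$background_gc))
    }
    pos <- e0
  }
  list(length = pos,
       genes = rbind_or(genes), exons = rbind_or(exons),
       repeats = rbind_or(reps), seeds = rbind_or(seed_rows),
       sequence = if (cfg$emit_sequence) paste(pieces, collapse = "") else NULL)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

rbind_or <- function(lst) {
  if (!length(lst)) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# segment layout of one telocentric ancestor element
element_segments <- function(el, cfg) {
  segs <- list()
  add <- function(s) segs[[length(segs) + 1L]] <<- s
  gid <- function(i, where) sprintf("%s_%s_g%03d", el, where, i)

  # centromeric satellite core (the anchor)
  add(seg("satellite", cfg$cen_length, family = "cenSat"))

  # pericentromere body: repeat gaps alternating with gene islands
  body <- cfg$peri_length - cfg$cen_length
  island <- cfg$gene_length + 2000L
  gap_total <- body - cfg$peri_genes * island
  n_gap <- cfg$peri_genes + 1L
  gap <- gap_total / n_gap
  te_part <- round(gap * cfg$peri_repeat_fraction * 0.85)
  sat_part <- round(gap * cfg$peri_repeat_fraction * 0.15)
  sp_part <- round(gap) - te_part - sat_part
  fams <- paste0("TEfam", seq_len(cfg$te_families))
  for (i in seq_len(n_gap)) {
    add(seg("te", te_part, family = fams[1L + (i %% 2L)]))
    add(seg("satellite", sat_part, family = "cenSat"))
    add(seg("spacer", sp_part, gc = cfg$background_gc))
    if (i <= cfg$peri_genes) {
      add(seg("gene", cfg$gene_length, gene_id = gid(i, "peri")))
      add(seg("spacer", 2000L, gc = cfg$background_gc))
    }
  }

  # euchromatic arm: evenly spread genes, scattered TEs, seed windows
  arm <- cfg$element_length - cfg$peri_length
  n_g <- cfg$genes_per_element
  n_seed <- 3L
  te_bp <- round(arm * cfg$background_te_fraction)
  te_frag <- 2000L
  n_te <- max(0L, te_bp %/% te_frag)
  spacer_total <- arm - n_g * cfg$gene_length -
    n_seed * cfg$seed_region_length - n_te * te_frag
  n_gaps <- n_g + 1L
  base_gap <- spacer_total / n_gaps
  te_in_gap <- round(seq(1L, n_gaps, length.out = n_te))
  seed_after_gene <- round(n_g * c(0.30, 0.55, 0.82))
  jitter <- stats::runif(n_gaps, 0.85, 1.15)
  jitter <- jitter * n_gaps / sum(jitter)
  for (g in seq_len(n_gaps)) {
    half <- round(base_gap * jitter[g] / 2)
    add(seg("spacer", half, gc = cfg$background_gc))
    n_here <- sum(te_in_gap == g)
    if (n_here > 0L) {
      add(seg("te", n_here * te_frag,
              family = fams[1L + (g %% cfg$te_families)]))
    }
    if (g %in% (seed_after_gene + 1L)) {
      add(seg("seed", cfg$seed_region_length))
    }
    add(seg("spacer", round(base_gap * jitter[g]) - half,
            gc = cfg$background_gc))
    if (g <= n_g) add(seg("gene", cfg$gene_length, gene_id = gid(g, "arm")))
  }
  segs
}

#' Build the ancestral telocentric karyotype
#'
#' Generates the ancestor species: `n_elements` telocentric chromosomes
#' (plus a dot), each with a terminal satellite-plus-TE pericentromere,
#' uniformly spread genes, AT-rich candidate seed windows, a background of
#' scattered TEs, and unplaced contigs (two Y-linked, one collapsed
#' satellite contig carrying two 12-mer arrays, one ordinary). Fully
#' deterministic given `rng_seed`.
#'
#' @param config a [sim_config].
#' @return list of class `karyo_sim` with elements `assembly` (an
#'   [assembly_model]), `truth` (planted intervals and classes) and
#'   `events` (empty log).
#' @export
build_ancestor <- function(config) {
  cfg <- config
  with_seed(cfg$rng_seed, {
    sat_units <- list(cenSat = make_hor_unit(cfg),
                      sat12 = rand_seq(12L, 0.3))
    # guard the 12-mer against internal periodicity
    while (hor_decompose(sat_units$sat12, 0.0)$fundamental_period < 12L ||
           grepl("^(.)\\1{11}$", sat_units$sat12)) {
      sat_units$sat12 <- rand_seq(12L, 0.3)
    }
    te_lib <- stats::setNames(
      lapply(seq_len(cfg$te_families), function(i) rand_seq(1500L, 0.42)),
      paste0("TEfam", seq_len(cfg$te_families)))

    els <- LETTERS[seq_len(cfg$n_elements)]
    chroms <- list(); genes <- list(); exons <- list(); reps <- list()
    seeds <- list(); seqs <- list(); het <- list()
    for (el in els) {
      nm <- paste0("chr", el)
      built <- build_chromosome(nm, element_segments(el, cfg), cfg,
                                sat_units, te_lib)
      chroms[[nm]] <- data.frame(name = nm, length = built$length,
                                 muller = el, cen_start = 0,
                                 cen_end = cfg$cen_length)
      genes[[nm]] <- built$genes; exons[[nm]] <- built$exons
      reps[[nm]] <- built$repeats; seeds[[nm]] <- built$seeds
      if (!is.null(built$sequence)) seqs[[nm]] <- built$sequence
      het[[nm]] <- data.frame(chrom = nm, start = 0, end = cfg$peri_length)
    }
    if (cfg$include_dot) {
      nm <- "chrF"
      dsegs <- list(seg("satellite", 2e4, family = "cenSat"))
      gap <- (cfg$dot_length - 2e4 - cfg$dot_genes * cfg$gene_length) /
        (cfg$dot_genes + 1L)
      for (i in seq_len(cfg$dot_genes)) {
        dsegs <- c(dsegs, list(
          seg("spacer", gap, gc = cfg$background_gc),
          seg("gene", cfg$gene_length,
              gene_id = sprintf("F_dot_g%03d", i))))
      }
      dsegs <- c(dsegs, list(seg("spacer", gap, gc = cfg$background_gc)))
      built <- build_chromosome(nm, dsegs, cfg, sat_units, te_lib)
      chroms[[nm]] <- data.frame(name = nm, length = built$length,
                                 muller = "F", cen_start = 0, cen_end = 2e4)
      genes[[nm]] <- built$genes; exons[[nm]] <- built$exons
      reps[[nm]] <- built$repeats
      if (!is.null(built$sequence)) seqs[[nm]] <- built$sequence
      het[[nm]] <- data.frame(chrom = nm, start = 0, end = built$length)
    }

    # unplaced contigs
    unplaced <- list()
    add_contig <- function(nm, segs2, class, copy_ratio = 1) {
      built <- build_chromosome(nm, segs2, cfg, sat_units, te_lib)
      chroms[[nm]] <<- data.frame(name = nm, length = built$length,
                                  muller = "unplaced", cen_start = NA_real_,
                                  cen_end = NA_real_)
      if (!is.null(built$repeats)) reps[[nm]] <<- built$repeats
      if (!is.null(built$sequence)) seqs[[nm]] <<- built$sequence
      unplaced[[length(unplaced) + 1L]] <<- data.frame(
        name = nm, class = class, copy_ratio = copy_ratio)
    }
    for (i in 1:2) {
      add_contig(paste0("contig_Y", i), list(
        seg("spacer", 2e4, gc = 0.40),
        seg("te", 2e4, family = "TEfam1"),
        seg("spacer", 1e4, gc = 0.40)), "Y")
    }
    add_contig("contig_sat12", list(
      seg("spacer", 4000L, gc = cfg$background_gc),
      seg("satellite", 278L * 12L, family = "sat12"),
      seg("spacer", 2000L, gc = cfg$background_gc),
      seg("satellite", 250L * 12L, family = "sat12"),
      seg("spacer", 2400L, gc = cfg$background_gc)),
      "collapsed_satellite", copy_ratio = cfg$collapsed_copy_ratio)
    add_contig("contig_u1", list(seg("spacer", 3e4, gc = cfg$background_gc)),
               "autosomal")

    chrom_df <- rbind_or(chroms)
    gene_df <- rbind_or(genes) %||% empty_genes()
    cds <- stats::setNames(
      vapply(gene_df$gene_id, function(g) rand_seq(cfg$cds_length, 0.5), ""),
      gene_df$gene_id)
    assembly <- assembly_model(
      species = "ancestor", chromosomes = chrom_df, genes = gene_df,
      exons = rbind_or(exons) %||% empty_exons(),
      repeats = rbind_or(reps) %||% empty_repeats(),
      sequences = if (length(seqs)) unlist(seqs) else NULL, cds = cds)

    gene_class <- ifelse(grepl("_peri_", gene_df$gene_id), "peri",
                         ifelse(grepl("_dot_", gene_df$gene_id), "dot", "arm"))
    truth <- list(
      peri = do.call(rbind, lapply(els, function(el) data.frame(
        chrom = paste0("chr", el), element = el, start = 0,
        end = cfg$peri_length))),
      paleo = data.frame(chrom = character(), element = character(),
                         start = numeric(), end = numeric()),
      seeds = rbind_or(seeds),
      het = rbind_or(het),
      gene_class = stats::setNames(gene_class, gene_df$gene_id),
      unplaced = rbind_or(unplaced),
      satellite_units = sat_units, te_library = te_lib)
    structure(list(assembly = assembly, truth = truth, events = list()),
              class = "karyo_sim")
  })
}

#' @export
print.karyo_sim <- function(x, ...) {
  cat(sprintf("<karyo_sim> %s: %d chromosome(s), %d logged event(s)\n",
              x$assembly$species, nrow(x$assembly$chromosomes),
              length(x$events)))
  invisible(x)
}
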