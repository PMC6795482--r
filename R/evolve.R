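#' Construct a karyotype-evolution event
#'
#' @param type one of `"reposition"`, `"pericentric_inversion"`,
#'   `"fusion"`, `"pericentromere_expansion"`,
#'   `"paleocentromere_contraction"`.
#' @param element Muller element the event acts on (for `"fusion"`, the
#'   first element; pass the second as `element_b`).
#' @param ... event-specific parameters (e.g. `b2` for an inversion
#'   breakpoint, `element_b` for fusion, `extra_bp` for expansion).
#' @return list of class `sim_event`.
#' @export
sim_event <- function(type = c("reposition", "pericentric_inversion",
                               "fusion", "pericentromere_expansion",
                               "paleocentromere_contraction"),
                      element, ...) {
  type <- match.arg(type)
  structure(list(type = type, element = element, params = list(...)),
            class = "sim_event")
}

shift_df <- function(df, chrom, pos, delta) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  sel <- df$chrom == chrom
  straddle <- sel & df$start < pos & df$end > pos
  if (any(straddle)) stop("insertion point inside a feature")
  mv <- sel & df$start >= pos
  df$start[mv] <- df$start[mv] + delta
  df$end[mv] <- df$end[mv] + delta
  df
}

shift_truth <- function(truth, chrom, pos, delta) {
  for (f in c("peri", "paleo", "seeds", "het")) {
    df <- truth[[f]]
    if (is.null(df) || nrow(df) == 0L) next
    sel <- df$chrom == chrom
    # truth intervals may span the insertion point: stretch them
    sp <- sel & df$start < pos & df$end > pos
    df$end[sp] <- df$end[sp] + delta
    mv <- sel & df$start >= pos
    df$start[mv] <- df$start[mv] + delta
    df$end[mv] <- df$end[mv] + delta
    truth[[f]] <- df
  }
  truth
}

# midpoints of the k largest feature-free gaps within [lo, hi), sorted by
# position; with k = 1 this is the single best insertion point
free_point <- function(assembly, chrom, lo, hi, k = 1L) {
  occ <- rbind(
    assembly$genes[assembly$genes$chrom == chrom, c("start", "end")],
    assembly$repeats[assembly$repeats$chrom == chrom, c("start", "end")])
  occ <- occ[occ$end > lo & occ$start < hi, , drop = FALSE]
  if (nrow(occ)) {
    m <- merge_intervals(data.frame(chrom = chrom, start = pmax(occ$start, lo),
                                    end = pmin(occ$end, hi)))
    gaps <- complement_intervals(m$start, m$end, hi)
    gaps <- gaps[gaps$start >= lo, , drop = FALSE]
  } else {
    gaps <- data.frame(start = lo, end = hi)
  }
  if (!nrow(gaps)) stop("no feature-free gap in [", lo, ", ", hi, ")")
  gaps <- gaps[order(gaps$end - gaps$start, decreasing = TRUE), ]
  take <- gaps[rep(seq_len(nrow(gaps)), length.out = k), , drop = FALSE]
  # spread multiple points across a shared gap
  out <- vapply(seq_len(k), function(i) {
    g <- take[i, ]
    floor(g$start + (g$end - g$start) * i / (k + 1))
  }, 0)
  sort(unique(out))
}

# splice a block of segments into a chromosome at pos
insert_block <- function(sim, chrom, pos, segs, cfg) {
  g <- sim$assembly$genes
  inside <- g$chrom == chrom & g$start < pos & g$end > pos
  if (any(inside)) {
    stop("breakpoint inside a gene: ", g$gene_id[inside][1L])
  }
  built <- build_chromosome(chrom, segs, cfg, sim$truth$satellite_units,
                            sim$truth$te_library)
  delta <- built$length
  a <- sim$assembly
  a$genes <- shift_df(a$genes, chrom, pos, delta)
  a$exons <- shift_df(a$exons, chrom, pos, delta)
  a$repeats <- shift_df(a$repeats, chrom, pos, delta)
  off <- function(df) {
    if (is.null(df)) return(NULL)
    df$start <- df$start + pos; df$end <- df$end + pos
    df
  }
  a$repeats <- rbind(a$repeats, off(built$repeats))
  ci <- which(a$chromosomes$name == chrom)
  a$chromosomes$length[ci] <- a$chromosomes$length[ci] + delta
  if (!is.na(a$chromosomes$cen_start[ci]) &&
      a$chromosomes$cen_start[ci] >= pos) {
    a$chromosomes$cen_start[ci] <- a$chromosomes$cen_start[ci] + delta
    a$chromosomes$cen_end[ci] <- a$chromosomes$cen_end[ci] + delta
  }
  if (!is.null(a$sequences)) {
    s <- a$sequences[[chrom]]
    a$sequences[[chrom]] <- paste0(substr(s, 1L, pos), built$sequence,
                                   substr(s, pos + 1L, nchar(s)))
  }
  sim$assembly <- a
  sim$truth <- shift_truth(sim$truth, chrom, pos, delta)
  sim
}

# deactivate a pericentromere: delete satellite annotations, thin each TE
# feature to `target_fraction` of the regional span, retain heterochromatin
deactivate_region <- function(sim, chrom, lo, hi, target_fraction, cfg) {
  a <- sim$assembly
  r <- a$repeats
  in_reg <- r$chrom == chrom & r$start >= lo & r$end <= hi
  sat <- in_reg & r$repeat_class == "satellite"
  te <- in_reg & r$repeat_class == "TE"
  wipe <- function(s0, e0) {
    if (!is.null(a$sequences)) {
      seq <- a$sequences[[chrom]]
      substr(seq, s0 + 1L, e0) <- rand_seq(e0 - s0, cfg$background_gc)
      a$sequences[[chrom]] <<- seq
    }
  }
  for (i in which(sat)) wipe(r$start[i], r$end[i])
  te_bp <- sum(r$end[te] - r$start[te])
  target_bp <- target_fraction * (hi - lo)
  keep_ratio <- min(1, target_bp / max(te_bp, 1))
  for (i in which(te)) {
    len <- r$end[i] - r$start[i]
    keep <- round(len * keep_ratio)
    if (keep < len) {
      wipe(r$start[i] + keep, r$end[i])
      r$end[i] <- r$start[i] + keep
    }
  }
  r <- r[!(sat | (te & r$end - r$start <= 0)), , drop = FALSE]
  a$repeats <- r
  sim$assembly <- a
  sim
}

split_repeats_at <- function(repeats, chrom, pos) {
  hit <- repeats$chrom == chrom & repeats$start < pos & repeats$end > pos
  if (!any(hit)) return(repeats)
  left <- repeats[hit, , drop = FALSE]; right <- left
  left$end <- pos; right$start <- pos
  rbind(repeats[!hit, , drop = FALSE], left, right)
}

remap_inv <- function(df, chrom, b1, b2) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  sel <- df$chrom == chrom & df$start >= b1 & df$end <= b2
  ns <- b1 + (b2 - df$end[sel])
  ne <- b1 + (b2 - df$start[sel])
  df$start[sel] <- ns; df$end[sel] <- ne
  if ("strand" %in% names(df)) {
    df$strand[sel] <- ifelse(df$strand[sel] == "+", "-", "+")
  }
  df
}

apply_inversion <- function(sim, chrom, b1, b2, cfg) {
  a <- sim$assembly
  g <- a$genes
  for (b in c(b1, b2)) {
    inside <- g$chrom == chrom & g$start < b & g$end > b
    if (any(inside)) stop("breakpoint inside a gene: ",
                          g$gene_id[inside][1L])
  }
  a$repeats <- split_repeats_at(split_repeats_at(a$repeats, chrom, b1),
                                chrom, b2)
  cross <- function(df) any(df$chrom == chrom &
                              ((df$start < b1 & df$end > b1) |
                                 (df$start < b2 & df$end > b2)))
  stopifnot(!cross(a$genes))
  a$genes <- remap_inv(a$genes, chrom, b1, b2)
  a$exons <- remap_inv(a$exons, chrom, b1, b2)
  a$repeats <- remap_inv(a$repeats, chrom, b1, b2)
  ci <- which(a$chromosomes$name == chrom)
  cs <- a$chromosomes$cen_start[ci]; ce <- a$chromosomes$cen_end[ci]
  if (!is.na(cs) && cs >= b1 && ce <= b2) {
    a$chromosomes$cen_start[ci] <- b1 + (b2 - ce)
    a$chromosomes$cen_end[ci] <- b1 + (b2 - cs)
  }
  if (!is.null(a$sequences)) {
    s <- a$sequences[[chrom]]
    mid <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(s, b1 + 1L, b2))))
    a$sequences[[chrom]] <- paste0(substr(s, 1L, b1), mid,
                                   substr(s, b2 + 1L, nchar(s)))
  }
  sim$assembly <- a
  for (f in c("peri", "paleo", "seeds", "het")) {
    sim$truth[[f]] <- remap_inv(sim$truth[[f]], chrom, b1, b2)
  }
  sim
}

#' Replay an event log on an ancestor
#'
#' Applies karyotype-evolution events in order, each deterministic given
#' the configuration seed: \strong{reposition} inserts a new interior
#' satellite-plus-TE pericentromere around a run of arm genes (centred on
#' an AT-rich seed window) and deactivates the old one (satellite
#' annotations deleted, TE features thinned to the paleocentromere
#' fraction, heterochromatin retained); \strong{pericentric_inversion}
#' reverses a segment including one pericentromere edge, carrying the
#' centromere and part of its gene complement to the interior;
#' \strong{fusion} concatenates two elements head-to-head and deactivates
#' one centromere; \strong{pericentromere_expansion} inserts an extra TE
#' burst; \strong{paleocentromere_contraction} deletes part of a
#' paleocentromere's remaining repeats. Events never break genes
#' (breakpoints inside a gene raise a placement error); gene content is
#' preserved by every event.
#'
#' @param ancestor a `karyo_sim` (from [build_ancestor]) or the result of a
#'   previous [evolve] call.
#' @param event_log list of [sim_event]s.
#' @param config the [sim_config] used to build the ancestor.
#' @return a `karyo_sim` with updated assembly, truth annotations and the
#'   appended event log.
#' @export
evolve <- function(ancestor, event_log, config) {
  sim <- ancestor
  sim$assembly$species <- paste0(sim$assembly$species, "_derived")
  for (i in seq_along(event_log)) {
    ev <- event_log[[i]]
    sim <- with_seed(config$rng_seed + 7919L * i, {
      switch(ev$type,
             reposition = ev_reposition(sim, ev, config),
             pericentric_inversion = ev_inversion(sim, ev, config),
             fusion = ev_fusion(sim, ev, config),
             pericentromere_expansion = ev_expansion(sim, ev, config),
             paleocentromere_contraction = ev_contraction(sim, ev, config),
             stop("unknown event type: ", ev$type))
    })
    sim$events <- c(sim$events, list(ev))
  }
  # re-validate the assembly invariants after surgery
  a <- sim$assembly
  sim$assembly <- assembly_model(a$species, a$chromosomes, a$genes, a$exons,
                                 a$repeats, a$sequences, a$cds)
  sim
}

ev_reposition <- function(sim, ev, cfg) {
  el <- ev$element
  ch <- sim$assembly$chromosomes$name[sim$assembly$chromosomes$muller == el]
  if (!length(ch)) stop("no chromosome for element ", el)
  g <- sim$assembly$genes[sim$assembly$genes$chrom == ch, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  arm <- g[grepl("_arm_", g$gene_id), , drop = FALSE]

  seeds <- sim$truth$seeds[sim$truth$seeds$chrom == ch, , drop = FALSE]
  seeds <- seeds[order(seeds$start), , drop = FALSE]
  si <- min(ev$params$seed_index %||% cfg$neo_seed_index, nrow(seeds))
  center <- (seeds$start[si] + seeds$end[si]) / 2
  n_eng <- ev$params$n_seed_genes %||% cfg$neo_seed_genes
  mid <- (arm$start + arm$end) / 2
  eng <- arm[order(abs(mid - center))[seq_len(n_eng)], , drop = FALSE]
  eng <- eng[order(eng$start), , drop = FALSE]

  # the ancestral seed span, recorded before coordinates change
  seed_span <- c(min(eng$start), max(eng$end))
  old_peri <- sim$truth$peri[sim$truth$peri$chrom == ch, , drop = FALSE]

  # insertion points in the gaps flanking and separating the engulfed genes
  chrom_len <- sim$assembly$chromosomes$length[
    sim$assembly$chromosomes$name == ch]
  lo_bound <- max(old_peri$end, eng$start[1L] - 15000L)
  hi_bound <- min(chrom_len, eng$end[n_eng] + 15000L)
  gaps <- rbind(c(lo_bound, eng$start[1L]),
                cbind(eng$end[seq_len(n_eng - 1L)],
                      eng$start[seq.int(2L, n_eng)]),
                c(eng$end[n_eng], hi_bound))
  # two insertion points per gap keep euchromatic stretches inside the new
  # pericentromere shorter than an analysis window
  pts <- as.numeric(apply(gaps, 1L, function(g)
    free_point(sim$assembly, ch, g[1L], g[2L], k = 2L)))
  per_gap <- round(ev$params$block_bp %||% cfg$neo_block_bp / length(pts))
  central <- ceiling(length(pts) / 2)
  blocks <- lapply(seq_along(pts), function(k) {
    te_fams <- names(sim$truth$te_library)
    base <- list(seg("te", round(per_gap * 0.7),
                     family = te_fams[1L + (k %% length(te_fams))]),
                 seg("satellite", round(per_gap * 0.3), family = "cenSat"))
    if (k == central) {
      base <- c(list(seg("satellite", cfg$cen_length, family = "cenSat")),
                base)
    }
    base
  })
  # apply right-to-left so earlier points stay valid
  new_lo <- NA; new_hi <- NA
  for (k in rev(seq_along(pts))) {
    sim <- insert_block(sim, ch, pts[k], blocks[[k]], cfg)
  }
  ins_bp <- vapply(blocks, function(b) sum(vapply(b, `[[`, 0L, "len")), 0)
  shift_before <- function(k) sum(ins_bp[seq_len(k - 1L)])
  new_lo <- pts[1L] + 0
  new_hi <- pts[length(pts)] + sum(ins_bp)
  anchor_lo <- pts[central] + shift_before(central) +
    0  # central block starts with the satellite core
  anchor_hi <- anchor_lo + cfg$cen_length

  ci <- which(sim$assembly$chromosomes$name == ch)
  sim$assembly$chromosomes$cen_start[ci] <- anchor_lo
  sim$assembly$chromosomes$cen_end[ci] <- anchor_hi

  # deactivate the old pericentromere (its coordinates are unshifted:
  # all insertions lie to its right)
  sim <- deactivate_region(sim, ch, old_peri$start, old_peri$end,
                           ev$params$paleo_te_fraction %||%
                             cfg$paleo_te_fraction, cfg)
  pt <- sim$truth$peri
  keep <- pt$chrom != ch
  sim$truth$paleo <- rbind(sim$truth$paleo,
                           data.frame(chrom = ch, element = el,
                                      start = old_peri$start,
                                      end = old_peri$end))
  sim$truth$peri <- rbind(pt[keep, , drop = FALSE],
                          data.frame(chrom = ch, element = el,
                                     start = new_lo, end = new_hi))
  sim$truth$het <- rbind(sim$truth$het,
                         data.frame(chrom = ch, start = new_lo,
                                    end = new_hi))
  eng_class <- rep("neo_peri", n_eng)
  sim$truth$gene_class[eng$gene_id] <- eng_class
  sim$truth$neo_seed <- rbind(
    sim$truth$neo_seed,
    cbind(data.frame(chrom = ch, element = el, start = seed_span[1L],
                     end = seed_span[2L]),
          genes = I(list(eng$gene_id))))
  sim
}

ev_inversion <- function(sim, ev, cfg) {
  el <- ev$element
  ch <- sim$assembly$chromosomes$name[sim$assembly$chromosomes$muller == el]
  len <- sim$assembly$chromosomes$length[
    sim$assembly$chromosomes$name == ch]
  peri <- sim$truth$peri[sim$truth$peri$chrom == ch, , drop = FALSE]
  b1 <- ev$params$b1 %||% 0
  b2 <- ev$params$b2 %||% free_point(sim$assembly, ch,
                                     floor(len * 0.52), floor(len * 0.58))
  if (b1 > peri$start + 1 && b1 < peri$end) {
    # acceptable: breakpoint inside the pericentromere body
  } else if (b1 != 0) {
    stop("inversion breakpoint b1 must touch the pericentromere")
  }
  sim <- apply_inversion(sim, ch, b1, b2, cfg)
  sim
}

ev_fusion <- function(sim, ev, cfg) {
  el_a <- ev$element
  el_b <- ev$params$element_b %||% stop("fusion needs element_b")
  a <- sim$assembly
  cha <- a$chromosomes$name[a$chromosomes$muller == el_a]
  chb <- a$chromosomes$name[a$chromosomes$muller == el_b]
  ia <- which(a$chromosomes$name == cha)
  ib <- which(a$chromosomes$name == chb)
  len_a <- a$chromosomes$length[ia]; len_b <- a$chromosomes$length[ib]
  new_name <- paste0("chr", el_a, el_b)
  new_muller <- paste(el_a, el_b, sep = "-")

  flip_a <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    sel <- df$chrom == cha
    ns <- len_a - df$end[sel]; ne <- len_a - df$start[sel]
    df$start[sel] <- ns; df$end[sel] <- ne
    if ("strand" %in% names(df)) {
      df$strand[sel] <- ifelse(df$strand[sel] == "+", "-", "+")
    }
    df$chrom[sel] <- new_name
    df
  }
  shift_b <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    sel <- df$chrom == chb
    df$start[sel] <- df$start[sel] + len_a
    df$end[sel] <- df$end[sel] + len_a
    df$chrom[sel] <- new_name
    df
  }
  for (f in c("genes", "exons", "repeats")) {
    a[[f]] <- shift_b(flip_a(a[[f]]))
  }
  # A's terminal anchor [0, c) maps to [len_a - c, len_a): the junction
  cs <- a$chromosomes$cen_start[ia]; ce <- a$chromosomes$cen_end[ia]
  new_row <- data.frame(name = new_name, length = len_a + len_b,
                        muller = new_muller,
                        cen_start = len_a - ce, cen_end = len_a - cs)
  if (!is.null(a$sequences)) {
    sa <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(a$sequences[[cha]])))
    a$sequences[[new_name]] <- paste0(sa, a$sequences[[chb]])
    a$sequences <- a$sequences[setdiff(names(a$sequences), c(cha, chb))]
  }
  a$chromosomes <- rbind(a$chromosomes[-c(ia, ib), , drop = FALSE], new_row)
  sim$assembly <- a
  for (f in c("peri", "paleo", "seeds", "het")) {
    sim$truth[[f]] <- shift_b(flip_a(sim$truth[[f]]))
  }
  # deactivate B's centromere: its pericentromere becomes a paleo region
  pt <- sim$truth$peri
  bi <- pt$chrom == new_name & pt$element == el_b
  if (any(bi)) {
    reg <- pt[bi, , drop = FALSE]
    sim <- deactivate_region(sim, new_name, reg$start, reg$end,
                             cfg$paleo_te_fraction, cfg)
    sim$truth$paleo <- rbind(sim$truth$paleo, reg)
    sim$truth$peri <- pt[!bi, , drop = FALSE]
  }
  sim
}

ev_expansion <- function(sim, ev, cfg) {
  el <- ev$element
  peri <- sim$truth$peri[sim$truth$peri$element == el, , drop = FALSE]
  ch <- peri$chrom[1L]
  extra <- ev$params$extra_bp %||% round(0.3 * (peri$end - peri$start))
  pt <- free_point(sim$assembly, ch, peri$start, peri$end)
  fam <- names(sim$truth$te_library)[1L]
  insert_block(sim, ch, pt, list(seg("te", extra, family = fam)), cfg)
}

ev_contraction <- function(sim, ev, cfg) {
  el <- ev$element
  pal <- sim$truth$paleo[sim$truth$paleo$element == el, , drop = FALSE]
  if (!nrow(pal)) stop("element ", el, " has no paleocentromere")
  ch <- pal$chrom[1L]
  frac <- ev$params$remove_fraction %||% 0.5
  a <- sim$assembly
  r <- a$repeats
  in_reg <- which(r$chrom == ch & r$start >= pal$start & r$end <= pal$end &
                    r$repeat_class == "TE")
  # delete the right `frac` of each remaining TE feature, right-to-left
  for (i in in_reg[order(-r$start[in_reg])]) {
    len <- r$end[i] - r$start[i]
    cut <- round(len * frac)
    if (cut <= 0) next
    s0 <- r$end[i] - cut; e0 <- r$end[i]
    if (!is.null(a$sequences)) {
      s <- a$sequences[[ch]]
      a$sequences[[ch]] <- paste0(substr(s, 1L, s0), substr(s, e0 + 1L,
                                                            nchar(s)))
    }
    a$repeats$end[i] <- s0  # truncate this feature before shifting the rest
    a$repeats <- shift_df(a$repeats, ch, e0, -(e0 - s0))
    a$genes <- shift_df(a$genes, ch, e0, -(e0 - s0))
    a$exons <- shift_df(a$exons, ch, e0, -(e0 - s0))
    ci <- which(a$chromosomes$name == ch)
    a$chromosomes$length[ci] <- a$chromosomes$length[ci] - (e0 - s0)
    if (!is.na(a$chromosomes$cen_start[ci]) &&
        a$chromosomes$cen_start[ci] >= e0) {
      a$chromosomes$cen_start[ci] <- a$chromosomes$cen_start[ci] - (e0 - s0)
      a$chromosomes$cen_end[ci] <- a$chromosomes$cen_end[ci] - (e0 - s0)
    }
    sim$assembly <- a
    sim$truth <- shift_truth(sim$truth, ch, e0, -(e0 - s0))
    a <- sim$assembly
  }
  sim$assembly <- a
  sim
}

#' Simulate one named transition scenario
#'
#' Builds an ancestor and one derived species related by a known event:
#' `"conserved"` (empty event log), `"inversion"` (pericentric inversion
#' carrying the terminal centromere to the interior), `"reposition"`
#' (de novo interior pericentromere, old one deactivated) or `"fusion"`
#' (two elements joined head-to-head).
#'
#' @param type scenario name.
#' @param seed RNG seed for the whole scenario.
#' @param config optional [sim_config] override (its `rng_seed` is
#'   replaced by `seed`).
#' @param element element the event acts on.
#' @return list with `ancestor`, `derived` (both `karyo_sim`) and `events`.
#' @export
simulate_scenario <- function(type = c("conserved", "inversion",
                                       "reposition", "fusion"),
                              seed = 1L, config = NULL, element = "A") {
  type <- match.arg(type)
  if (is.null(config)) {
    config <- sim_config(n_elements = if (type == "fusion") 2L else 1L,
                         include_dot = FALSE, emit_sequence = FALSE,
                         rng_seed = seed)
  } else {
    config$rng_seed <- seed
  }
  anc <- build_ancestor(config)
  events <- switch(type,
                   conserved = list(),
                   inversion = list(sim_event("pericentric_inversion",
                                              element)),
                   reposition = list(sim_event("reposition", element)),
                   fusion = list(sim_event("fusion", element,
                                           element_b = "B")))
  der <- evolve(anc, events, config)
  der$assembly$species <- paste0("derived_", type)
  list(ancestor = anc, derived = der, events = events, config = config)
}
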