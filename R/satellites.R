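#' Reverse complement of a plain character sequence
#' @keywords internal
revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""),
                ""))
}

#' Canonical form of a tandem-repeat unit
#'
#' Tandem-repeat monomers are equivalent up to rotation and strand; the
#' canonical form is the lexicographically minimal string over all rotations
#' of the unit and of its reverse complement, so equivalent units collapse
#' to one key. The map is idempotent and constant on equivalence classes.
#'
#' @param unit a non-empty string over A/C/G/T.
#' @return the canonical unit string.
#' @export
canonical_unit <- function(unit) {
  if (!nzchar(unit)) stop("unit must be non-empty")
  if (grepl("[^ACGT]", unit)) stop("unit contains non-ACGT characters")
  n <- nchar(unit)
  rots <- function(x) {
    dd <- paste0(x, x)
    vapply(seq_len(n), function(i) substr(dd, i, i + n - 1L), "")
  }
  min(c(rots(unit), rots(unname(revcomp_chr(unit)))))
}

# majority-rule consensus of units stacked as rows of a character matrix;
# ties resolved to the alphabetically smallest base
consensus_of <- function(mat) {
  apply(mat, 2L, function(col) {
    tb <- table(col)
    names(tb)[tb == max(tb)][1L]
  })
}

# mean per-unit divergence of an array region (0-based [start,end) within
# chars) re-chunked at period q; returns list(divergence, consensus)
divergence_at <- function(chars, start0, end0, q) {
  m <- (end0 - start0) %/% q
  if (m < 1L) return(list(divergence = Inf, consensus = ""))
  idx <- start0 + seq_len(m * q)
  mat <- matrix(chars[idx], nrow = m, ncol = q, byrow = TRUE)
  cons <- consensus_of(mat)
  div <- mean(sweep(mat, 2L, cons, FUN = "!="))
  list(divergence = div, consensus = paste(cons, collapse = ""))
}

#' Find tandem arrays by period scanning
#'
#' A self-contained tandem-repeat detector: for each candidate period `p`
#' the sequence is compared against itself shifted by `p`; runs of agreement
#' delimit candidate arrays, which must reach `min_copies` copies and whose
#' units must diverge from their consensus by at most `max_divergence`
#' (mean fraction of mismatching positions per unit). Overlapping candidates
#' across periods are resolved longest-first, ties by smaller period, then
#' leftmost; each accepted array is reported at the smallest period
#' consistent with `max_divergence` (arrays whose true period falls below
#' `min_unit`, e.g. homopolymers, are discarded). `N` breaks arrays.
#'
#' @param sequence a character string over A/C/G/T/N.
#' @param min_unit,max_unit period search range in bp.
#' @param min_copies minimum number of copies.
#' @param max_divergence maximum mean per-unit divergence vs the consensus.
#' @return data.frame with one row per array: `start`, `end` (0-based
#'   half-open), `unit` (consensus), `canonical` (rotation/strand canonical
#'   form), `unit_length`, `copies` (real), `divergence`.
#' @export
find_tandem_arrays <- function(sequence, min_unit = 4L, max_unit = 500L,
                               min_copies = 3L, max_divergence = 0.1) {
  if (min_unit < 1L || max_unit < min_unit) {
    stop("need 1 <= min_unit <= max_unit")
  }
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bytes <- charToRaw(toupper(sequence))
  n <- length(chars)
  empty <- data.frame(start = numeric(), end = numeric(), unit = character(),
                      canonical = character(), unit_length = integer(),
                      copies = numeric(), divergence = numeric())
  if (n < min_unit * min_copies) return(empty)
  is_n <- chars == "N"
  break_len <- if (max_divergence == 0) 1L else 4L

  cands <- list()
  for (p in seq.int(min_unit, min(max_unit, n %/% min_copies))) {
    d <- bytes[seq_len(n - p)] != bytes[seq.int(p + 1L, n)]
    d <- d | is_n[seq_len(n - p)] | is_n[seq.int(p + 1L, n)]
    # hard breaks: long mismatch runs and N positions
    r <- rle(d)
    hard <- inverse.rle(list(lengths = r$lengths,
                             values = r$values & r$lengths >= break_len))
    hard <- hard | is_n[seq_len(n - p)] | is_n[seq.int(p + 1L, n)]
    # segments between hard breaks; only those long enough to hold an
    # array are examined at all
    hr <- rle(hard)
    hpos <- cumsum(c(1L, hr$lengths))
    for (k in which(!hr$values & hr$lengths + p >= p * min_copies)) {
      i <- hpos[k]; j <- hpos[k + 1L] - 1L
      # trim each edge to the first/last matching position; remaining
      # flank bleed-through is bounded by the mismatch-rate check below
      seg_m <- which(!d[i:j])
      if (!length(seg_m)) next
      i2 <- i + seg_m[1L] - 1L
      j2 <- i + seg_m[length(seg_m)] - 1L
      if (j2 - i2 + 1L + p < p * min_copies) next
      rate <- mean(d[i2:j2])
      if (rate > 2 * max_divergence + 1e-12) next
      start0 <- i2 - 1L
      end0 <- j2 + p
      dv <- divergence_at(chars, start0, end0, p)
      if (dv$divergence > max_divergence + 1e-12) next
      cands[[length(cands) + 1L]] <-
        list(start = start0, end = end0, p = p,
             divergence = dv$divergence, consensus = dv$consensus)
    }
  }
  if (!length(cands)) return(empty)

  len <- vapply(cands, function(c) c$end - c$start, 0)
  per <- vapply(cands, function(c) c$p, 0L)
  st <- vapply(cands, function(c) c$start, 0)
  ord <- order(-len, per, st)
  accepted <- list()
  occupied_s <- numeric(); occupied_e <- numeric()
  for (k in ord) {
    c <- cands[[k]]
    if (any(c$start < occupied_e & c$end > occupied_s)) next
    # reduce to the smallest qualifying period among divisors
    best <- c
    for (q in seq_len(c$p)) {
      if (c$p %% q != 0L) next
      dv <- divergence_at(chars, c$start, c$end, q)
      if (dv$divergence <= max_divergence + 1e-12) {
        best <- list(start = c$start, end = c$end, p = q,
                     divergence = dv$divergence, consensus = dv$consensus)
        break
      }
    }
    if (best$p < min_unit) next  # true period below the search floor
    occupied_s <- c(occupied_s, c$start)
    occupied_e <- c(occupied_e, c$end)
    accepted[[length(accepted) + 1L]] <- best
  }
  if (!length(accepted)) return(empty)
  out <- data.frame(
    start = vapply(accepted, function(a) a$start, 0),
    end = vapply(accepted, function(a) a$end, 0),
    unit = vapply(accepted, function(a) a$consensus, ""),
    canonical = vapply(accepted, function(a)
      canonical_unit(gsub("N", "A", a$consensus)), ""),
    unit_length = vapply(accepted, function(a) a$p, 0L),
    copies = vapply(accepted, function(a) (a$end - a$start) / a$p, 0),
    divergence = vapply(accepted, function(a) a$divergence, 0))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-abundance histogram of tandem arrays
#'
#' Aggregates arrays by unit length: total bp in arrays, copy totals, and
#' the most abundant canonical unit per length class. The modal length
#' (argmax of total bp, ties to the smaller length) identifies the dominant
#' satellite of a genome.
#'
#' @param arrays data.frame from [find_tandem_arrays] (possibly
#'   concatenated over chromosomes).
#' @return data.frame (`unit_length`, `total_bp`, `total_copies`,
#'   `n_arrays`, `top_unit`) sorted by unit length, with attribute
#'   `modal_length`.
#' @export
abundance_histogram <- function(arrays) {
  if (nrow(arrays) == 0L) {
    out <- data.frame(unit_length = integer(), total_bp = numeric(),
                      total_copies = numeric(), n_arrays = integer(),
                      top_unit = character())
    attr(out, "modal_length") <- NA_integer_
    return(out)
  }
  bp <- arrays$end - arrays$start
  sp <- split(seq_len(nrow(arrays)), arrays$unit_length)
  out <- do.call(rbind, lapply(sp, function(idx) {
    by_unit <- tapply(bp[idx], arrays$canonical[idx], sum)
    data.frame(unit_length = arrays$unit_length[idx[1L]],
               total_bp = sum(bp[idx]),
               total_copies = sum(arrays$copies[idx]),
               n_arrays = length(idx),
               top_unit = names(by_unit)[which.max(by_unit)])
  }))
  out <- out[order(out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "modal_length") <-
    out$unit_length[which.max(out$total_bp)]  # which.max: first = smallest
  out
}

#' Higher-order repeat decomposition of a unit
#'
#' Tests whether a repeat unit is itself a tandem of a shorter fundamental
#' monomer (e.g. an 84-bp unit made of four diverged 21-bp motifs).
#' Candidate fundamental periods are the divisors `p` of the unit length
#' with `4 <= p <= length/2`, tested ascending; the first whose subunits
#' diverge from their consensus by at most `max_divergence` is accepted,
#' otherwise the unit is its own fundamental period.
#'
#' @param unit repeat unit string (length >= 8 for a decomposition to be
#'   attempted).
#' @param max_divergence maximum mean subunit divergence from consensus.
#' @return list with `fundamental_period`, `n_subunits`,
#'   `subunit_divergence`.
#' @export
hor_decompose <- function(unit, max_divergence = 0.10) {
  n <- nchar(unit)
  chars <- strsplit(unit, "")[[1L]]
  if (n >= 8L) {
    for (p in seq.int(4L, n %/% 2L)) {
      if (n %% p != 0L) next
      dv <- divergence_at(chars, 0L, n, p)
      if (dv$divergence <= max_divergence + 1e-12) {
        return(list(fundamental_period = p, n_subunits = n %/% p,
                    subunit_divergence = dv$divergence))
      }
    }
  }
  list(fundamental_period = n, n_subunits = 1L, subunit_divergence = 0)
}

# best ungapped circular identity of unit a against unit b (either strand),
# as matching positions divided by the shorter length
unit_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  sa <- strsplit(a, "")[[1L]]
  la <- length(sa); lb <- nchar(b)
  best <- 0L
  for (bb in c(b, unname(revcomp_chr(b)))) {
    dd <- strsplit(paste0(bb, bb), "")[[1L]]
    for (o in 0:(lb - 1L)) {
      m <- sum(sa == dd[o + seq_len(la)])
      if (m > best) best <- m
    }
  }
  best / la
}

#' Greedy identity clustering of satellite units
#'
#' Clusters canonicalised units in the longest-first greedy style of
#' CD-HIT: a unit joins the first cluster whose representative matches at
#' `identity` or better over the shorter length (best rotation, either
#' strand) with a length difference of at most `length_cutoff` bp;
#' otherwise it founds a new cluster.
#'
#' @param units character vector of units.
#' @param identity minimum identity in (0, 1].
#' @param length_cutoff maximum length difference in bp.
#' @return data.frame (`unit`, `cluster`, `representative`); cluster ids
#'   number the representatives in visiting order.
#' @export
cluster_units <- function(units, identity = 0.90, length_cutoff = 10L) {
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  ord <- order(-nchar(units), units)
  reps <- character()
  assign <- integer(length(units))
  for (k in ord) {
    u <- units[k]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (abs(nchar(u) - nchar(reps[ci])) > length_cutoff) next
      if (unit_identity(u, reps[ci]) >= identity) {
        assign[k] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, u)
      assign[k] <- length(reps)
    }
  }
  data.frame(unit = units, cluster = assign, representative = reps[assign])
}

#' Satellite density track and centromere candidate
#'
#' Bp of annotated satellite arrays of one family per window; the window of
#' maximum density on each chromosome (ties to the leftmost) is the
#' centromere candidate.
#'
#' @param assembly an [assembly_model] with satellite annotations.
#' @param unit_family family label of the satellite.
#' @param window window size in bp.
#' @return a [window_track] of satellite bp with attribute `candidates`, a
#'   data.frame of the argmax window per chromosome (`none` flag when the
#'   family is absent).
#' @export
satellite_density_track <- function(assembly, unit_family, window = 100000L) {
  sat <- assembly$repeats[assembly$repeats$repeat_class == "satellite" &
                            assembly$repeats$family == unit_family, ,
                          drop = FALSE]
  merged <- merge_intervals(sat)
  win <- make_windows(assembly, window)
  win$value <- 0
  for (ch in unique(win$chrom)) {
    wi <- win$chrom == ch
    f <- merged[merged$chrom == ch, , drop = FALSE]
    win$value[wi] <- overlap_bp_per_window(win$start[wi], win$end[wi],
                                           f$start, f$end)
  }
  tr <- window_track(win, window, window, paste0("satellite:", unit_family))
  cand <- do.call(rbind, lapply(split(win, win$chrom), function(w) {
    if (all(w$value == 0)) {
      data.frame(chrom = w$chrom[1L], start = NA_real_, end = NA_real_,
                 value = 0, flag = "none")
    } else {
      i <- which.max(w$value)
      data.frame(chrom = w$chrom[1L], start = w$start[i], end = w$end[i],
                 value = w$value[i], flag = "ok")
    }
  }))
  rownames(cand) <- NULL
  attr(tr, "candidates") <- cand
  tr
}

#' Coverage-implied copy number of a collapsed array
#'
#' Assembled satellite arrays that collapsed during assembly show excess
#' read coverage; the implied genomic copy number scales the assembled
#' copies by the contig-to-genome coverage ratio.
#'
#' @param assembled_copies copies present in the assembly.
#' @param contig_mean_coverage mean read coverage of the collapsed contig.
#' @param genome_mean_coverage genome-wide mean coverage (> 0).
#' @return implied copy number.
#' @export
collapsed_copy_estimate <- function(assembled_copies, contig_mean_coverage,
                                    genome_mean_coverage) {
  if (genome_mean_coverage <= 0) stop("genome_mean_coverage must be > 0")
  assembled_copies * contig_mean_coverage / genome_mean_coverage
}
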