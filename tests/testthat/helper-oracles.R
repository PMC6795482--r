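# Independent brute-force oracles. Each re-implements the declared
# semantics of an operation with naive loops so the vectorised package
# code can be checked against it on small instances.

# per-base bitmap: masked bp of `feats` (0-based half-open) in each window
oracle_window_masked_bp <- function(chrom_len, window, feats) {
  mask <- logical(chrom_len)
  for (i in seq_len(nrow(feats))) {
    if (feats$end[i] > feats$start[i]) {
      mask[(feats$start[i] + 1):feats$end[i]] <- TRUE
    }
  }
  starts <- seq(0, max(0, chrom_len - 1), by = window)
  starts <- starts[starts < chrom_len]
  if (chrom_len >= window) {
    n <- ceiling((chrom_len - window) / window) + 1
  } else n <- 1
  vapply(seq_len(n), function(k) {
    s <- (k - 1) * window
    e <- min(s + window, chrom_len)
    sum(mask[(s + 1):e])
  }, 0)
}

# double-argmax reciprocal best hits with tie-drop
oracle_rbh <- function(score_df) {
  ga <- unique(score_df$gene_a); gb <- unique(score_df$gene_b)
  sc <- function(a, b) {
    i <- score_df$gene_a == a & score_df$gene_b == b
    if (any(i)) score_df$score[i][1] else 0
  }
  pairs <- list()
  for (a in ga) {
    row <- vapply(gb, function(b) sc(a, b), 0)
    if (max(row) <= 0 || sum(row == max(row)) > 1) next
    b <- gb[which.max(row)]
    col <- vapply(ga, function(a2) sc(a2, b), 0)
    if (sum(col == max(col)) > 1) next
    if (ga[which.max(col)] == a) {
      pairs[[length(pairs) + 1]] <- data.frame(gene_a = a, gene_b = b,
                                               score = sc(a, b))
    }
  }
  if (!length(pairs)) return(data.frame(gene_a = character(),
                                        gene_b = character(),
                                        score = numeric()))
  out <- do.call(rbind, pairs)
  out[order(out$gene_a), ]
}

# Mann-Whitney U of x (vs y) by direct pair counting
oracle_mwu_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

# divisor-scan HOR decomposition with explicit consensus counting
oracle_hor <- function(unit, max_divergence = 0.10) {
  n <- nchar(unit)
  ch <- strsplit(unit, "")[[1]]
  if (n >= 8) {
    for (p in 4:(n %/% 2)) {
      if (n %% p != 0) next
      m <- n %/% p
      cons <- character(p)
      for (col in seq_len(p)) {
        bases <- ch[col + (seq_len(m) - 1) * p]
        tb <- sort(table(bases), decreasing = TRUE)
        top <- names(tb)[tb == max(tb)]
        cons[col] <- sort(top)[1]
      }
      mism <- 0
      for (r in seq_len(m)) for (col in seq_len(p)) {
        if (ch[(r - 1) * p + col] != cons[col]) mism <- mism + 1
      }
      if (mism / (m * p) <= max_divergence + 1e-12) {
        return(list(fundamental_period = p, n_subunits = m,
                    subunit_divergence = mism / (m * p)))
      }
    }
  }
  list(fundamental_period = n, n_subunits = 1L, subunit_divergence = 0)
}

# naive-loop period scan implementing the same declared array semantics
oracle_tandem_arrays <- function(sequence, min_unit = 4, max_unit = 500,
                                 min_copies = 3, max_divergence = 0.1) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(ch)
  break_len <- if (max_divergence == 0) 1 else 4
  consensus_div <- function(s0, e0, q) {
    m <- (e0 - s0) %/% q
    if (m < 1) return(list(div = Inf, cons = ""))
    cons <- character(q)
    for (col in seq_len(q)) {
      bases <- ch[s0 + col + (seq_len(m) - 1) * q]
      tb <- sort(table(bases), decreasing = TRUE)
      cons[col] <- sort(names(tb)[tb == max(tb)])[1]
    }
    mism <- 0
    for (r in seq_len(m)) for (col in seq_len(q)) {
      if (ch[s0 + (r - 1) * q + col] != cons[col]) mism <- mism + 1
    }
    list(div = mism / (m * q), cons = paste(cons, collapse = ""))
  }
  cands <- list()
  for (p in min_unit:min(max_unit, n %/% min_copies)) {
    d <- logical(n - p); hard <- logical(n - p)
    for (k in seq_len(n - p)) {
      d[k] <- ch[k] != ch[k + p] || ch[k] == "N" || ch[k + p] == "N"
      hard[k] <- ch[k] == "N" || ch[k + p] == "N"
    }
    run <- 0
    for (k in seq_len(n - p)) {
      if (d[k]) run <- run + 1 else run <- 0
      if (run >= break_len) hard[(k - run + 1):k] <- TRUE
    }
    k <- 1
    while (k <= n - p) {
      if (hard[k]) { k <- k + 1; next }
      j <- k
      while (j < n - p && !hard[j + 1]) j <- j + 1
      # trim to the first/last matching position
      a <- NA; b <- NA
      for (t in k:j) if (!d[t]) { a <- t; break }
      for (t in j:k) if (!d[t]) { b <- t; break }
      if (!is.na(a) && !is.na(b) && b >= a &&
          (b - a + 1 + p) >= p * min_copies &&
          mean(d[a:b]) <= 2 * max_divergence + 1e-12) {
        cd <- consensus_div(a - 1, b + p, p)
        if (cd$div <= max_divergence + 1e-12) {
          cands[[length(cands) + 1]] <- list(start = a - 1, end = b + p,
                                             p = p)
        }
      }
      k <- j + 1
    }
  }
  if (!length(cands)) {
    return(data.frame(start = numeric(), end = numeric(),
                      unit_length = integer(), copies = numeric()))
  }
  len <- sapply(cands, function(c) c$end - c$start)
  per <- sapply(cands, function(c) c$p)
  st <- sapply(cands, function(c) c$start)
  ord <- order(-len, per, st)
  acc <- list()
  for (k in ord) {
    c <- cands[[k]]
    clash <- FALSE
    for (a2 in acc) {
      if (c$start < a2$end && c$end > a2$start) { clash <- TRUE; break }
    }
    if (clash) next
    q_best <- c$p
    for (q in 1:c$p) {
      if (c$p %% q != 0) next
      if (consensus_div(c$start, c$end, q)$div <= max_divergence + 1e-12) {
        q_best <- q; break
      }
    }
    if (q_best < min_unit) next
    acc[[length(acc) + 1]] <- list(start = c$start, end = c$end, p = q_best)
  }
  if (!length(acc)) {
    return(data.frame(start = numeric(), end = numeric(),
                      unit_length = integer(), copies = numeric()))
  }
  out <- data.frame(start = sapply(acc, `[[`, "start"),
                    end = sapply(acc, `[[`, "end"),
                    unit_length = sapply(acc, `[[`, "p"))
  out$copies <- (out$end - out$start) / out$unit_length
  out[order(out$start), ]
}

# maximal-run island enumeration on a qualifying mask
oracle_islands <- function(qualified, ws, we, min_span) {
  out <- list()
  i <- 1; n <- length(qualified)
  while (i <= n) {
    if (!qualified[i]) { i <- i + 1; next }
    j <- i
    while (j < n && qualified[j + 1]) j <- j + 1
    if (we[j] - ws[i] >= min_span) {
      out[[length(out) + 1]] <- c(ws[i], we[j])
    }
    i <- j + 1
  }
  out
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

mutate_dna <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
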