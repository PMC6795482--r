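test_that("canonical_unit is minimal over rotation and strand", {
  expect_equal(canonical_unit("GTAC"), "ACGT")
  expect_equal(canonical_unit("AAAA"), "AAAA")
  expect_error(canonical_unit(""), "non-empty")
  expect_error(canonical_unit("ACGN"), "non-ACGT")

  # class function: invariant under rotation and reverse complement, and
  # idempotent (property over random units)
  set.seed(9)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  for (i in 1:25) {
    u <- rand_dna(sample(4:40, 1))
    cu <- canonical_unit(u)
    expect_equal(canonical_unit(cu), cu)
    k <- sample(nchar(u), 1)
    rot <- paste0(substr(u, k, nchar(u)), substr(u, 1, k - 1))
    expect_equal(canonical_unit(rot), cu)
    expect_equal(canonical_unit(rc(rot)), cu)
  }
})

test_that("perfect planted arrays are recovered exactly", {
  set.seed(12)
  # "ACGT" x 50 embedded in random flanks
  s <- paste0(rand_dna(400), strrep("ACGT", 50), rand_dna(400))
  arr <- find_tandem_arrays(s, max_divergence = 0)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$unit_length, 4L)
  expect_gte(arr$copies, 50)
  expect_lt(arr$copies, 51)
  expect_equal(canonical_unit(arr$unit), "ACGT")

  # homopolymers fall below the period floor
  expect_equal(nrow(find_tandem_arrays(strrep("A", 100))), 0L)
  expect_error(find_tandem_arrays("ACGT", min_unit = 0), "min_unit")

  # exact unit/copies/interval recovery across many seeded constructions
  hits <- 0L
  for (i in 1:50) {
    p <- sample(5:30, 1)
    copies <- sample(5:20, 1)
    unit <- rand_dna(p)
    if (hor_decompose(unit, 0)$fundamental_period < p) next  # skip periodic
    s2 <- paste0(rand_dna(150), strrep(unit, copies), rand_dna(150))
    a2 <- find_tandem_arrays(s2, max_divergence = 0)
    a2 <- a2[which.max(a2$end - a2$start), ]
    expect_equal(a2$unit_length, p)
    expect_equal(floor(a2$copies), copies)
    # interval covers the planted array (allowing chance 1-2 bp extension)
    expect_lte(abs(a2$start - 150), p)
    expect_lte(abs(a2$end - (150 + p * copies)), p)
    hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("diverged planted arrays overlap truth and match the oracle", {
  set.seed(33)
  for (i in 1:6) {
    p <- sample(c(8, 12, 21), 1)
    copies <- sample(20:40, 1)
    unit <- rand_dna(p)
    body <- paste(vapply(seq_len(copies), function(k)
      mutate_dna(unit, rbinom(1, p, 0.05)), ""), collapse = "")
    s <- paste0(rand_dna(600), body, rand_dna(600))
    arr <- find_tandem_arrays(s, max_divergence = 0.1)
    expect_gte(nrow(arr), 1L)
    big <- arr[which.max(arr$end - arr$start), ]
    planted <- c(600, 600 + nchar(body))
    ov <- min(big$end, planted[2]) - max(big$start, planted[1])
    expect_gte(ov / max(big$end - big$start, diff(planted)), 0.9)
  }

  # full agreement with the naive period-scan oracle on short sequences
  for (i in 1:4) {
    p <- sample(5:12, 1)
    unit <- rand_dna(p)
    body <- paste(vapply(1:15, function(k)
      mutate_dna(unit, rbinom(1, p, 0.04)), ""), collapse = "")
    s <- paste0(rand_dna(250), body, rand_dna(100),
                strrep(rand_dna(6), 8), rand_dna(150))
    got <- find_tandem_arrays(s, min_unit = 4, max_unit = 30)
    want <- oracle_tandem_arrays(s, min_unit = 4, max_unit = 30)
    expect_equal(got[, c("start", "end", "unit_length", "copies")],
                 want[, c("start", "end", "unit_length", "copies")],
                 ignore_attr = TRUE)
  }
})

test_that("N breaks arrays", {
  s <- paste0(strrep("ACGT", 30), "N", strrep("ACGT", 30))
  arr <- find_tandem_arrays(s, max_divergence = 0)
  expect_equal(nrow(arr), 2L)
})

test_that("abundance histogram aggregates bp by unit length", {
  set.seed(2)
  s <- strrep("ACGTGTCAGTCA", 100)
  arr <- find_tandem_arrays(s, max_divergence = 0)
  h <- abundance_histogram(arr)
  expect_equal(h$unit_length, 12L)
  expect_equal(h$total_bp, 1200)
  expect_equal(attr(h, "modal_length"), 12L)
  h0 <- abundance_histogram(arr[0, ])
  expect_equal(nrow(h0), 0L)
  # totals conserved: sum of class bp equals sum of interval lengths
  expect_equal(sum(h$total_bp), sum(arr$end - arr$start))
})

test_that("HOR decomposition matches constructed units and the oracle", {
  set.seed(44)
  base <- rand_dna(21)
  u84 <- paste(vapply(1:4, function(i) mutate_dna(base, 1), ""),
               collapse = "")
  d84 <- hor_decompose(u84, 0.10)
  expect_equal(d84$fundamental_period, 21L)
  expect_equal(d84$n_subunits, 4L)
  expect_lte(d84$subunit_divergence, 0.05)

  u63 <- paste(vapply(1:3, function(i) mutate_dna(base, 1), ""),
               collapse = "")
  expect_equal(hor_decompose(u63, 0.10)$n_subunits, 3L)

  # random unit has no substructure
  r100 <- rand_dna(100)
  expect_equal(hor_decompose(r100, 0.10),
               list(fundamental_period = 100L, n_subunits = 1L,
                    subunit_divergence = 0))

  # inverse pair: concatenating n copies then decomposing returns (|u|, n)
  for (i in 1:10) {
    p <- sample(4:25, 1)
    n <- sample(2:6, 1)
    u <- rand_dna(p)
    if (hor_decompose(u, 0)$fundamental_period < p) next
    got <- hor_decompose(strrep(u, n), 0)
    expect_equal(got$fundamental_period, p)
    expect_equal(got$n_subunits, n)
  }

  # equality with the explicit divisor-scan oracle
  for (i in 1:10) {
    n <- sample(c(12, 18, 24, 36, 84), 1)
    u <- if (runif(1) < 0.5) rand_dna(n) else
      strrep(rand_dna(n / sample(c(2, 3), 1)), sample(c(2, 3), 1))
    u <- substr(u, 1, n)
    expect_equal(hor_decompose(u, 0.1), oracle_hor(u, 0.1),
                 ignore_attr = TRUE)
  }
})

test_that("unit clustering follows greedy identity/length rules", {
  expect_equal(max(cluster_units(c("ACGTACGTAA", "ACGTACGTAA"))$cluster), 1L)
  # length gap beyond the cutoff forces separate clusters
  two <- cluster_units(c(rand_dna(21), rand_dna(99)))
  expect_equal(sort(unique(two$cluster)), c(1L, 2L))
  expect_error(cluster_units("ACGT", identity = 0), "identity")

  # rotated/strand-shifted copies of one unit join its cluster
  set.seed(8)
  u <- rand_dna(30)
  rot <- paste0(substr(u, 11, 30), substr(u, 1, 10))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(u)))
  cl <- cluster_units(c(u, rot, rc, rand_dna(30)))
  expect_equal(length(unique(cl$cluster[1:3])), 1L)

  # partition equals an exhaustive pairwise-threshold check under the same
  # longest-first visiting order
  for (rep in 1:3) {
    units <- c(replicate(4, rand_dna(sample(10:40, 1))))
    units <- c(units, vapply(units[1:2], function(x)
      mutate_dna(x, 1), ""))
    got <- cluster_units(units)
    ord <- order(-nchar(units), units)
    reps <- character(); assign <- integer(length(units))
    for (k in ord) {
      placed <- FALSE
      for (ci in seq_along(reps)) {
        if (abs(nchar(units[k]) - nchar(reps[ci])) <= 10 &&
            centrokaryo:::unit_identity(units[k], reps[ci]) >= 0.9) {
          assign[k] <- ci; placed <- TRUE; break
        }
      }
      if (!placed) { reps <- c(reps, units[k]); assign[k] <- length(reps) }
    }
    expect_equal(got$cluster, assign)
  }
})

test_that("satellite density track finds the planted centromere window", {
  reps <- data.frame(chrom = "chr1",
                     start = c(110000, 115000, 250000),
                     end = c(114000, 118000, 251000),
                     family = "cenSat", repeat_class = "satellite")
  a <- toy_assembly(len = 300000, repeats = reps)
  tr <- satellite_density_track(a, "cenSat", 1e5)
  cand <- attr(tr, "candidates")
  expect_equal(cand$start, 1e5)
  expect_equal(sum(tr$value), 8000)
  # absent family: all-zero track, candidate flagged none
  tr0 <- satellite_density_track(a, "nope", 1e5)
  expect_true(all(tr0$value == 0))
  expect_equal(attr(tr0, "candidates")$flag, "none")
})

test_that("collapsed-array copy estimate scales by the coverage ratio", {
  expect_equal(collapsed_copy_estimate(278, 650, 118), 278 * 650 / 118)
  expect_equal(round(collapsed_copy_estimate(278, 650, 118)), 1531)
  expect_equal(collapsed_copy_estimate(100, 40, 40), 100)
  expect_equal(collapsed_copy_estimate(10, 8500, 40), 10 * 212.5)
  expect_error(collapsed_copy_estimate(1, 1, 0), "genome_mean_coverage")
})
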