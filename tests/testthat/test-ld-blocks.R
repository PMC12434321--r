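test_that("two-locus EM recovers complete LD and linkage equilibrium exactly", {
  # only AB/ab haplotypes at f = 0.5: genotypes perfectly coupled
  set.seed(51)
  hap <- rep(c(0L, 1L), each = 20)     # one haplotype pool
  g1 <- matrix(hap, 40)[sample(40), , drop = FALSE]
  # individuals = random unions
  pick <- matrix(sample(rep(c(0L, 1L), each = 30)), ncol = 2)
  gA <- pick[, 1] + pick[, 2]          # same at both sites (coupling)
  r <- pair_r2(hard_triplet(gA), hard_triplet(gA))
  expect_equal(r$r2, 1, tolerance = 1e-6)

  # all four haplotypes at 0.25: independent sites
  h1 <- sample(rep(0:1, each = 40)); h2 <- sample(rep(0:1, each = 40))
  m1 <- h1[1:40] + h1[41:80]
  m2 <- h2[1:40] + h2[41:80]
  r0 <- pair_r2(hard_triplet(m1), hard_triplet(m2))
  # sampling noise only; the estimator itself is exact at the EM optimum
  expect_lt(r0$r2, 0.1)

  # deterministic equilibrium: equal counts of all nine genotype pairs
  g1d <- rep(0:2, each = 3); g2d <- rep(0:2, times = 3)
  w <- c(1, 2, 1)
  gg1 <- rep(g1d, times = w[g1d + 1] * w[g2d + 1])
  gg2 <- rep(g2d, times = w[g1d + 1] * w[g2d + 1])
  re <- pair_r2(hard_triplet(gg1), hard_triplet(gg2))
  expect_lt(re$r2, 1e-6)
})

test_that("two-locus EM matches the closed form on hard unambiguous genotypes", {
  # no double heterozygotes: phase is unambiguous, haplotype counts are
  # directly countable
  g1 <- c(0, 0, 1, 2, 2, 1, 0, 2)
  g2 <- c(0, 0, 0, 2, 2, 2, 0, 2)   # het pairs (1,0) and (1,2): resolved
  est <- pair_r2(hard_triplet(g1), hard_triplet(g2))
  # direct haplotype counts
  hap <- matrix(0, 4, 1)
  n <- length(g1)
  counts <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in seq_len(n)) {
    # enumerate the unique phasing
    a <- g1[i]; b <- g2[i]
    h1 <- c(min(a, 1), min(b, 1))
    h2 <- c(a - h1[1], b - h1[2])
    for (h in list(h1, h2)) {
      key <- 1 + h[1] * 2 + h[2]
      counts[key] <- counts[key] + 1
    }
  }
  hfreq <- counts / (2 * n)
  f1 <- hfreq[3] + hfreq[4]; f2 <- hfreq[2] + hfreq[4]
  D <- hfreq[4] - f1 * f2
  r2_direct <- D^2 / (f1 * (1 - f1) * f2 * (1 - f2))
  expect_equal(est$r2, unname(r2_direct), tolerance = 1e-6)
})

test_that("two-locus EM log-likelihood is monotone and r2 tracks truth at low coverage", {
  set.seed(53)
  hfreq <- c(AB = 0.4, Ab = 0.1, aB = 0.1, ab = 0.4)
  f1 <- 0.5; f2 <- 0.5
  D <- hfreq["ab"] - f1 * f2
  r2_true <- unname(D^2 / (f1 * (1 - f1) * f2 * (1 - f2)))
  n <- 100
  hap_a1 <- c(0, 0, 1, 1); hap_a2 <- c(0, 1, 0, 1)
  draw <- function() {
    h <- sample(1:4, 2 * n, replace = TRUE, prob = hfreq)
    g1 <- hap_a1[h[1:n]] + hap_a1[h[(n + 1):(2 * n)]]
    g2 <- hap_a2[h[1:n]] + hap_a2[h[(n + 1):(2 * n)]]
    # realised-haplotype r2: the oracle for this draw
    hf <- tabulate(h, 4) / (2 * n)
    f1r <- hf[3] + hf[4]; f2r <- hf[2] + hf[4]
    r2r <- (hf[4] - f1r * f2r)^2 / (f1r * (1 - f1r) * f2r * (1 - f2r))
    d1 <- rpois(n, 10); d2 <- rpois(n, 10)
    nm1 <- rbinom(n, d1, 0.01 + g1 / 2 * 0.98)
    nm2 <- rbinom(n, d2, 0.01 + g2 / 2 * 0.98)
    list(gl1 = gl_from_counts(d1 - nm1, nm1, 0.01),
         gl2 = gl_from_counts(d2 - nm2, nm2, 0.01),
         r2_realised = r2r)
  }
  # haplotype sampling noise dominates the deviation from the parametric
  # 0.36 (hard genotypes show the same spread), so score the estimator
  # against each draw's realised haplotype frequencies
  errs <- replicate(12, {
    x <- draw()
    r <- pair_r2(x$gl1, x$gl2, track_loglik = TRUE)
    expect_true(all(diff(r$trace) > -1e-6))
    abs(r$r2 - x$r2_realised)
  })
  expect_lt(mean(errs), 0.05)
})

test_that("LD decay fit recovers a known exponential and flags constants", {
  set.seed(55)
  d <- sample.int(1e5, 4000, replace = TRUE)
  pairs <- data.frame(dist = d, r2 = exp(-d / 15000))
  dec <- ld_decay(pairs, max_dist = 1e5)
  expect_false(dec$degenerate)
  expect_lt(abs(dec$tau - 15000) / 15000, 0.1)
  expect_equal(dec$half_decay, dec$tau * log(2))

  flat <- data.frame(dist = d, r2 = 0.3)
  expect_true(ld_decay(flat, max_dist = 1e5)$degenerate)

  expect_error(ld_decay(data.frame(dist = c(100, 150), r2 = c(1, 1)),
                        max_dist = 1e5), "bins")
})

test_that("greedy pruning matches forced cases and the step-by-step oracle", {
  # nothing above the weight threshold: everything survives
  pos <- c(100, 200, 300)
  weak <- data.frame(a = c(1, 1, 2), b = c(2, 3, 3), r2 = c(0.3, 0.2, 0.39),
                     dist = c(100, 200, 100))
  expect_equal(prune_linked(pos, weak, min_weight = 0.4), 1:3)

  # complete triangle: exactly one survivor
  tri <- data.frame(a = c(1, 1, 2), b = c(2, 3, 3), r2 = 0.9,
                    dist = c(100, 200, 100))
  expect_equal(length(prune_linked(pos, tri, min_weight = 0.4)), 1)

  # random 50-node graphs against the oracle
  set.seed(57)
  for (rep in 1:3) {
    n <- 50
    pos <- sort(sample.int(1e5, n))
    pr <- t(utils::combn(n, 2))
    keep <- runif(nrow(pr)) < 0.08
    ed <- data.frame(a = pr[keep, 1], b = pr[keep, 2],
                     r2 = round(runif(sum(keep), 0.4, 1), 2))
    ed$dist <- pos[ed$b] - pos[ed$a]
    got <- prune_linked(pos, ed, min_weight = 0.4, max_dist = 0)
    expect_equal(got, prune_oracle(pos, ed))
  }
})

test_that("window-pair statistics use the requested quantile", {
  # constant field: every non-empty cell equals the constant
  set.seed(59)
  pos <- sort(sample.int(2e6, 80))
  pr <- t(utils::combn(length(pos), 2))
  pairs <- data.frame(pos_a = pos[pr[, 1]], pos_b = pos[pr[, 2]], r2 = 0.5)
  w <- window_pair_matrix(pairs, window = 250000, q = 0.3)
  expect_true(all(w$stat[!is.na(w$stat)] == 0.5))

  # quantile oracle: one cell holding 0.1..0.9, manual type-7 interpolation
  pairs9 <- data.frame(pos_a = rep(10, 9), pos_b = rep(300000, 9),
                       r2 = seq(0.1, 0.9, by = 0.1))
  w9 <- window_pair_matrix(pairs9, window = 250000, q = 0.98)
  h <- (9 - 1) * 0.98 + 1
  manual <- 0.1 * (floor(h) + (h - floor(h))) / 1  # x[k] + frac*(x[k+1]-x[k])
  manual <- seq(0.1, 0.9, by = 0.1)[floor(h)] +
    (h - floor(h)) * 0.1
  expect_equal(w9$stat[1, 2], manual)

  # subsampled matrix is deterministic under a fixed seed
  wa <- window_pair_matrix(pairs, window = 250000, q = 0.9,
                           subsample = 0.5, seed = 4)
  wb <- window_pair_matrix(pairs, window = 250000, q = 0.9,
                           subsample = 0.5, seed = 4)
  expect_identical(wa$stat, wb$stat)

  expect_error(window_pair_matrix(pairs, window = 0), "window")
})

test_that("haploblock detection finds planted squares and nothing in noise", {
  mk_wpm <- function(stat) {
    structure(list(stat = stat, window = 250000, q = 0.98, chrom = "c1",
                   n_win = nrow(stat)), class = "window_pair_matrix")
  }
  # uniform low background: no blocks
  w <- 40
  base <- matrix(0.1, w, w)
  expect_equal(nrow(detect_haploblocks(mk_wpm(base), min_span = 1e6)), 0)

  # one planted 20-window square
  m <- base
  m[11:30, 11:30] <- 0.9
  got <- detect_haploblocks(mk_wpm(m), min_span = 1e6)
  expect_equal(nrow(got), 1)
  expect_lte(abs(got$start / 250000 - 10), 1)
  expect_lte(abs(got$end / 250000 - 30), 1)

  # two disjoint squares, reported in order
  m2 <- base
  m2[3:10, 3:10] <- 0.9
  m2[25:38, 25:38] <- 0.9
  got2 <- detect_haploblocks(mk_wpm(m2), min_span = 1e6)
  expect_equal(nrow(got2), 2)
  expect_lt(got2$start[1], got2$start[2])

  # invariant to appending all-missing windows at the ends
  m3 <- matrix(NA_real_, w + 10, w + 10)
  m3[6:(w + 5), 6:(w + 5)] <- m
  got3 <- detect_haploblocks(mk_wpm(m3), min_span = 1e6)
  expect_equal(nrow(got3), 1)
  expect_equal(got3$end - got3$start, got$end - got$start,
               tolerance = 0.11)
})
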