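test_that("genotype likelihoods from counts follow the symmetric-error model", {
  # no data: uniform, flagged by uniformity rather than error
  expect_equal(as.numeric(gl_from_counts(0, 0, 0.01)), rep(1 / 3, 3))

  # error-free limit: all-major reads exclude the minor homozygote;
  # the heterozygote keeps its (1/2)^n sampling term, so the limit
  # triplet is (8/9, 1/9, 0)
  g <- gl_from_counts(3, 0, 1e-9)
  expect_equal(as.numeric(g), c(8 / 9, 1 / 9, 0), tolerance = 1e-6)
  expect_lt(g[3], 1e-20)

  # closed-form check for (1, 2) reads at eps = 0.01
  eps <- 0.01
  direct <- vapply(0:2, function(gg) {
    pm <- (1 - gg / 2) * (1 - eps) + (gg / 2) * eps
    pm^1 * (1 - pm)^2
  }, numeric(1))
  expect_equal(as.numeric(gl_from_counts(1, 2, eps)),
               direct / sum(direct), tolerance = 1e-12)

  # heterozygote term is (1/2)^(n_major + n_minor) before normalisation
  raw_het <- 0.5^(4 + 3)
  got <- gl_from_counts(4, 3, eps)
  pm0 <- (1 - eps); pm2 <- eps
  raw <- c(pm0^4 * (1 - pm0)^3, raw_het, pm2^4 * (1 - pm2)^3)
  expect_equal(as.numeric(got), raw / sum(raw), tolerance = 1e-12)
})

test_that("depth filter reproduces mean +/- c*sd bounds and the brute-force mask", {
  # totals {474, 575, 676}: mean 575, sd 101 -> bounds (474, 676)
  depth <- cbind(c(474, 575, 676), 0, 0)
  df <- depth_filter(depth, c_sd = 1, min_ind = 1)
  expect_equal(unname(df$bounds), c(474, 676))
  expect_true(all(df$mask))

  # degenerate histogram: sd 0, everything passes
  du <- matrix(10L, 5, 4)
  expect_true(all(depth_filter(du, c_sd = 1, min_ind = 1)$mask))

  # random matrix against per-site recomputation
  set.seed(91)
  d <- matrix(rpois(300 * 12, 4), 300, 12)
  got <- depth_filter(d, c_sd = 0.8, min_ind = 5)
  tot <- rowSums(d)
  lo <- mean(tot) - 0.8 * sd(tot); hi <- mean(tot) + 0.8 * sd(tot)
  manual <- vapply(seq_len(nrow(d)), function(i) {
    tot[i] >= lo && tot[i] <= hi && sum(d[i, ] > 0) >= 5
  }, logical(1))
  expect_equal(got$mask, manual)
})

test_that("EM allele frequency matches forced cases and the grid-search oracle", {
  het <- matrix(rep(c(0, 1, 0), each = 10), 10)
  expect_equal(em_maf(het)$f, 0.5, tolerance = 1e-6)
  hom <- matrix(rep(c(1, 0, 0), each = 10), 10)
  expect_lt(em_maf(hom)$f, 1e-5)

  set.seed(7)
  for (rep in 1:5) {
    f_true <- runif(1, 0.1, 0.5)
    g <- rbinom(8, 2, f_true)
    gl <- gl_from_counts(rpois(8, 4), 0, 0.05)   # start from counts...
    d <- rpois(8, 4)
    nm <- rbinom(8, d, 0.01 + (g / 2) * 0.98)
    gl <- gl_from_counts(d - nm, nm, 0.01)
    est <- em_maf(gl)
    expect_lt(abs(est$f - maf_grid_oracle(gl)), 1e-3)
  }
})

test_that("EM allele-frequency log-likelihood is monotone over iterations", {
  set.seed(12)
  d <- rpois(30, 3)
  g <- rbinom(30, 2, 0.3)
  nm <- rbinom(30, d, 0.01 + (g / 2) * 0.98)
  gl <- gl_from_counts(d - nm, nm, 0.01)
  tr <- em_maf(gl, track_loglik = TRUE)$trace
  expect_true(all(diff(tr) > -1e-9))
})

test_that("SNP calling applies the MAF floor, drops monomorphic sites, and controls type-I error", {
  n <- 100
  # hard-call sites: f_hat 0.30 (kept); f_hat 0.04 (< MAF floor,
  # excluded regardless of p); monomorphic (LRT 0, excluded)
  genos <- rbind(c(rep(1L, 60), rep(0L, 40)),
                 c(rep(1L, 8), rep(0L, 92)),
                 rep(0L, n))
  gl <- array(0, c(3, n, 3))
  for (i in 1:3) gl[i, , ] <- hard_triplet(genos[i, ])
  depth <- matrix(10L, 3, n)
  ds <- gl_dataset(data.frame(chrom = "c1", pos = c(10L, 20L, 30L),
                              major = "A", minor = "C"),
                   sprintf("i%02d", 1:n), gl, depth)
  st <- call_snps(ds, p_threshold = 1e-6, min_maf = 0.05)
  expect_true(10 %in% st$position)
  expect_false(20 %in% st$position)
  expect_false(30 %in% st$position)

  # type-I: monomorphic sites essentially never pass p < 1e-6
  s <- 1000
  geno0 <- matrix(0L, s, n)
  ds0 <- gl_from_genotypes(geno0, seq_len(s) * 10L, depth_mean = 10)
  st0 <- call_snps(ds0, p_threshold = 1e-6, min_maf = 0)
  expect_lte(nrow(st0) / s, 1e-4)
})

test_that("covariance PCA separates clones and matches the truth-genotype oracle", {
  # two clone pairs differing at every site
  s <- 60
  gA <- matrix(0L, s, 2); gB <- matrix(2L, s, 2)
  geno <- cbind(gA, gB)
  gl <- array(0, c(s, 4, 3))
  for (i in 1:4) gl[, i, ] <- hard_triplet(geno[, i])
  ds <- gl_dataset(data.frame(chrom = "c1", pos = seq_len(s) * 5L,
                              major = "A", minor = "C"),
                   paste0("i", 1:4), gl)
  st <- data.frame(chromo = "c1", position = seq_len(s) * 5L,
                   major = "A", minor = "C", freq_em = 0.5,
                   pvalue = 0, n_ind = 4)
  p <- covariance_pca(ds, st)
  expect_gte(p$pct_var[1], 99)
  expect_gt(abs(mean(p$scores[1:2, 1]) - mean(p$scores[3:4, 1])), 0.1)

  # high depth: covariance close to the same formula on true genotypes
  set.seed(31)
  n <- 30; s <- 400
  f <- runif(s, 0.1, 0.5)
  geno <- matrix(rbinom(s * n, 2, rep(f, n)), s, n)
  ds <- gl_from_genotypes(geno, sort(sample.int(1e6, s)), depth_mean = 30)
  st <- call_snps(ds, p_threshold = 0.999999, min_maf = 0.01)
  p <- covariance_pca(ds, st)
  idx <- st$site_index
  fe <- st$freq_em
  gm <- geno[idx, , drop = FALSE]
  flip <- abs(colMeans(t(gm)) / 2 - fe) > abs(1 - colMeans(t(gm)) / 2 - fe)
  gm[flip, ] <- 2 - gm[flip, ]
  dn <- (gm - 2 * fe) / sqrt(2 * fe * (1 - fe))
  ctruth <- crossprod(dn) / length(fe)
  expect_lt(max(abs(p$cov - ctruth)), 0.02)

  # permutation equivariance
  perm <- sample(n)
  ds_p <- gl_subset(ds, individuals = perm)
  p2 <- covariance_pca(ds_p, st)
  expect_equal(unname(p2$cov), unname(p$cov[perm, perm]), tolerance = 1e-10)
})

test_that("group genotype frequencies reduce to counting and match the grid oracle", {
  gl <- rbind(hard_triplet(rep(0L, 2)), hard_triplet(rep(1L, 6)),
              hard_triplet(rep(2L, 2)))
  gf <- group_genotype_freq(gl)
  expect_equal(gf$p, c(0.2, 0.6, 0.2), tolerance = 1e-6)
  expect_equal(gf$hobs, 0.6, tolerance = 1e-6)

  expect_lt(group_genotype_freq(hard_triplet(rep(0L, 5)))$hobs, 1e-8)

  set.seed(41)
  d <- rpois(12, 4)
  g <- sample(0:2, 12, replace = TRUE)
  nm <- rbinom(12, d, 0.01 + (g / 2) * 0.98)
  gl <- gl_from_counts(d - nm, nm, 0.01)
  est <- group_genotype_freq(gl)
  oracle <- genofreq_grid_oracle(gl)
  expect_lt(max(abs(est$p - oracle)), 0.02)
})
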