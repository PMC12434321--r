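test_that("a fixed seed reproduces the cohort, environment and mitogenomes exactly", {
  cfg <- sim_config(n_demes = 2, n_per_deme = 10, chrom_length = 2e6,
                    n_sites = 200, inversion_interval = c(5e5, 1.5e6),
                    inversion_freq_per_deme = c(0.5, 0), seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gl$gl, b$gl$gl)
  expect_identical(a$gl$depth, b$gl$depth)
  expect_identical(a$truth$true_genotypes, b$truth$true_genotypes)
  expect_identical(a$truth$arrangement_labels, b$truth$arrangement_labels)
  expect_identical(simulate_env(cfg, a$truth), simulate_env(cfg, b$truth))
  ma <- simulate_mito(cfg, a$truth)
  mb <- simulate_mito(cfg, b$truth)
  expect_identical(ma$sequences, mb$sequences)
})

test_that("genotypes, arrangements and karyotypes are mutually consistent", {
  sim <- small_sim()
  tr <- sim$truth
  n_inv <- rowSums(tr$arrangement_labels == "INV")
  expect_identical(tr$karyotype,
                   c("STD/STD", "STD/INV", "INV/INV")[n_inv + 1L])
  expect_true(all(tr$true_genotypes %in% 0:2))
  # minor-allele orientation: every site at frequency <= 0.5
  expect_true(all(rowMeans(tr$true_genotypes) / 2 <= 0.5 + 1e-12))
})

test_that("zero inversion frequency leaves no arrangement signal in LD", {
  cfg <- sim_config(n_demes = 2, n_per_deme = 100, chrom_length = 4e6,
                    n_sites = 300, inversion_interval = c(1e6, 3e6),
                    inversion_freq_per_deme = c(0, 0), mean_depth = 10,
                    recomb_rate = 4e6 / 15000, seed = 17)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$arrangement_labels == "STD"))
  st <- call_snps(sim$gl)
  set.seed(1)
  idx <- sort(sample(st$site_index, 120))
  sub <- gl_subset(sim$gl, sites = idx)
  inside <- sub$sites$pos > 1e6 & sub$sites$pos <= 3e6
  pr <- site_pairs(sub$sites$pos)
  pairs <- pair_r2_batch(sub, pr, max_iter = 200, tol = 1e-6)
  grp_in <- inside[pairs$a] & inside[pairs$b]
  grp_out <- !inside[pairs$a] & !inside[pairs$b]
  # long-range pairs only, away from the founder-mosaic decay scale
  long <- pairs$dist > 1e5
  expect_lt(abs(mean(pairs$r2[grp_in & long]) - mean(pairs$r2[grp_out & long])),
            0.05)
})

test_that("true-genotype heterozygosity inside the interval orders het > STD/STD > INV/INV", {
  cfg <- sim_config(n_demes = 1, n_per_deme = 60, chrom_length = 8e6,
                    n_sites = 600, inversion_interval = c(2e6, 6e6),
                    inversion_freq_per_deme = 0.5, seed = 23)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  hobs_true <- function(k) {
    g <- tr$true_genotypes[tr$inside_interval, tr$karyotype == k, drop = FALSE]
    mean(g == 1)
  }
  expect_gt(hobs_true("STD/INV"), hobs_true("STD/STD"))
  expect_gt(hobs_true("STD/STD"), hobs_true("INV/INV"))
})

test_that("an inversion frequency with no sites in the interval errors", {
  cfg <- sim_config(n_demes = 1, n_per_deme = 5, chrom_length = 1e6,
                    n_sites = 10, inversion_interval = c(999990, 999995),
                    inversion_freq_per_deme = 0.5, seed = 3)
  expect_error(simulate_cohort(cfg), "no sites")
})

test_that("LD decays on the scale implied by the recombination rate", {
  # default preset: segment length ~30 kb, hence an r2 decay scale of
  # ~15 kb (both haplotypes must share a founder segment)
  cfg <- sim_config(n_demes = 1, n_per_deme = 80, chrom_length = 2e6,
                    n_sites = 500, inversion_interval = c(1, 2),
                    inversion_freq_per_deme = 0, mean_depth = 10,
                    seed = 29)
  sim <- simulate_cohort(cfg)
  st <- call_snps(sim$gl)
  sub <- gl_subset(sim$gl, sites = st$site_index)
  pr <- site_pairs(sub$sites$pos, max_dist = 1e5)
  pairs <- pair_r2_batch(sub, pr, max_iter = 200, tol = 1e-6)
  dec <- ld_decay(pairs, max_dist = 1e5, bin_width = 2000)
  expect_false(dec$degenerate)
  # half-decay within a factor 2 of the 15 kb segment-length preset
  expect_gt(dec$half_decay, 15000 / 2)
  expect_lt(dec$half_decay, 15000 * 2)
})

test_that("arrangement-diagnostic sites are in complete LD on pure haplotypes", {
  sim <- small_sim()
  tr <- sim$truth
  # diagnostic sites: fixed difference between arrangements in truth
  inv_ind <- tr$karyotype == "INV/INV"
  std_ind <- tr$karyotype == "STD/STD"
  g_inv <- tr$true_genotypes[, inv_ind, drop = FALSE]
  g_std <- tr$true_genotypes[, std_ind, drop = FALSE]
  diag_sites <- which(tr$inside_interval &
                        apply(g_inv, 1, function(r) length(unique(r)) == 1) &
                        apply(g_std, 1, function(r) length(unique(r)) == 1) &
                        g_inv[, 1] != g_std[, 1])
  expect_gt(length(diag_sites), 10)
  # correlation of true genotypes across diagnostic sites is 1
  cc <- cor(t(tr$true_genotypes[diag_sites, ]))
  expect_true(all(abs(cc) > 0.999))
})

test_that("environmental covariates track arrangement frequency and stay non-collinear", {
  cfg <- sim_config(n_demes = 6, n_per_deme = 12, chrom_length = 2e6,
                    n_sites = 150, inversion_interval = c(5e5, 1.5e6),
                    inversion_freq_per_deme = c(0.6, 0.4, 0.2, 0, 0, 0),
                    seed = 31)
  sim <- simulate_cohort(cfg)
  env <- simulate_env(cfg, sim$truth)
  expect_equal(nrow(env), 6)
  expect_true(all(c("temperature", "pH", "streamflow") %in% names(env)))
  cm <- cor(env[, c("temperature", "pH", "streamflow")])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.70)
  expect_gt(cor(env$temperature, env$inv_freq), 0)
  # broadcast to individuals
  bi <- env_by_individual(env, sim$truth)
  expect_equal(nrow(bi), length(sim$truth$individuals))
  expect_equal(bi$temperature[1], env$temperature[1])
})

test_that("mitochondrial radiation is star-like with bounded pairwise distances", {
  cfg <- sim_config(n_demes = 2, n_per_deme = 30, chrom_length = 2e6,
                    n_sites = 150, inversion_interval = c(5e5, 1.5e6),
                    inversion_freq_per_deme = c(0.5, 0), mito_length = 2000,
                    n_mito_haplotypes = 8, seed = 37)
  sim <- simulate_cohort(cfg)
  mito <- simulate_mito(cfg, sim$truth)
  expect_equal(length(mito$hap_sequences), 8)
  d <- hamming_matrix_test(mito$hap_sequences)
  expect_lte(max(d), 2 * cfg$mito_step_range[2])
  # distances from the centre equal the drawn step counts
  expect_equal(unname(d[1, -1]), unname(mito$steps[-1]))
  # at least two haplotypes shared by carriers and non-carriers
  carriers <- sim$truth$individuals[sim$truth$karyotype != "STD/STD"]
  hs <- collapse_haplotypes(mito$sequences)
  shared <- vapply(hs$members, function(mm) {
    any(mm %in% carriers) && any(!mm %in% carriers)
  }, logical(1))
  expect_gte(sum(shared), 2)
})

test_that("mito_length too short for the requested steps errors", {
  cfg <- sim_config(n_demes = 1, n_per_deme = 10, chrom_length = 1e6,
                    n_sites = 50, inversion_interval = c(1e5, 9e5),
                    inversion_freq_per_deme = 0, mito_length = 10,
                    n_mito_haplotypes = 10, mito_step_range = c(5, 7),
                    seed = 5)
  sim <- simulate_cohort(cfg)
  expect_error(simulate_mito(cfg, sim$truth), "mito_length")
})
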