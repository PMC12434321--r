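# Fixtures built in code: hard-call triplets, datasets from genotype
# matrices, and a memoised small simulated cohort shared across tests.

hard_triplet <- function(g) {
  out <- matrix(0, length(g), 3)
  out[cbind(seq_along(g), g + 1L)] <- 1
  out
}

# gl_dataset from a true genotype matrix (sites x individuals) with
# Poisson depth and symmetric read error
gl_from_genotypes <- function(geno, pos, depth_mean, eps = 0.01,
                              chrom = "chrT", depth = NULL) {
  s <- nrow(geno); n <- ncol(geno)
  if (is.null(depth)) depth <- matrix(rpois(s * n, depth_mean), s, n)
  p_minor <- eps + (geno / 2) * (1 - 2 * eps)
  n_minor <- matrix(rbinom(s * n, depth, p_minor), s, n)
  glm <- gl_from_counts(as.vector(depth - n_minor), as.vector(n_minor), eps)
  gl_dataset(
    sites = data.frame(chrom = chrom, pos = pos, major = "A", minor = "C",
                       stringsAsFactors = FALSE),
    individuals = sprintf("t%03d", seq_len(n)),
    gl = array(glm, dim = c(s, n, 3)), depth = depth
  )
}

hamming_matrix_test <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

local({
  cache <- new.env(parent = emptyenv())
  small_sim <<- function() {
    if (is.null(cache$sim)) {
      cfg <- sim_config(
        n_demes = 2, n_per_deme = 30, chrom_length = 10e6, n_sites = 1000,
        inversion_interval = c(3e6, 7e6),
        inversion_freq_per_deme = c(0.4, 0.1),
        recomb_rate = 10e6 / 15000, mean_depth = 3, seed = 11
      )
      sim <- simulate_cohort(cfg)
      sim$config <- cfg
      sim$snps <- call_snps(sim$gl)
      cache$sim <- sim
    }
    cache$sim
  }
})
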