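# Genotype-likelihood engine: likelihoods from read counts, depth
# filtering, EM allele frequencies, LRT SNP calling, posterior-dosage
# covariance PCA, and per-group genotype-frequency (H_obs) estimation.
#
# Model: biallelic sites, symmetric per-read error rate eps. For genotype
# g in {0,1,2} copies of the minor allele,
#   P(read = major | g) = (1 - g/2)(1 - eps) + (g/2) eps
# so L(g) = P(major)^n_major * P(minor)^n_minor, returned normalised.

#' Genotype likelihoods from allele-specific read counts
#'
#' @param n_major,n_minor non-negative integer vectors (recycled) of reads
#'   supporting the major and minor allele.
#' @param eps per-read error probability, in (0, 0.5).
#' @return matrix `length x 3` of normalised likelihoods for 0, 1, 2 minor
#'   copies. Sites/individuals with no reads get the uniform triplet.
#' @export
gl_from_counts <- function(n_major, n_minor, eps) {
  stopifnot(eps > 0, eps < 0.5, all(n_major >= 0), all(n_minor >= 0))
  n <- max(length(n_major), length(n_minor))
  n_major <- rep_len(as.numeric(n_major), n)
  n_minor <- rep_len(as.numeric(n_minor), n)
  # P(major read | g) for g = 0, 1, 2
  pm <- c(1 - eps, 0.5, eps)
  ll <- sapply(1:3, function(g) {
    n_major * log(pm[g]) + n_minor * log(1 - pm[g])
  })
  ll <- matrix(ll, nrow = n)
  ll <- ll - apply(ll, 1, max)
  l <- exp(ll)
  l / rowSums(l)
}

#' Depth-based site filter
#'
#' Bounds are `mean +/- c * sd` of the per-site total read depth, after the
#' common practice of inspecting the global depth histogram. A site passes
#' when its total depth lies within the bounds (inclusive) and at least
#' `min_ind` individuals carry a read.
#'
#' @param depth integer matrix `n_sites x n_ind`.
#' @param c_sd standard-deviation multiplier (default 1).
#' @param min_ind minimum number of individuals with >= 1 read.
#' @return object of class `depth_filter`: bounds, summary stats, and the
#'   logical site `mask`.
#' @export
depth_filter <- function(depth, c_sd = 1, min_ind = 1L) {
  depth <- as.matrix(depth)
  total <- rowSums(depth)
  mu <- mean(total)
  sigma <- sd(total)
  if (is.na(sigma)) sigma <- 0
  lo <- mu - c_sd * sigma
  hi <- mu + c_sd * sigma
  n_with <- rowSums(depth > 0)
  mask <- total >= lo & total <= hi & n_with >= min_ind
  if (!any(mask)) warning("all sites removed by the depth filter")
  structure(
    list(mean = mu, sd = sigma, multiplier = c_sd,
         bounds = c(min_depth = lo, max_depth = hi),
         min_ind = min_ind, mask = mask, total_depth = total),
    class = "depth_filter"
  )
}

#' @export
print.depth_filter <- function(x, ...) {
  cat(sprintf("depth_filter: mean %.1f sd %.1f c %.2f -> [%.0f, %.0f]; %d/%d sites pass\n",
              x$mean, x$sd, x$multiplier, x$bounds[1], x$bounds[2],
              sum(x$mask), length(x$mask)))
  invisible(x)
}

# Vectorised EM for the minor-allele frequency at many sites at once.
# l0/l1/l2: S x N matrices of normalised likelihoods. Returns f per site.
em_maf_matrix <- function(l0, l1, l2, tol = 1e-8, max_iter = 200L) {
  n_ind <- ncol(l0)
  # flat-prior dosage as the starting point
  tot <- l0 + l1 + l2
  f <- rowMeans((l1 + 2 * l2) / tot) / 2
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  for (it in seq_len(max_iter)) {
    p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f); p2 <- f^2
    w0 <- l0 * p0; w1 <- l1 * p1; w2 <- l2 * p2
    den <- w0 + w1 + w2
    eg <- (w1 + 2 * w2) / den
    f_new <- rowSums(eg) / (2 * n_ind)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  f
}

# log-likelihood of frequency f (vector per site) under the HWE prior
loglik_maf <- function(l0, l1, l2, f) {
  p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f); p2 <- f^2
  rowSums(log(l0 * p0 + l1 * p1 + l2 * p2))
}

#' EM estimate of the minor-allele frequency at one site
#'
#' Maximises `sum_i log sum_g P(g | f) L_i(g)` with the Hardy-Weinberg
#' prior `P(g | f) = Binom(2, f)` by expectation-maximisation:
#' `f_{t+1} = (1/2N) sum_i E[g_i | triplet_i, f_t]`.
#'
#' @param gl numeric matrix `N x 3` of likelihood triplets.
#' @param tol convergence tolerance on `|delta f|` (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @param track_loglik if TRUE, also return the per-iteration log-likelihood
#'   trace (used to assert EM monotonicity).
#' @return list with `f`, `loglik` (at the optimum) and optionally `trace`.
#' @export
em_maf <- function(gl, tol = 1e-8, max_iter = 200L, track_loglik = FALSE) {
  gl <- as.matrix(gl)
  stopifnot(ncol(gl) == 3L, nrow(gl) >= 1L)
  gl <- gl / rowSums(gl)
  l0 <- matrix(gl[, 1], 1); l1 <- matrix(gl[, 2], 1); l2 <- matrix(gl[, 3], 1)
  n_ind <- ncol(l0)
  f <- mean((l1 + 2 * l2)) / 2
  f <- min(max(f, 1e-6), 1 - 1e-6)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (track_loglik) trace <- c(trace, loglik_maf(l0, l1, l2, f))
    p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f); p2 <- f^2
    w0 <- l0 * p0; w1 <- l1 * p1; w2 <- l2 * p2
    den <- w0 + w1 + w2
    f_new <- sum((w1 + 2 * w2) / den) / (2 * n_ind)
    if (abs(f_new - f) < tol) { f <- f_new; break }
    f <- f_new
  }
  out <- list(f = f, loglik = loglik_maf(l0, l1, l2, f))
  if (track_loglik) out$trace <- c(trace, out$loglik)
  out
}

#' Likelihood-ratio SNP calling
#'
#' Estimates the minor-allele frequency at every (unmasked) site by EM,
#' orients alleles so the frequency is at most 0.5, and tests polymorphism
#' with `LRT = 2 (l(f_hat) - l(0))` against a chi-square with 1 df (no
#' boundary correction; conservative). Sites with
#' `p < p_threshold` and `f_hat >= min_maf` are kept.
#'
#' @param x a `gl_dataset`.
#' @param p_threshold SNP p-value threshold (default 1e-6).
#' @param min_maf minor-allele-frequency floor (default 0.05).
#' @param mask optional logical site mask (e.g. from [depth_filter()]).
#' @return data.frame site table with columns `chromo`, `position`,
#'   `major`, `minor`, `freq_em`, `lrt`, `pvalue`, `n_ind`, plus
#'   `site_index` into the dataset.
#' @export
call_snps <- function(x, p_threshold = 1e-6, min_maf = 0.05, mask = NULL) {
  stopifnot(inherits(x, "gl_dataset"))
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  idx <- seq_len(nrow(x$sites))
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(x$sites))
    idx <- idx[mask]
  }
  l0 <- x$gl[idx, , 1, drop = FALSE]
  l1 <- x$gl[idx, , 2, drop = FALSE]
  l2 <- x$gl[idx, , 3, drop = FALSE]
  dim(l0) <- dim(l1) <- dim(l2) <- c(length(idx), length(x$individuals))
  f <- em_maf_matrix(l0, l1, l2)
  # orient to the minor allele
  swap <- f > 0.5
  if (any(swap)) {
    tmp <- l0[swap, , drop = FALSE]
    l0[swap, ] <- l2[swap, , drop = FALSE]
    l2[swap, ] <- tmp
    f[swap] <- 1 - f[swap]
  }
  lrt <- 2 * (loglik_maf(l0, l1, l2, f) - loglik_maf(l0, l1, l2, rep(0, length(f))))
  lrt <- pmax(lrt, 0)
  pval <- pchisq(lrt, df = 1, lower.tail = FALSE)
  if (!is.null(x$depth)) {
    n_ind <- rowSums(x$depth[idx, , drop = FALSE] > 0)
  } else {
    informative <- abs(l0 - 1 / 3) + abs(l1 - 1 / 3) + abs(l2 - 1 / 3) > 1e-12
    n_ind <- rowSums(informative)
  }
  major <- ifelse(swap, x$sites$minor[idx], x$sites$major[idx])
  minor <- ifelse(swap, x$sites$major[idx], x$sites$minor[idx])
  keep <- pval < p_threshold & f >= min_maf
  data.frame(
    chromo = x$sites$chrom[idx], position = x$sites$pos[idx],
    major = major, minor = minor,
    freq_em = f, lrt = lrt, pvalue = pval, n_ind = n_ind,
    site_index = idx, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
}

#' Covariance PCA from genotype-likelihood posterior dosages
#'
#' Per SNP, the posterior mean dosage under the estimated allele frequency
#' is `g_hat_i = sum_g g P(g | f) L_i(g) / sum_g P(g | f) L_i(g)`; the
#' individual-by-individual covariance is
#' `C_jk = (1/M) sum_s (g_hat_js - 2 f_s)(g_hat_ks - 2 f_s) / (2 f_s (1 - f_s))`.
#' Individuals without data contribute the prior mean `2 f` and hence zero
#' to the centred sum. Eigendecomposition gives axis scores and percent
#' variance (positive eigenvalues only).
#'
#' @param x a `gl_dataset`.
#' @param site_table site table from [call_snps()] (any subset); alleles may
#'   be oriented either way relative to the dataset.
#' @return object of class `pca_result`: `cov`, `values`, `vectors`,
#'   `scores` (vectors scaled by sqrt of eigenvalue), `pct_var`.
#' @export
covariance_pca <- function(x, site_table) {
  stopifnot(inherits(x, "gl_dataset"), nrow(site_table) >= 2L,
            length(x$individuals) >= 2L)
  m <- match_sites(x, site_table)
  l0 <- x$gl[m$idx, , 1, drop = FALSE]
  l1 <- x$gl[m$idx, , 2, drop = FALSE]
  l2 <- x$gl[m$idx, , 3, drop = FALSE]
  dim(l0) <- dim(l1) <- dim(l2) <- c(length(m$idx), length(x$individuals))
  if (any(m$flip)) {
    tmp <- l0[m$flip, , drop = FALSE]
    l0[m$flip, ] <- l2[m$flip, , drop = FALSE]
    l2[m$flip, ] <- tmp
  }
  f <- site_table$freq_em
  ok <- f > 0 & f < 1
  if (!all(ok)) {
    warning(sum(!ok), " sites with boundary allele frequency excluded")
    l0 <- l0[ok, , drop = FALSE]; l1 <- l1[ok, , drop = FALSE]
    l2 <- l2[ok, , drop = FALSE]; f <- f[ok]
  }
  n_snp <- length(f)
  if (n_snp < 2L) stop("fewer than 2 usable SNPs")
  p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f); p2 <- f^2
  w0 <- l0 * p0; w1 <- l1 * p1; w2 <- l2 * p2
  dosage <- (w1 + 2 * w2) / (w0 + w1 + w2)
  dnorm_ <- (dosage - 2 * f) / sqrt(2 * f * (1 - f))
  cmat <- crossprod(dnorm_) / n_snp
  dimnames(cmat) <- list(x$individuals, x$individuals)
  eig <- eigen(cmat, symmetric = TRUE)
  pos <- eig$values > 0
  pct <- ifelse(pos, eig$values / sum(eig$values[pos]) * 100, 0)
  scores <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), nrow = length(eig$values))
  rownames(scores) <- x$individuals
  structure(
    list(cov = cmat, values = eig$values, vectors = eig$vectors,
         scores = scores, pct_var = pct, n_snps = n_snp),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d individuals, %d SNPs; PC1 %.2f%%, PC2 %.2f%%\n",
              nrow(x$cov), x$n_snps, x$pct_var[1],
              if (length(x$pct_var) > 1) x$pct_var[2] else NA))
  invisible(x)
}

# Vectorised unconstrained trinomial EM across sites for one group.
# l0/l1/l2: S x N likelihood matrices (group members only).
# Returns S x 3 matrix of genotype frequencies.
genotype_freq_matrix <- function(l0, l1, l2, tol = 1e-8, max_iter = 200L) {
  s <- nrow(l0)
  p <- matrix(1 / 3, s, 3)
  for (it in seq_len(max_iter)) {
    w0 <- l0 * p[, 1]; w1 <- l1 * p[, 2]; w2 <- l2 * p[, 3]
    den <- w0 + w1 + w2
    p_new <- cbind(rowMeans(w0 / den), rowMeans(w1 / den), rowMeans(w2 / den))
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  p
}

#' Genotype frequencies and observed heterozygosity for a group
#'
#' Unconstrained trinomial EM over the genotype-likelihood triplets of a
#' named group of individuals at one site. With hard-call triplets this
#' reduces to empirical genotype counting. `H_obs` is the estimated
#' heterozygote frequency.
#'
#' @param gl numeric matrix `N x 3` of likelihood triplets for the group.
#' @param tol,max_iter EM controls.
#' @return list with `p` (length-3 genotype frequencies) and `hobs`.
#' @export
group_genotype_freq <- function(gl, tol = 1e-8, max_iter = 200L) {
  gl <- as.matrix(gl)
  stopifnot(ncol(gl) == 3L, nrow(gl) >= 2L)
  gl <- gl / rowSums(gl)
  p <- genotype_freq_matrix(matrix(gl[, 1], 1), matrix(gl[, 2], 1),
                            matrix(gl[, 3], 1), tol, max_iter)
  list(p = as.numeric(p), hobs = p[1, 2])
}

#' Per-site observed heterozygosity for a group of individuals
#'
#' Vectorised trinomial EM over all requested sites.
#'
#' @param x a `gl_dataset`.
#' @param individuals index or ids of the group members (>= 2).
#' @param sites optional site index (default all).
#' @return numeric vector of `H_obs` per site.
#' @export
hobs_sites <- function(x, individuals, sites = NULL) {
  stopifnot(inherits(x, "gl_dataset"))
  if (is.character(individuals)) individuals <- match(individuals, x$individuals)
  stopifnot(length(individuals) >= 2L)
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  l0 <- x$gl[si, individuals, 1, drop = FALSE]
  l1 <- x$gl[si, individuals, 2, drop = FALSE]
  l2 <- x$gl[si, individuals, 3, drop = FALSE]
  dim(l0) <- dim(l1) <- dim(l2) <- c(length(si), length(individuals))
  p <- genotype_freq_matrix(l0, l1, l2)
  p[, 2]
}
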