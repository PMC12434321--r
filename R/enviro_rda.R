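# Genotype-environment association by redundancy analysis (RDA):
# hard genotype calls from GLs with per-individual depth gates, modal
# imputation, least-squares + SVD constrained ordination, permutation
# significance, and 3-SD loading outliers intersected with haploblocks.

#' Hard genotype calls from genotype likelihoods
#'
#' Per individual and SNP, the argmax-likelihood genotype is called only
#' when that individual's read depth at the site lies within
#' `[min_depth, max_depth]`; otherwise (and on likelihood ties) the entry
#' is missing.
#'
#' @param x a `gl_dataset` with a depth layer.
#' @param sites optional site index (default all).
#' @param min_depth,max_depth per-individual depth gates (defaults 2, 5).
#' @return integer matrix individuals x SNPs with entries 0/1/2/NA;
#'   columns named `chrom_pos`.
#' @export
hard_call <- function(x, sites = NULL, min_depth = 2L, max_depth = 5L) {
  stopifnot(inherits(x, "gl_dataset"))
  if (is.null(x$depth)) stop("depth layer required for hard calling")
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  s <- length(si); n <- length(x$individuals)
  l0 <- x$gl[si, , 1]; l1 <- x$gl[si, , 2]; l2 <- x$gl[si, , 3]
  dim(l0) <- dim(l1) <- dim(l2) <- c(s, n)
  g <- max.col(cbind(as.vector(l0), as.vector(l1), as.vector(l2)),
               ties.method = "first") - 1L
  # ties -> missing
  mx <- pmax(l0, l1, l2)
  n_at_max <- (abs(l0 - mx) < 1e-12) + (abs(l1 - mx) < 1e-12) +
    (abs(l2 - mx) < 1e-12)
  g <- matrix(g, s, n)
  g[n_at_max > 1L] <- NA_integer_
  d <- x$depth[si, , drop = FALSE]
  g[d < min_depth | d > max_depth] <- NA_integer_
  out <- t(g)
  rownames(out) <- x$individuals
  colnames(out) <- paste(x$sites$chrom[si], x$sites$pos[si], sep = "_")
  out
}

#' Filter and impute a hard-called genotype matrix
#'
#' Drops SNPs with a called fraction below `min_ind` or a called-genotype
#' minor-allele frequency below `min_maf`, then fills each remaining
#' missing entry with that SNP's modal genotype (ties: the lower genotype).
#'
#' @param G matrix from [hard_call()] (individuals x SNPs).
#' @param min_maf MAF floor on called genotypes (default 0.10).
#' @param min_ind minimum called fraction per SNP (default 0.90).
#' @return list with complete `G`, `kept` (column index),
#'   `missingness` (fraction NA among kept SNPs before imputation).
#' @export
filter_impute <- function(G, min_maf = 0.10, min_ind = 0.90) {
  called_frac <- colMeans(!is.na(G))
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- called_frac >= min_ind & !is.na(maf) & maf >= min_maf
  if (!any(keep)) stop("no SNP passes the filters")
  Gk <- G[, keep, drop = FALSE]
  missingness <- mean(is.na(Gk))
  for (j in seq_len(ncol(Gk))) {
    nas <- is.na(Gk[, j])
    if (any(nas)) {
      tab <- tabulate(Gk[!nas, j] + 1L, 3L)
      Gk[nas, j] <- which.max(tab) - 1L   # which.max takes the lower tie
    }
  }
  list(G = Gk, kept = which(keep), missingness = missingness)
}

#' Redundancy analysis of a genotype matrix on environmental predictors
#'
#' `Y` is the column-centred genotype matrix (optionally scaled), `X` the
#' standardised environment matrix; the fit is
#' `Y_hat = X (X'X)^{-1} X' Y`, decomposed by SVD into canonical axes
#' (singular values, SNP loadings = right vectors, sample scores = left
#' vectors times singular values). `R^2 = ||Y_hat||^2 / ||Y||^2` with the
#' Ezekiel adjustment `1 - (1 - R^2)(n - 1)/(n - p - 1)`. Environmental
#' predictors with pairwise |Pearson r| >= 0.70 are rejected.
#'
#' @param G complete genotype matrix (individuals x SNPs).
#' @param env data.frame/matrix of numeric predictors, rows matching `G`.
#' @param scale_genotypes also scale genotype columns to unit variance
#'   (default FALSE, the conventional genotype-RDA choice).
#' @return object of class `rda_fit`.
#' @export
rda_fit <- function(G, env, scale_genotypes = FALSE) {
  G <- as.matrix(G)
  env <- as.matrix(env)
  stopifnot(nrow(env) == nrow(G))
  storage.mode(env) <- "double"
  n <- nrow(G); p <- ncol(env)
  if (p >= n) stop("more predictors than observations")
  cm <- cor(env)
  high <- which(abs(cm) >= 0.70 & upper.tri(cm), arr.ind = TRUE)
  if (nrow(high))
    stop("collinear predictors (|r| >= 0.70): ",
         paste(colnames(env)[high[1, 1]], colnames(env)[high[1, 2]],
               sep = " ~ "))
  X <- scale(env)
  Y <- scale(G, center = TRUE, scale = scale_genotypes)
  Y[is.nan(Y)] <- 0    # monomorphic column under scaling
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12) stop("singular predictor cross-product")
  B <- solve(xtx, crossprod(X, Y))
  Yhat <- X %*% B
  sv <- svd(Yhat, nu = p, nv = p)
  d <- sv$d[seq_len(p)]
  r2 <- sum(Yhat^2) / sum(Y^2)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(
    list(Y = Y, X = X, B = B, Yhat = Yhat,
         d = d, loadings = sv$v, scores = sv$u %*% diag(d, p),
         axis_prop = d^2 / sum(d^2),
         r2 = r2, adj_r2 = adj_r2, n = n, p = p,
         snp_names = colnames(G)),
    class = "rda_fit"
  )
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("rda_fit: n = %d, %d SNPs, %d predictors; R2 = %.4f, adj R2 = %.4f\n",
              x$n, ncol(x$Y), x$p, x$r2, x$adj_r2))
  invisible(x)
}

#' Permutation significance of an RDA
#'
#' Overall pseudo-F is `(||Y_hat||^2 / p) / (||Y - Y_hat||^2 / (n - p - 1))`;
#' rows of `X` are permuted (equivalently, of `Y`), the statistic is
#' recomputed, and `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. Per-axis
#' p-values use each axis's squared singular value as a marginal
#' statistic under the same permutation scheme.
#'
#' @param fit an `rda_fit`.
#' @param n_perm number of permutations (default 999, minimum 99).
#' @param seed RNG seed.
#' @param axes also compute per-axis p-values (default TRUE; the axis SVDs
#'   dominate the cost).
#' @return list with `p_overall`, `f_obs`, `p_axis`.
#' @export
rda_significance <- function(fit, n_perm = 999L, seed = 1L, axes = TRUE) {
  stopifnot(inherits(fit, "rda_fit"), n_perm >= 99L)
  set.seed(seed)
  n <- fit$n; p <- fit$p
  X <- fit$X; Y <- fit$Y
  ss_tot <- sum(Y^2)
  hat <- X %*% solve(crossprod(X), t(X))
  f_stat <- function(Yp) {
    fitted_ss <- sum((hat %*% Yp)^2)
    (fitted_ss / p) / ((ss_tot - fitted_ss) / (n - p - 1))
  }
  ax_stat <- function(Yp) {
    sort(svd(hat %*% Yp, nu = 0, nv = 0)$d[seq_len(p)], decreasing = TRUE)^2
  }
  f_obs <- f_stat(Y)
  d2_obs <- fit$d^2
  cnt_f <- 0L
  cnt_ax <- integer(p)
  for (b in seq_len(n_perm)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    if (f_stat(Yp) >= f_obs) cnt_f <- cnt_f + 1L
    if (axes) cnt_ax <- cnt_ax + as.integer(ax_stat(Yp) >= d2_obs)
  }
  list(p_overall = (1 + cnt_f) / (1 + n_perm),
       f_obs = f_obs,
       p_axis = if (axes) (1 + cnt_ax) / (1 + n_perm) else NULL)
}

#' Loading outliers of an RDA, intersected with haploblocks
#'
#' Per constrained axis, SNPs whose loading is more than `k_sd` standard
#' deviations from that axis's mean loading are flagged; the outlier set
#' is the union over axes (a `pooled` switch uses all axes' loadings as
#' one pool). Each outlier is annotated with its most-correlated
#' environmental variable, and counts falling inside each supplied region
#' are reported.
#'
#' @param fit an `rda_fit` (SNP names `chrom_pos` enable block counts).
#' @param k_sd standard-deviation multiplier (default 3).
#' @param blocks optional region data.frame (`chrom`, `start`, `end`).
#' @param pooled pool loadings across axes instead of per-axis (default
#'   FALSE).
#' @return list with `outliers` data.frame (`snp`, `axis`, `loading`,
#'   `env_var`) and `block_counts`.
#' @export
rda_outliers <- function(fit, k_sd = 3, blocks = NULL, pooled = FALSE) {
  stopifnot(inherits(fit, "rda_fit"))
  L <- fit$loadings
  p <- fit$p
  flag <- matrix(FALSE, nrow(L), p)
  if (pooled) {
    mu <- mean(L[, seq_len(p)]); sg <- sd(as.vector(L[, seq_len(p)]))
    if (sg > 0) flag[, ] <- abs(L[, seq_len(p)] - mu) > k_sd * sg
  } else {
    for (k in seq_len(p)) {
      mu <- mean(L[, k]); sg <- sd(L[, k])
      if (sg > 0) flag[, k] <- abs(L[, k] - mu) > k_sd * sg
    }
  }
  hit <- which(rowSums(flag) > 0)
  snp <- if (!is.null(fit$snp_names)) fit$snp_names[hit] else as.character(hit)
  env_var <- character(length(hit))
  if (length(hit)) {
    cors <- abs(cor(fit$Y[, hit, drop = FALSE], fit$X))
    env_var <- colnames(fit$X)[max.col(cors, ties.method = "first")]
  }
  axis_of <- vapply(hit, function(i) which(flag[i, ])[1], integer(1))
  outliers <- data.frame(
    snp = snp, index = hit, axis = axis_of,
    loading = L[cbind(hit, axis_of)], env_var = env_var,
    stringsAsFactors = FALSE
  )
  block_counts <- NULL
  if (!is.null(blocks) && nrow(blocks) && length(hit)) {
    mm <- regmatches(snp, regexec("^(.*)_([0-9]+)$", snp))
    chrom <- vapply(mm, `[`, "", 2L)
    posn <- as.numeric(vapply(mm, `[`, "", 3L))
    block_counts <- blocks
    block_counts$n_outliers <- vapply(seq_len(nrow(blocks)), function(i) {
      sum(chrom == blocks$chrom[i] & posn > blocks$start[i] &
            posn <= blocks$end[i])
    }, numeric(1))
  } else if (!is.null(blocks) && nrow(blocks)) {
    block_counts <- blocks
    block_counts$n_outliers <- 0L
  }
  list(outliers = outliers, block_counts = block_counts)
}
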