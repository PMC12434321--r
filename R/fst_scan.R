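# Sample-allele-frequency (SAF) likelihoods, 2D-SFS EM, per-site Reynolds
# variance components and windowed FST.
#
# SAF: for a population of N diploids, the likelihood of j = 0..2N copies
# of the minor allele marginalised over genotype configurations with
# multivariate hypergeometric weights, via the dynamic programme
#   V_i[j] = sum_g V_{i-1}[j-g] L_i(g) C(2,g) C(2(i-1), j-g) / C(2i, j).

#' Site allele-frequency likelihood vectors
#'
#' @param x a `gl_dataset` restricted to one population (or `individuals`
#'   given).
#' @param individuals optional index/ids of the population members.
#' @param sites optional site index (default all).
#' @return matrix `n_sites x (2N + 1)`, rows normalised to sum 1.
#' @export
site_saf <- function(x, individuals = NULL, sites = NULL) {
  stopifnot(inherits(x, "gl_dataset"))
  ii <- if (is.null(individuals)) seq_along(x$individuals) else individuals
  if (is.character(ii)) ii <- match(ii, x$individuals)
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  n <- length(ii)
  s <- length(si)
  l <- lapply(1:3, function(g) {
    m <- x$gl[si, ii, g, drop = FALSE]
    dim(m) <- c(s, n)
    m
  })
  # DP across individuals, vectorised over sites
  v <- matrix(1, s, 1)
  cg <- c(1, 2, 1)   # C(2, g)
  for (i in seq_len(n)) {
    jmax_prev <- 2L * (i - 1L)
    jmax <- 2L * i
    vn <- matrix(0, s, jmax + 1L)
    for (g in 0:2) {
      lg <- l[[g + 1L]][, i]
      for (jp in 0:jmax_prev) {
        j <- jp + g
        w <- cg[g + 1L] * choose(jmax_prev, jp) / choose(jmax, j)
        vn[, j + 1L] <- vn[, j + 1L] + v[, jp + 1L] * lg * w
      }
    }
    rs <- rowSums(vn)
    rs[rs <= 0] <- 1
    v <- vn / rs
  }
  v
}

#' Joint 2D site-frequency spectrum by EM
#'
#' Estimates the distribution `Phi[j, k]` of joint sample allele counts
#' from two populations' SAF matrices over the same sites. E-step:
#' `gamma_s(j,k) proportional to Phi(j,k) saf1_s(j) saf2_s(k)`; M-step:
#' `Phi <- mean_s gamma_s`. Starts uniform; sites with zero likelihood
#' under every cell are dropped (count reported). Folding merges `(j, k)`
#' with its minor-allele mirror `(2N1 - j, 2N2 - k)` after the EM, leaving
#' orbit fixed points unhalved.
#'
#' @param saf1,saf2 SAF matrices from [site_saf()] over the same sites.
#' @param fold fold the spectrum (default FALSE).
#' @param tol max absolute change in `Phi` to stop (default 1e-9).
#' @param max_iter iteration cap (default 500).
#' @return object of class `sfs2d`: `phi`, `folded`, `n_sites`,
#'   `n_dropped`, `loglik`.
#' @export
sfs_em_2d <- function(saf1, saf2, fold = FALSE, tol = 1e-9, max_iter = 500L) {
  stopifnot(nrow(saf1) == nrow(saf2))
  d1 <- ncol(saf1); d2 <- ncol(saf2)
  bad <- rowSums(saf1) <= 0 | rowSums(saf2) <= 0 |
    !is.finite(rowSums(saf1)) | !is.finite(rowSums(saf2))
  n_dropped <- sum(bad)
  a <- saf1[!bad, , drop = FALSE]
  b <- saf2[!bad, , drop = FALSE]
  s <- nrow(a)
  if (s == 0L) stop("no usable sites")
  phi <- matrix(1 / (d1 * d2), d1, d2)
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    den <- rowSums((a %*% phi) * b)          # per-site normalising constant
    drop2 <- den <= 0
    if (any(drop2)) {
      a <- a[!drop2, , drop = FALSE]; b <- b[!drop2, , drop = FALSE]
      n_dropped <- n_dropped + sum(drop2)
      s <- nrow(a)
      den <- den[!drop2]
    }
    ll <- sum(log(den))
    phi_new <- phi * (crossprod(a / den, b)) / s
    phi_new <- phi_new / sum(phi_new)
    delta <- max(abs(phi_new - phi))
    phi <- phi_new
    if (delta < tol) break
  }
  if (fold) phi <- fold_sfs2d(phi)
  structure(list(phi = phi, folded = fold, n_sites = s,
                 n_dropped = n_dropped, loglik = ll),
            class = "sfs2d")
}

# fold onto minor-allele orbit representatives; fixed points unhalved
fold_sfs2d <- function(phi) {
  d1 <- nrow(phi); d2 <- ncol(phi)
  out <- matrix(0, d1, d2)
  for (j in seq_len(d1)) {
    for (k in seq_len(d2)) {
      jm <- d1 - j + 1L; km <- d2 - k + 1L
      rep_first <- (j < jm) || (j == jm && k <= km)
      if (rep_first) {
        out[j, k] <- phi[j, k] +
          if (j == jm && k == km) 0 else phi[jm, km]
      }
    }
  }
  out
}

# Reynolds-type moment variance components on sample allele counts.
# p_i = j_i / m_i with m_i = 2 N_i sampled alleles:
#   alpha = (p1 - p2)^2 - p1(1-p1)/(m1-1) - p2(1-p2)/(m2-1)
#   beta  = alpha + (m1 p1(1-p1)/(m1-1) + m2 p2(1-p2)/(m2-1)) / 2
# alpha is an unbiased moment estimate of the squared frequency
# difference; the within term makes beta the total, so alpha/beta <= 1
# with equality at a fixed difference.
reynolds_grid <- function(m1, m2) {
  j <- 0:m1; k <- 0:m2
  p1 <- j / m1; p2 <- k / m2
  v1 <- p1 * (1 - p1) / (m1 - 1)
  v2 <- p2 * (1 - p2) / (m2 - 1)
  alpha <- outer(p1, p2, function(x, y) (x - y)^2) -
    outer(v1, rep(1, m2 + 1L)) - outer(rep(1, m1 + 1L), v2)
  within <- (outer(v1 * m1, rep(1, m2 + 1L)) +
               outer(rep(1, m1 + 1L), v2 * m2)) / 2
  list(alpha = alpha, beta = alpha + within)
}

#' Per-site Reynolds variance components from SAF posteriors
#'
#' Posterior over joint counts `P(j, k | site) proportional to
#' Phi(j,k) saf1(j) saf2(k)`; `alpha` and `beta` are posterior
#' expectations of the Reynolds (1983)-type between-population and total
#' components evaluated at the sample counts. A folded spectrum is
#' expanded over mirror cells (the components are mirror-invariant).
#'
#' @param saf1,saf2 SAF matrices over the same sites.
#' @param sfs an `sfs2d` (or a bare `phi` matrix).
#' @return data.frame with `alpha`, `beta` per site (NA where the
#'   posterior is degenerate).
#' @export
site_fst_components <- function(saf1, saf2, sfs) {
  phi <- if (inherits(sfs, "sfs2d")) sfs$phi else sfs
  folded <- inherits(sfs, "sfs2d") && sfs$folded
  d1 <- ncol(saf1); d2 <- ncol(saf2)
  stopifnot(nrow(phi) == d1, ncol(phi) == d2)
  if (folded) {
    # spread folded mass equally over the two mirror cells
    full <- matrix(0, d1, d2)
    for (j in seq_len(d1)) for (k in seq_len(d2)) {
      if (phi[j, k] > 0) {
        jm <- d1 - j + 1L; km <- d2 - k + 1L
        if (j == jm && k == km) full[j, k] <- full[j, k] + phi[j, k]
        else {
          full[j, k] <- full[j, k] + phi[j, k] / 2
          full[jm, km] <- full[jm, km] + phi[j, k] / 2
        }
      }
    }
    phi <- full
  }
  gr <- reynolds_grid(d1 - 1L, d2 - 1L)
  # posterior expectations, vectorised over sites
  denom <- rowSums((saf1 %*% phi) * saf2)
  ea <- rowSums((saf1 %*% (phi * gr$alpha)) * saf2) / denom
  eb <- rowSums((saf1 %*% (phi * gr$beta)) * saf2) / denom
  bad <- !is.finite(ea) | !is.finite(eb)
  ea[bad] <- NA_real_; eb[bad] <- NA_real_
  data.frame(alpha = ea, beta = eb)
}

#' Windowed FST (ratio of sums)
#'
#' @param pos site positions (1-based bp).
#' @param components data.frame with `alpha`, `beta` per site.
#' @param window,slide window size and slide in bp (default 10 kb each;
#'   windows are anchored at position 0, half-open, last partial window
#'   kept).
#' @param min_sites windows with fewer sites are flagged (default 5).
#' @param chrom chromosome id for the output.
#' @return data.frame `chrom`, `start`, `end`, `n_sites`, `sum_alpha`,
#'   `sum_beta`, `fst`, `flagged`.
#' @export
windowed_fst <- function(pos, components, window = 10000, slide = 10000,
                         min_sites = 5L, chrom = "chr") {
  if (window <= 0 || slide <= 0) stop("window and slide must be positive")
  stopifnot(length(pos) == nrow(components))
  keep <- !is.na(components$alpha) & !is.na(components$beta)
  pos_k <- pos[keep]
  al <- components$alpha[keep]; be <- components$beta[keep]
  max_pos <- max(pos)
  starts <- seq(0, max(0, max_pos - 1), by = slide)
  out <- lapply(starts, function(s) {
    inw <- pos_k > s & pos_k <= s + window
    n <- sum(inw)
    sa <- sum(al[inw]); sb <- sum(be[inw])
    data.frame(chrom = chrom, start = s, end = s + window, n_sites = n,
               sum_alpha = sa, sum_beta = sb,
               fst = if (n > 0 && sb != 0) sa / sb else NA_real_,
               flagged = n < min_sites)
  })
  do.call(rbind, out)
}

#' FST scan between two groups of a dataset
#'
#' Wrapper: SAF per group at the given sites, (optionally folded) 2D-SFS
#' EM, per-site components and windowed FST.
#'
#' @param x a `gl_dataset` (one chromosome).
#' @param group1,group2 individual indices or ids.
#' @param sites optional site index (default all).
#' @param fold fold the 2D SFS (default TRUE, minor-allele orientation).
#' @param window,slide,min_sites see [windowed_fst()].
#' @return list with `sfs`, `components`, `windows`, and the genome-wide
#'   ratio-of-sums `fst_global`.
#' @export
fst_scan <- function(x, group1, group2, sites = NULL, fold = TRUE,
                     window = 10000, slide = 10000, min_sites = 5L) {
  stopifnot(inherits(x, "gl_dataset"))
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  saf1 <- site_saf(x, group1, si)
  saf2 <- site_saf(x, group2, si)
  sfs <- sfs_em_2d(saf1, saf2, fold = fold)
  comp <- site_fst_components(saf1, saf2, sfs)
  win <- windowed_fst(x$sites$pos[si], comp, window = window,
                      slide = slide, min_sites = min_sites,
                      chrom = x$sites$chrom[si][1])
  ok <- !is.na(comp$alpha)
  list(sfs = sfs, components = comp, windows = win,
       fst_global = sum(comp$alpha[ok]) / sum(comp$beta[ok]))
}
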