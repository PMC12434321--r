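# Linkage disequilibrium from genotype likelihoods: pairwise r2 by
# two-locus haplotype EM, LD decay, graph pruning, windowed heatmap
# statistics and haploblock (candidate inversion) detection.

#' Two-locus r2 by haplotype-frequency EM
#'
#' Estimates the four haplotype frequencies at a pair of sites from
#' unphased genotype likelihoods, assuming random union of gametes, and
#' derives D, D' and r2. Either site monomorphic under the estimate gives
#' r2 = 0 with a flag.
#'
#' @param gl1,gl2 numeric matrices `N x 3` of likelihood triplets at the
#'   two sites (same individual order).
#' @param max_iter,tol EM controls (defaults 500, 1e-8).
#' @param track_loglik return the per-iteration log-likelihood trace.
#' @return list with `h` (hAB, hAb, haB, hab), `D`, `Dprime`, `r2`, `f1`,
#'   `f2`, `monomorphic` flag and optionally `trace`.
#' @export
pair_r2 <- function(gl1, gl2, max_iter = 500L, tol = 1e-8,
                    track_loglik = FALSE) {
  gl1 <- as.matrix(gl1); gl2 <- as.matrix(gl2)
  stopifnot(ncol(gl1) == 3L, ncol(gl2) == 3L, nrow(gl1) == nrow(gl2),
            nrow(gl1) >= 2L)
  gl1 <- gl1 / rowSums(gl1); gl2 <- gl2 / rowSums(gl2)
  res <- .pair_ld_single(gl1, gl2, max_iter, tol, track_loglik)
  res$monomorphic <- min(res$f1, 1 - res$f1, res$f2, 1 - res$f2) < 1e-6
  res
}

#' Pairwise r2 for many site pairs of a dataset
#'
#' @param x a `gl_dataset`.
#' @param pairs two-column integer matrix of site indices.
#' @param max_iter,tol EM controls per pair.
#' @return data.frame with site indices, positions, distance and the EM
#'   `r2`, `D`, `Dprime` per pair.
#' @export
pair_r2_batch <- function(x, pairs, max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(x, "gl_dataset"))
  pairs <- as.matrix(pairs)
  l0 <- x$gl[, , 1]; l1 <- x$gl[, , 2]; l2 <- x$gl[, , 3]
  dim(l0) <- dim(l1) <- dim(l2) <- c(nrow(x$sites), length(x$individuals))
  res <- .pair_ld_batch(l0, l1, l2, pairs[, 1], pairs[, 2], max_iter, tol)
  data.frame(
    a = pairs[, 1], b = pairs[, 2],
    pos_a = x$sites$pos[pairs[, 1]], pos_b = x$sites$pos[pairs[, 2]],
    dist = abs(x$sites$pos[pairs[, 2]] - x$sites$pos[pairs[, 1]]),
    r2 = res[, "r2"], D = res[, "D"], Dprime = res[, "Dprime"]
  )
}

# all within-chromosome pairs up to max_dist (0 = no cap) for given sites
site_pairs <- function(pos, max_dist = 0) {
  n <- length(pos)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    if (max_dist > 0) {
      jmax <- i + findInterval(pos[i] + max_dist, pos[(i + 1L):n])
      if (jmax <= i) next
      out[[i]] <- cbind(i, (i + 1L):jmax)
    } else {
      out[[i]] <- cbind(i, (i + 1L):n)
    }
  }
  do.call(rbind, out)
}

#' LD decay curve and half-decay distance
#'
#' Bins pair r2 by distance and fits `r2(d) = r0 exp(-d / tau) + c` by
#' nonlinear least squares. The half-decay distance is where the fitted
#' curve falls halfway to its asymptote (`tau * log(2)`).
#'
#' @param pairs data.frame with `dist` and `r2` (e.g. from
#'   [pair_r2_batch()]).
#' @param max_dist pairs beyond this distance are dropped (default 100 kb).
#' @param bin_width distance bin width in bp (default 1 kb).
#' @return list with the binned `decay` table, `tau`, `r0`, `c`,
#'   `half_decay`, and a `degenerate` flag when the fit is unidentifiable.
#' @export
ld_decay <- function(pairs, max_dist = 1e5, bin_width = 1000) {
  d <- pairs$dist
  keep <- d <= max_dist & d > 0
  d <- d[keep]; r2 <- pairs$r2[keep]
  bin <- floor(d / bin_width)
  tab <- aggregate(r2, list(bin = bin), mean)
  names(tab) <- c("bin", "r2")
  tab$dist <- (tab$bin + 0.5) * bin_width
  if (nrow(tab) < 3L) stop("fewer than 3 non-empty distance bins")
  if (sd(tab$r2) < 1e-6) {
    return(list(decay = tab, tau = NA_real_, r0 = NA_real_,
                c = mean(tab$r2), half_decay = NA_real_, degenerate = TRUE))
  }
  start <- list(r0 = max(tab$r2) - min(tab$r2),
                tau = max_dist / 10,
                cc = min(tab$r2))
  fit <- try(minpack.lm::nlsLM(
    r2 ~ r0 * exp(-dist / tau) + cc, data = tab, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(decay = tab, tau = NA_real_, r0 = NA_real_,
                c = NA_real_, half_decay = NA_real_, degenerate = TRUE))
  }
  cf <- coef(fit)
  if (!is.finite(cf["tau"]) || cf["tau"] <= 0 || cf["r0"] <= 0) {
    return(list(decay = tab, tau = NA_real_, r0 = NA_real_,
                c = unname(cf["cc"]), half_decay = NA_real_,
                degenerate = TRUE))
  }
  list(decay = tab, tau = unname(cf["tau"]), r0 = unname(cf["r0"]),
       c = unname(cf["cc"]), half_decay = unname(cf["tau"]) * log(2),
       degenerate = FALSE)
}

#' Greedy graph-based LD pruning
#'
#' Builds a graph with edges between sites whose r2 is at least
#' `min_weight` (within `max_dist`), then repeatedly deletes the node with
#' the largest sum of incident edge weights (ties: the lowest genomic
#' position is deleted) until no edges remain.
#'
#' @param pos site positions (defines the node set and tie order).
#' @param pairs data.frame with `a`, `b` (site indices into `pos`) and
#'   `r2`; `dist` used when present.
#' @param min_weight edge threshold (default 0.4).
#' @param max_dist edge distance cap in bp (default 15 kb; 0 = none).
#' @return integer vector of surviving site indices, in original order.
#' @export
prune_linked <- function(pos, pairs, min_weight = 0.4, max_dist = 15000) {
  keep_edge <- pairs$r2 >= min_weight
  if (!is.null(pairs$dist) && max_dist > 0)
    keep_edge <- keep_edge & pairs$dist <= max_dist
  ed <- pairs[keep_edge, c("a", "b", "r2"), drop = FALSE]
  alive <- rep(TRUE, length(pos))
  if (nrow(ed)) {
    repeat {
      wd <- numeric(length(pos))
      live <- alive[ed$a] & alive[ed$b]
      if (!any(live)) break
      ea <- ed$a[live]; eb <- ed$b[live]; ew <- ed$r2[live]
      for (k in seq_along(ew)) {
        wd[ea[k]] <- wd[ea[k]] + ew[k]
        wd[eb[k]] <- wd[eb[k]] + ew[k]
      }
      mx <- max(wd)
      cand <- which(wd >= mx - 1e-12)
      victim <- cand[which.min(pos[cand])]
      alive[victim] <- FALSE
    }
  }
  which(alive)
}

#' Window-pair LD matrix (heatmap statistic)
#'
#' For every pair of windows, the statistic is a configurable quantile of
#' the r2 values over SNP pairs with one SNP in each window. The default
#' `q = 0.98` is the high quantile that makes haploblocks stand out on a
#' heatmap.
#'
#' @param pairs data.frame with `pos_a`, `pos_b`, `r2` (one chromosome).
#' @param window window size in bp (default 250 kb).
#' @param q quantile in (0, 1) (default 0.98).
#' @param chrom chromosome id stored with the result.
#' @param subsample optional fraction of SNPs to retain (seeded).
#' @param seed RNG seed for subsampling.
#' @return object of class `window_pair_matrix`: symmetric `stat` matrix
#'   with `NA` for empty cells, plus window metadata.
#' @export
window_pair_matrix <- function(pairs, window = 250000, q = 0.98,
                               chrom = "chr", subsample = NULL, seed = 1L) {
  if (window <= 0) stop("window size must be positive")
  if (!is.null(subsample)) {
    stopifnot(subsample > 0, subsample <= 1)
    set.seed(seed)
    snps <- sort(unique(c(pairs$pos_a, pairs$pos_b)))
    keep_snp <- sort(sample(snps, ceiling(length(snps) * subsample)))
    pairs <- pairs[pairs$pos_a %in% keep_snp & pairs$pos_b %in% keep_snp, ,
                   drop = FALSE]
  }
  wa <- floor((pairs$pos_a - 1) / window)
  wb <- floor((pairs$pos_b - 1) / window)
  lo <- pmin(wa, wb); hi <- pmax(wa, wb)
  n_win <- max(hi) + 1L
  dt <- data.table::data.table(lo = lo, hi = hi, r2 = pairs$r2)
  agg <- dt[, list(stat = as.numeric(quantile(r2, q)), n = .N),
            by = c("lo", "hi")]
  m <- matrix(NA_real_, n_win, n_win)
  m[cbind(agg$lo + 1L, agg$hi + 1L)] <- agg$stat
  m[cbind(agg$hi + 1L, agg$lo + 1L)] <- agg$stat
  structure(
    list(stat = m, window = window, q = q, chrom = chrom, n_win = n_win),
    class = "window_pair_matrix"
  )
}

#' Detect haploblocks from a window-pair LD matrix
#'
#' Binarises cells at `r2_min` and grows maximal diagonal squares: from
#' each start window the end is extended while the fraction of ON cells
#' (among non-missing pairs with window separation >= 2 inside the square)
#' stays at least `density` and at least half the cells are non-missing.
#' Maximal non-nested intervals spanning at least `min_span` are reported,
#' merging intervals that overlap by a window or more.
#'
#' @param wpm a `window_pair_matrix`.
#' @param r2_min cell threshold (default 0.6, the level at which inversion
#'   haploblocks stand out).
#' @param density minimum ON fraction (default 0.6, tolerant of missing
#'   cells).
#' @param min_span minimum block span in bp (default 1 Mb; study-scale
#'   usage is 10 Mb).
#' @return data.frame of regions: `chrom`, `start`, `end` (0-based
#'   half-open bp), `n_windows`, `mean_stat`, `median_stat`, `status`.
#' @export
detect_haploblocks <- function(wpm, r2_min = 0.6, density = 0.6,
                               min_span = 1e6) {
  stopifnot(inherits(wpm, "window_pair_matrix"))
  m <- wpm$stat
  w <- wpm$n_win
  on <- m >= r2_min
  # grow squares incrementally: extending [s, e] to [s, e+1] adds the
  # separation >= 2 cells (i, e+1) for i in s..e-1. A single sparse or
  # noisy window must not stop the growth while the square is still
  # small, so failing extensions are carried provisionally for up to
  # `patience` windows and committed only if the square density
  # recovers; otherwise the scan reverts to the last good end.
  patience <- 5L
  ends <- integer(w)
  for (s in seq_len(w)) {
    e <- s
    tot <- 0L; obs <- 0L; onc <- 0L
    pend <- 0L
    ptot <- 0L; pobs <- 0L; pon <- 0L
    while (e + pend < w) {
      ep <- e + pend + 1L
      if (ep - s >= 2L) {
        new_cells <- on[s:(ep - 2L), ep]
        ptot <- ptot + length(new_cells)
        pobs <- pobs + sum(!is.na(new_cells))
        pon <- pon + sum(new_cells, na.rm = TRUE)
      }
      ntot <- tot + ptot; nobs <- obs + pobs; non <- onc + pon
      ok <- if (ntot == 0L) TRUE
      else nobs >= 0.5 * ntot && nobs > 0L && non / nobs >= density
      if (ok) {
        e <- ep; tot <- ntot; obs <- nobs; onc <- non
        pend <- 0L; ptot <- 0L; pobs <- 0L; pon <- 0L
      } else {
        pend <- pend + 1L
        if (pend >= patience) break
      }
    }
    # trim edge windows whose own (marginal) cell density falls below
    # the threshold: the square criterion alone lets a dense core drag
    # low-LD windows along
    marg_ok <- function(w_edge, s0, e0) {
      others <- setdiff(s0:e0, (w_edge - 1L):(w_edge + 1L))
      if (!length(others)) return(TRUE)
      cells <- on[w_edge, others]
      if (all(is.na(cells))) return(TRUE)
      mean(cells, na.rm = TRUE) >= density
    }
    s0 <- s
    while (e > s0 && !marg_ok(e, s0, e)) e <- e - 1L
    while (s0 < e && !marg_ok(s0, s0, e)) s0 <- s0 + 1L
    if (s0 > s) { ends[s] <- s; next }   # start itself trimmed: no block here
    ends[s] <- e
  }
  min_windows <- ceiling(min_span / wpm$window)
  cand <- data.frame(s = seq_len(w), e = ends)
  cand <- cand[cand$e - cand$s + 1L >= min_windows, , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      mean_stat = numeric(0), median_stat = numeric(0),
                      status = character(0)))
  }
  # drop nested intervals
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    nested <- cand$s <= cand$s[i] & cand$e >= cand$e[i] &
      (cand$s < cand$s[i] | cand$e > cand$e[i])
    if (any(nested)) keep[i] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  # merge intervals overlapping by >= 1 window
  cand <- cand[order(cand$s), , drop = FALSE]
  merged <- list()
  cur <- cand[1, ]
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      if (cand$s[i] <= cur$e) {
        cur$e <- max(cur$e, cand$e[i])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- cand[i, ]
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  stats_in <- function(s, e) {
    i <- s:e
    sub <- m[i, i, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    c(mean(vals, na.rm = TRUE), median(vals, na.rm = TRUE))
  }
  st <- t(mapply(stats_in, out$s, out$e))
  data.frame(
    chrom = wpm$chrom,
    start = (out$s - 1L) * wpm$window,
    end = out$e * wpm$window,
    n_windows = out$e - out$s + 1L,
    mean_stat = st[, 1], median_stat = st[, 2],
    status = "detected", stringsAsFactors = FALSE
  )
}

#' Whole-chromosome LD scan
#'
#' Convenience wrapper: restricts a dataset to called SNPs, optionally
#' subsamples them, computes all pairwise r2 (no distance cap), builds the
#' window-pair matrix and calls haploblocks.
#'
#' @param x a `gl_dataset` (one chromosome).
#' @param site_table called SNPs from [call_snps()].
#' @param window,q,r2_min,density,min_span see [window_pair_matrix()] and
#'   [detect_haploblocks()].
#' @param subsample fraction of SNPs to sample (default 0.5), seeded.
#' @param seed RNG seed.
#' @return list with `pairs`, `matrix`, `blocks`.
#' @export
ld_scan <- function(x, site_table, window = 250000, q = 0.98,
                    r2_min = 0.6, density = 0.6, min_span = 1e6,
                    subsample = 0.5, seed = 1L) {
  stopifnot(inherits(x, "gl_dataset"))
  chrom <- unique(site_table$chromo)
  if (length(chrom) != 1L) stop("ld_scan expects a single chromosome")
  idx <- match_sites(x, site_table)$idx
  if (!is.null(subsample) && subsample < 1) {
    set.seed(seed)
    idx <- sort(sample(idx, ceiling(length(idx) * subsample)))
  }
  sub <- gl_subset(x, sites = idx)
  pr <- site_pairs(sub$sites$pos, max_dist = 0)
  # a 1e-6 tolerance is ample for a quantile-of-r2 heatmap and about
  # halves the scan time on whole-chromosome pair sets
  pairs <- pair_r2_batch(sub, pr, max_iter = 200L, tol = 1e-6)
  wpm <- window_pair_matrix(pairs, window = window, q = q, chrom = chrom)
  blocks <- detect_haploblocks(wpm, r2_min = r2_min, density = density,
                               min_span = min_span)
  list(pairs = pairs, matrix = wpm, blocks = blocks)
}
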