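# Independent oracles: brute-force or closed-form reimplementations kept
# deliberately separate from the package's computation paths.

# SAF by exhaustive enumeration over all 3^N genotype configurations,
# grouped by total minor count with multivariate hypergeometric weights
saf_enum_oracle <- function(gl) {
  n <- nrow(gl)
  v <- rep(0, 2 * n + 1)
  grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    j <- sum(g)
    lik <- prod(gl[cbind(seq_len(n), g + 1L)])
    w <- prod(choose(2, g)) / choose(2 * n, j)
    v[j + 1L] <- v[j + 1L] + lik * w
  }
  v / sum(v)
}

# Reynolds-type components from true genotype sample counts (the same
# moment formulas, evaluated on observed counts rather than SAF
# posteriors)
reynolds_from_counts <- function(j1, m1, j2, m2) {
  p1 <- j1 / m1; p2 <- j2 / m2
  a <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
  w <- (m1 * p1 * (1 - p1) / (m1 - 1) + m2 * p2 * (1 - p2) / (m2 - 1)) / 2
  list(alpha = a, beta = a + w)
}

# MAF log-likelihood maximised by grid search
maf_grid_oracle <- function(gl, step = 0.001) {
  fs <- seq(0, 1, by = step)
  ll <- vapply(fs, function(f) {
    p <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    sum(log(gl %*% p))
  }, numeric(1))
  fs[which.max(ll)]
}

# trinomial genotype-frequency likelihood maximised on a simplex grid
genofreq_grid_oracle <- function(gl, step = 0.01) {
  best <- -Inf; arg <- c(1, 0, 0)
  for (p0 in seq(0, 1, by = step)) {
    for (p1 in seq(0, 1 - p0, by = step)) {
      p <- c(p0, p1, 1 - p0 - p1)
      ll <- sum(log(gl %*% p))
      if (ll > best) { best <- ll; arg <- p }
    }
  }
  arg
}

# step-by-step simulation of the greedy pruning rule
prune_oracle <- function(pos, edges) {
  alive <- rep(TRUE, length(pos))
  edges <- as.data.frame(edges)
  repeat {
    live <- alive[edges$a] & alive[edges$b]
    if (!any(live)) break
    wd <- numeric(length(pos))
    for (r in which(live)) {
      wd[edges$a[r]] <- wd[edges$a[r]] + edges$r2[r]
      wd[edges$b[r]] <- wd[edges$b[r]] + edges$r2[r]
    }
    cand <- which(wd >= max(wd) - 1e-12)
    victim <- cand[which.min(pos[cand])]
    alive[victim] <- FALSE
  }
  which(alive)
}

# ---- median-joining oracle: quasi-median closure plus cost-minimal ----
# subnetwork enumeration (binary sequences, small instances only)

ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

dist_mat_str <- function(sq) {
  n <- length(sq)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) d[i, j] <- ham(sq[i], sq[j])
  d
}

mst_cost_oracle <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  cost <- 0
  for (s in seq_len(n - 1)) {
    v <- which(!intree)[which.min(best[!intree])]
    cost <- cost + best[v]
    intree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  cost
}

median3 <- function(a, b, c_) {
  am <- strsplit(a, "")[[1]]; bm <- strsplit(b, "")[[1]]; cm <- strsplit(c_, "")[[1]]
  out <- vapply(seq_along(am), function(i) {
    x <- c(am[i], bm[i], cm[i])
    tb <- table(x)
    names(tb)[which.max(tb)]
  }, "")
  paste(out, collapse = "")
}

quasi_median_closure <- function(seqs, cap = 64L) {
  all_s <- unique(seqs)
  repeat {
    added <- FALSE
    n <- length(all_s)
    if (n >= cap) break
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (i < j && j < k) {
        m <- median3(all_s[i], all_s[j], all_s[k])
        if (!m %in% all_s) { all_s <- c(all_s, m); added <- TRUE }
      }
    }
    if (!added) break
  }
  all_s
}

# minimal spanning cost over observed + any median subset of size <= k_max;
# among minimal-cost solutions prefer fewest medians, then lexicographic
mj_oracle <- function(seqs, k_max = length(seqs) - 2L) {
  closure <- quasi_median_closure(seqs)
  medians <- setdiff(closure, seqs)
  best <- list(cost = mst_cost_oracle(dist_mat_str(seqs)), set = character(0))
  if (length(medians)) {
    for (k in seq_len(min(k_max, length(medians)))) {
      sel <- utils::combn(sort(medians), k, simplify = FALSE)
      for (ss in sel) {
        cost <- mst_cost_oracle(dist_mat_str(c(seqs, ss)))
        if (cost < best$cost - 1e-9) best <- list(cost = cost, set = ss)
      }
    }
  }
  best
}
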