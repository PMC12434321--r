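# Karyotyping a haploblock: within-block PCA, three-cluster assignment on
# PC1, per-group heterozygosity profiles, arrangement orientation (the
# low-H_obs homokaryotype is taken as the inverted, i.e. derived,
# arrangement) and breakpoint refinement from the het-minus-inverted-hom
# H_obs contrast.

#' Within-block covariance PCA
#'
#' @param x a `gl_dataset`.
#' @param site_table called SNPs.
#' @param region one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open bp).
#' @param min_snps minimum SNPs required (default 50).
#' @return a `pca_result` on the block SNPs.
#' @export
block_pca <- function(x, site_table, region, min_snps = 50L) {
  in_block <- site_table$chromo == region$chrom &
    site_table$position > region$start &
    site_table$position <= region$end
  if (sum(in_block) < min_snps) stop("block too small for karyotyping")
  covariance_pca(x, site_table[in_block, , drop = FALSE])
}

# mean silhouette for a 1-d clustering
silhouette_1d <- function(x, cluster) {
  n <- length(x)
  ks <- sort(unique(cluster))
  if (length(ks) < 2L) return(0)
  d <- abs(outer(x, x, "-"))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    a <- if (sum(own) > 1L) sum(d[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(ks[ks != cluster[i]], function(k) {
      mean(d[i, cluster == k])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# exact 1-d k-means: dynamic programme minimising within-cluster sums of
# squares over contiguous segments of the sorted scores (deterministic,
# no initialisation; clusters in 1-d are intervals, so this is optimal)
kmeans_1d_exact <- function(x, k = 3L) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  seg_cost <- function(i, j) {   # 1-based inclusive
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  cost <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in 1:n) cost[1L, j] <- seg_cost(1L, j)
  if (k > 1L) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf; bi <- m
        for (i in m:j) {
          v <- cost[m - 1L, i - 1L] + seg_cost(i, j)
          if (v < best) { best <- v; bi <- i }
        }
        cost[m, j] <- best
        cut[m, j] <- bi
      }
    }
  }
  bounds <- integer(k + 1L)
  bounds[k + 1L] <- n
  j <- n
  for (m in k:2) {
    bounds[m] <- cut[m, j] - 1L
    j <- bounds[m]
  }
  bounds[1] <- 0L
  grp_sorted <- rep(seq_len(k), diff(bounds))
  grp <- integer(n)
  grp[ord] <- grp_sorted
  centers <- vapply(seq_len(k), function(m) mean(x[grp == m]), numeric(1))
  list(cluster = grp, centers = centers)
}

#' Three-cluster karyotype assignment from PC1 scores
#'
#' Exact (dynamic-programming) k-means with k = 3 on PC1 -- deterministic
#' and globally optimal, which matters when karyotype frequencies are
#' skewed and one homokaryotype cluster is small. Clusters are ordered by
#' centre; the middle cluster is the heterokaryotype. The solution is
#' accepted only when the mean silhouette reaches `silhouette_min`;
#' otherwise every individual is `unassigned` and the structure flag is
#' off. Homokaryotype labels (`INV/INV` vs `STD/STD`) are provisional
#' until [orient_and_refine()] fixes the orientation from heterozygosity.
#'
#' @param pc1 numeric PC1 scores (names taken as individual ids).
#' @param silhouette_min acceptance gate (default 0.75).
#' @return list with `assignments` (data.frame: individual, pc1, cluster,
#'   label, silhouette), `structure` flag, `silhouette`, `centers`.
#' @export
cluster_karyotypes <- function(pc1, silhouette_min = 0.75) {
  stopifnot(length(pc1) >= 6L)
  ids <- if (is.null(names(pc1))) sprintf("ind_%03d", seq_along(pc1)) else names(pc1)
  km <- kmeans_1d_exact(as.numeric(pc1), 3L)
  pos_of <- match(km$cluster, order(km$centers))  # 1 left, 2 middle, 3 right
  sil <- silhouette_1d(as.numeric(pc1), pos_of)
  if (length(unique(pos_of)) < 3L || sil < silhouette_min) {
    return(list(
      assignments = data.frame(individual = ids, pc1 = as.numeric(pc1),
                               cluster = "unassigned", label = "unassigned",
                               silhouette = NA_real_, stringsAsFactors = FALSE),
      structure = FALSE, silhouette = sil, centers = sort(km$centers)
    ))
  }
  cluster <- c("left", "middle", "right")[pos_of]
  label <- c("INV/INV", "STD/INV", "STD/STD")[pos_of]  # provisional sides
  list(
    assignments = data.frame(individual = ids, pc1 = as.numeric(pc1),
                             cluster = cluster, label = label,
                             silhouette = sil, stringsAsFactors = FALSE),
    structure = TRUE, silhouette = sil,
    centers = sort(km$centers)
  )
}

#' Windowed observed-heterozygosity profiles per karyotype group
#'
#' Per group, per-SNP H_obs comes from the trinomial genotype-frequency EM
#' and is averaged within non-overlapping windows tiling the chromosome;
#' the block-wide mean over SNPs inside `region` is also reported. Groups
#' smaller than two are omitted with a warning.
#'
#' @param x a `gl_dataset` (one chromosome).
#' @param groups named list of individual indices or ids.
#' @param region one-row region data.frame (`start`, `end` bp) used for
#'   the block-wide means.
#' @param window window and slide in bp (default 10 kb).
#' @return list per group: `profile` data.frame (`win_start`, `win_end`,
#'   `n_snps`, `hobs`) and `block_mean`.
#' @export
hobs_profiles <- function(x, groups, region, window = 10000) {
  stopifnot(inherits(x, "gl_dataset"))
  pos <- x$sites$pos
  win <- floor((pos - 1) / window)
  in_block <- pos > region$start & pos <= region$end
  out <- list()
  for (g in names(groups)) {
    memb <- groups[[g]]
    if (is.character(memb)) memb <- match(memb, x$individuals)
    if (length(memb) < 2L) {
      warning("group ", g, " has fewer than 2 members; profile omitted")
      next
    }
    h <- hobs_sites(x, memb)
    prof <- aggregate(h, list(win = win), mean)
    cnt <- as.integer(table(win)[as.character(prof$win)])
    out[[g]] <- list(
      profile = data.frame(win_start = prof$win * window,
                           win_end = (prof$win + 1) * window,
                           n_snps = cnt, hobs = prof$x),
      block_mean = mean(h[in_block]),
      hobs_by_site = h
    )
  }
  out
}

#' Orient the arrangement and refine breakpoints from H_obs
#'
#' The homokaryotype group with the lower block-wide mean H_obs is taken
#' as the inverted (derived) homokaryotype -- an assumption, recorded in
#' the output metadata. When the difference does not exceed `margin` the
#' orientation is `ambiguous` and no refinement is attempted. Breakpoints
#' are refined as the maximal run of windows, seeded at the LD block, in
#' which the heterokaryotype-minus-inverted-homokaryotype H_obs contrast
#' exceeds `margin`; the contrast series is smoothed with a centred
#' rolling mean over `smooth_k` data windows to keep single noisy windows
#' from splitting the run.
#'
#' @param block one-row region data.frame from [detect_haploblocks()].
#' @param profiles output of [hobs_profiles()] with groups named `left`,
#'   `middle`, `right` (clusters from [cluster_karyotypes()]).
#' @param margin minimum H_obs difference (default 0.02).
#' @param smooth_k rolling-mean width in data windows (default 5).
#' @return list with `region` (block plus `refined_start`, `refined_end`,
#'   `status`, `inv_cluster`), `group_means`, `orientation` (map from
#'   cluster to karyotype label) and `assumption` note.
#' @export
orient_and_refine <- function(block, profiles, margin = 0.02, smooth_k = 5L) {
  need <- c("left", "middle", "right")
  if (!all(need %in% names(profiles)))
    stop("profiles for left, middle and right groups are required")
  means <- vapply(profiles[need], `[[`, numeric(1), "block_mean")
  hom <- means[c("left", "right")]
  region <- block
  region$hobs_left <- means["left"]
  region$hobs_middle <- means["middle"]
  region$hobs_right <- means["right"]
  if (abs(hom[1] - hom[2]) <= margin) {
    region$status <- "ambiguous"
    region$inv_cluster <- NA_character_
    region$refined_start <- NA_real_
    region$refined_end <- NA_real_
    return(list(region = region, group_means = means,
                orientation = NULL,
                assumption = "inverted = lower-H_obs homokaryotype"))
  }
  inv_cluster <- names(hom)[which.min(hom)]
  std_cluster <- setdiff(c("left", "right"), inv_cluster)
  orientation <- setNames(c("INV/INV", "STD/INV", "STD/STD"),
                          c(inv_cluster, "middle", std_cluster))

  het <- profiles$middle$profile
  inv <- profiles[[inv_cluster]]$profile
  key <- intersect(het$win_start, inv$win_start)
  het_h <- het$hobs[match(key, het$win_start)]
  inv_h <- inv$hobs[match(key, inv$win_start)]
  ord <- order(key)
  key <- key[ord]
  contrast <- roll_mean((het_h - inv_h)[ord], smooth_k)
  pass <- contrast > margin
  # close isolated dips: a failing stretch of <= 2 data windows flanked
  # by passing ones does not split a run
  r0 <- rle(pass)
  if (length(r0$lengths) > 2L) {
    for (i in 2:(length(r0$lengths) - 1L)) {
      if (!r0$values[i] && r0$lengths[i] <= 2L &&
            r0$values[i - 1L] && r0$values[i + 1L])
        r0$values[i] <- TRUE
    }
    pass <- inverse.rle(r0)
  }
  # maximal run of passing data windows overlapping the LD block
  r <- rle(pass)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- data.frame(s = starts_i[r$values], e = ends_i[r$values])
  if (!nrow(runs)) {
    region$status <- "unrefined"
    region$inv_cluster <- inv_cluster
    region$refined_start <- NA_real_
    region$refined_end <- NA_real_
    return(list(region = region, group_means = means,
                orientation = orientation,
                assumption = "inverted = lower-H_obs homokaryotype"))
  }
  win_size <- if (length(key) > 1) min(diff(key)) else 10000
  overlap <- vapply(seq_len(nrow(runs)), function(i) {
    a <- c(key[runs$s[i]], key[runs$e[i]] + win_size)
    max(0, min(a[2], block$end) - max(a[1], block$start))
  }, numeric(1))
  best <- which.max(overlap)
  if (overlap[best] <= 0) {
    region$status <- "unrefined"
    region$inv_cluster <- inv_cluster
    region$refined_start <- NA_real_
    region$refined_end <- NA_real_
  } else {
    region$status <- "refined"
    region$inv_cluster <- inv_cluster
    region$refined_start <- key[runs$s[best]]
    region$refined_end <- key[runs$e[best]] + win_size
  }
  list(region = region, group_means = means, orientation = orientation,
       assumption = "inverted = lower-H_obs homokaryotype")
}

#' Full karyotyping of one haploblock
#'
#' Wrapper: within-block PCA, PC1 clustering, H_obs profiles per cluster,
#' orientation and breakpoint refinement, and final karyotype labels.
#'
#' @param x a `gl_dataset` (one chromosome).
#' @param site_table called SNPs.
#' @param block one-row region data.frame.
#' @param window H_obs window size (default 10 kb).
#' @param margin orientation margin (default 0.02).
#' @param silhouette_min cluster acceptance gate (default 0.75).
#' @return list with `assignments` (final labels), `region`, `pca`,
#'   `clusters`, `profiles`, `orientation`.
#' @export
karyotype_block <- function(x, site_table, block, window = 10000,
                            margin = 0.02, silhouette_min = 0.75) {
  pca <- block_pca(x, site_table, block)
  pc1 <- setNames(pca$scores[, 1], x$individuals)
  cl <- cluster_karyotypes(pc1, silhouette_min = silhouette_min)
  if (!cl$structure) {
    return(list(assignments = cl$assignments, region = block, pca = pca,
                clusters = cl, profiles = NULL, orientation = NULL))
  }
  groups <- split(seq_along(x$individuals), cl$assignments$cluster)
  # H_obs profiles over called SNPs only: monomorphic sites carry no
  # heterozygosity contrast and would dilute the windowed signal
  on_chrom <- site_table$chromo == block$chrom
  snp_idx <- match_sites(x, site_table[on_chrom, , drop = FALSE])$idx
  xs <- gl_subset(x, sites = snp_idx)
  profiles <- hobs_profiles(xs, groups, block, window = window)
  if (!all(c("left", "middle", "right") %in% names(profiles))) {
    cl$assignments$label <- "unassigned"
    return(list(assignments = cl$assignments, region = block, pca = pca,
                clusters = cl, profiles = profiles, orientation = NULL))
  }
  orf <- orient_and_refine(block, profiles, margin = margin)
  asg <- cl$assignments
  if (!is.null(orf$orientation)) {
    asg$label <- unname(orf$orientation[asg$cluster])
  }
  list(assignments = asg, region = orf$region, pca = pca, clusters = cl,
       profiles = profiles, orientation = orf$orientation)
}
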