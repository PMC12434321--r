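# The genotype-likelihood dataset: the pipeline's universal substrate.
# Likelihood triplets are stored normalised to sum 1 per (site, individual);
# every downstream quantity is a likelihood ratio, so the constant is
# irrelevant.

#' Construct a genotype-likelihood dataset
#'
#' Bundles per-site, per-individual genotype-likelihood triplets (ordered
#' major/major, major/minor, minor/minor) with site metadata and an optional
#' read-depth layer.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based),
#'   `major`, `minor` (single bases in A, C, G, T). Positions must be
#'   strictly increasing within each chromosome.
#' @param individuals character vector of individual ids.
#' @param gl numeric array `n_sites x n_ind x 3` of likelihoods; triplets
#'   are normalised to sum 1. All-zero triplets are invalid.
#' @param depth optional integer matrix `n_sites x n_ind` of read counts.
#' @return object of class `gl_dataset`.
#' @export
gl_dataset <- function(sites, individuals, gl, depth = NULL) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "major", "minor") %in% names(sites)))
  n_sites <- nrow(sites)
  n_ind <- length(individuals)
  stopifnot(is.array(gl), length(dim(gl)) == 3L,
            dim(gl)[1] == n_sites, dim(gl)[2] == n_ind, dim(gl)[3] == 3L)
  ok_allele <- function(a) all(a %in% c("A", "C", "G", "T"))
  if (!ok_allele(sites$major) || !ok_allele(sites$minor))
    stop("alleles must be one of A, C, G, T")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (any(gl < 0)) stop("negative genotype likelihoods")
  tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  if (any(tot <= 0)) stop("all-zero genotype-likelihood triplet")
  for (g in 1:3) gl[, , g] <- gl[, , g] / tot
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(nrow(depth) == n_sites, ncol(depth) == n_ind)
  }
  structure(
    list(sites = sites, individuals = as.character(individuals),
         gl = gl, depth = depth),
    class = "gl_dataset"
  )
}

#' @export
print.gl_dataset <- function(x, ...) {
  cat("gl_dataset:", nrow(x$sites), "sites x", length(x$individuals),
      "individuals;", if (is.null(x$depth)) "no" else "with", "depth layer\n")
  invisible(x)
}

#' @export
dim.gl_dataset <- function(x) c(nrow(x$sites), length(x$individuals))

#' Subset a gl_dataset by sites and/or individuals
#'
#' @param x a `gl_dataset`.
#' @param sites integer/logical index into site rows.
#' @param individuals integer/logical/character index into individuals.
#' @return a `gl_dataset`.
#' @export
gl_subset <- function(x, sites = NULL, individuals = NULL) {
  stopifnot(inherits(x, "gl_dataset"))
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  if (is.character(individuals)) individuals <- match(individuals, x$individuals)
  ii <- if (is.null(individuals)) seq_along(x$individuals) else individuals
  gl_dataset(
    sites = x$sites[si, , drop = FALSE],
    individuals = x$individuals[ii],
    gl = x$gl[si, ii, , drop = FALSE],
    depth = if (is.null(x$depth)) NULL else x$depth[si, ii, drop = FALSE]
  )
}

# sites of a site table matched against dataset rows (by chrom + pos);
# returns list(idx, flip): flip marks table rows whose major/minor are
# swapped relative to the dataset orientation.
match_sites <- function(x, site_table) {
  key_ds <- paste(x$sites$chrom, x$sites$pos)
  key_st <- paste(site_table$chromo, site_table$position)
  idx <- match(key_st, key_ds)
  if (anyNA(idx)) stop("site table contains sites absent from the dataset")
  flip <- site_table$major != x$sites$major[idx]
  bad <- flip & (site_table$major != x$sites$minor[idx] |
                   site_table$minor != x$sites$major[idx])
  if (any(bad)) stop("allele mismatch between site table and dataset")
  list(idx = idx, flip = flip)
}
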