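# Small shared helpers.

#' Rolling mean with partial windows at the edges
#'
#' @param x numeric vector.
#' @param k odd window width (centred); values at the ends use the
#'   available neighbours only.
#' @return numeric vector of the same length as `x`; `NA`s are ignored
#'   within each window (all-`NA` windows give `NA`).
#' @keywords internal
roll_mean <- function(x, k = 5L) {
  n <- length(x)
  if (n == 0L || k <= 1L) return(x)
  half <- k %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    w <- x[lo:hi]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

#' Jaccard overlap of two genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`.
#'
#' @param a,b numeric length-2 vectors `c(start, end)`.
#' @return intersection length divided by union length.
#' @export
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  un <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Fraction of a genome covered by a set of regions
#'
#' Sums region sizes (no overlap handling: published block tables list
#' disjoint regions on distinct chromosomes) and expresses the total as a
#' percentage of the genome size.
#'
#' @param sizes region sizes in base pairs (or any unit shared with
#'   `genome_size`).
#' @param genome_size total genome size in the same unit.
#' @return percentage in `[0, 100]`.
#' @export
genome_fraction_pct <- function(sizes, genome_size) {
  stopifnot(genome_size > 0, all(sizes >= 0))
  100 * sum(sizes) / genome_size
}

#' Pairwise Hamming distances between equal-length strings
#'
#' @param seqs character vector of equal-length sequences.
#' @return integer distance matrix with dimnames from `names(seqs)`.
#' @keywords internal
hamming_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      h <- sum(m[i, ] != m[j, ])
      d[i, j] <- d[j, i] <- h
    }
  }
  d
}

# deterministic derived seeds; keep well below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
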