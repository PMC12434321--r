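# Readers/writers for the text formats the pipeline touches.
# Conventions: site tables are 1-based (the .mafs ecosystem convention),
# BED intervals are 0-based half-open; conversion between the two is
# centralised here. Gzip is handled transparently by extension sniffing
# (reads decompress through a gzfile connection; writes use gzfile()).

write_lines_maybe_gz <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
}

# fread with gzip handled via a connection (no extra dependency)
fread_maybe_gz <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

allele_code <- c(A = "A", C = "C", G = "G", T = "T",
                 `0` = "A", `1` = "C", `2` = "G", `3` = "T")

#' Read a BEAGLE genotype-likelihood file
#'
#' Expects the header `marker allele1 allele2` followed by three columns
#' per individual (likelihoods for major/major, major/minor, minor/minor).
#' Markers are `chrom_pos`; alleles may be letters or the 0-3 numeric
#' encoding. Triplets are normalised on load.
#'
#' @param path file path (optionally gzipped).
#' @param depth optional path of a matching depth table written by
#'   [write_depth()].
#' @return a [gl_dataset()].
#' @export
read_beagle <- function(path, depth = NULL) {
  dt <- fread_maybe_gz(path, header = TRUE, sep = "\t",
                          colClasses = "character", fill = FALSE)
  if (ncol(dt) < 6L || (ncol(dt) - 3L) %% 3L != 0L)
    stop("malformed BEAGLE file: expected 3 + 3k columns, got ", ncol(dt))
  n_ind <- (ncol(dt) - 3L) %/% 3L
  ind_ids <- unique(sub("(\\.\\d+)?$", "", names(dt)[-(1:3)]))
  if (length(ind_ids) != n_ind) ind_ids <- paste0("Ind", seq_len(n_ind) - 1L)
  marker <- dt[[1]]
  mm <- regmatches(marker, regexec("^(.*)_([0-9]+)$", marker))
  bad <- which(vapply(mm, length, 1L) != 3L)
  if (length(bad))
    stop("malformed marker at line ", bad[1] + 1L, ": ", marker[bad[1]])
  chrom <- vapply(mm, `[`, "", 2L)
  pos <- as.integer(vapply(mm, `[`, "", 3L))
  a1 <- allele_code[dt[[2]]]
  a2 <- allele_code[dt[[3]]]
  if (anyNA(a1) || anyNA(a2)) {
    bad <- which(is.na(a1) | is.na(a2))[1]
    stop("unrecognised allele at line ", bad + 1L)
  }
  num <- suppressWarnings(
    matrix(as.numeric(as.matrix(dt[, -(1:3)])), nrow = nrow(dt))
  )
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop("non-numeric likelihood at line ", bad + 1L)
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      bad <- which(chrom == ch)[which(diff(p) <= 0)[1] + 1L]
      stop("non-monotone position at line ", bad + 1L)
    }
  }
  gl <- array(0, dim = c(nrow(dt), n_ind, 3L))
  for (g in 1:3) gl[, , g] <- num[, seq(g, by = 3L, length.out = n_ind)]
  d <- NULL
  if (!is.null(depth)) {
    dd <- fread_maybe_gz(depth, header = TRUE, sep = "\t")
    if (nrow(dd) != nrow(dt)) stop("depth table does not match BEAGLE sites")
    d <- as.matrix(dd[, -1])
  }
  gl_dataset(
    sites = data.frame(chrom = chrom, pos = pos, major = unname(a1),
                       minor = unname(a2), stringsAsFactors = FALSE),
    individuals = ind_ids, gl = gl, depth = d
  )
}

#' Write a gl_dataset as a BEAGLE genotype-likelihood file
#'
#' @param x a `gl_dataset`.
#' @param path output path (gzipped if it ends in `.gz`).
#' @export
write_beagle <- function(x, path) {
  stopifnot(inherits(x, "gl_dataset"))
  header <- c("marker", "allele1", "allele2",
              rep(x$individuals, each = 3L))
  n_ind <- length(x$individuals)
  cols <- lapply(seq_len(n_ind), function(i) {
    sapply(1:3, function(g) sprintf("%.8g", x$gl[, i, g]))
  })
  body <- cbind(paste(x$sites$chrom, x$sites$pos, sep = "_"),
                x$sites$major, x$sites$minor,
                matrix(unlist(cols), nrow = nrow(x$sites)))
  lines <- c(paste(header, collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  write_lines_maybe_gz(lines, path)
  invisible(path)
}

#' Write the per-site, per-individual read-depth layer
#' @param x a `gl_dataset` with a depth layer.
#' @param path output path.
#' @export
write_depth <- function(x, path) {
  stopifnot(inherits(x, "gl_dataset"), !is.null(x$depth))
  dt <- data.table::data.table(
    marker = paste(x$sites$chrom, x$sites$pos, sep = "_")
  )
  for (i in seq_along(x$individuals)) dt[[x$individuals[i]]] <- x$depth[, i]
  lines <- c(paste(names(dt), collapse = "\t"),
             do.call(paste, c(as.list(dt), sep = "\t")))
  write_lines_maybe_gz(lines, path)
  invisible(path)
}

#' Read a SNP site table
#'
#' TSV with columns `chromo`, `position` (1-based), `major`, `minor`,
#' `freq_em`, `pvalue`, `n_ind` (an `lrt` column is carried through when
#' present). Minor-allele frequencies outside `[0, 0.5]` are rejected.
#'
#' @param path file path (optionally gzipped).
#' @return data.frame site table.
#' @export
read_site_table <- function(path) {
  dt <- as.data.frame(fread_maybe_gz(path, header = TRUE, sep = "\t"))
  need <- c("chromo", "position", "major", "minor", "freq_em", "pvalue", "n_ind")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("site table missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$freq_em < 0 | dt$freq_em > 0.5))
    stop("freq_em outside [0, 0.5]: table is not minor-allele oriented")
  dt
}

#' Write a SNP site table
#' @param site_table data.frame from [call_snps()] or [read_site_table()].
#' @param path output path (gzipped if it ends in `.gz`).
#' @export
write_site_table <- function(site_table, path) {
  if (any(site_table$freq_em < 0 | site_table$freq_em > 0.5))
    stop("freq_em outside [0, 0.5]")
  cols <- intersect(c("chromo", "position", "major", "minor", "freq_em",
                      "lrt", "pvalue", "n_ind"), names(site_table))
  df <- site_table[, cols, drop = FALSE]
  lines <- c(paste(cols, collapse = "\t"),
             do.call(paste, c(lapply(df, function(col) {
               if (is.numeric(col) && !is.integer(col)) sprintf("%.8g", col)
               else as.character(col)
             }), sep = "\t")))
  write_lines_maybe_gz(lines, path)
  invisible(path)
}

#' Read a BED file of regions
#'
#' 3-5 column BED (chrom, start, end, name, score), 0-based half-open.
#' Overlapping records are preserved as-is.
#'
#' @param path file path (optionally gzipped).
#' @return data.frame with `chrom`, `start`, `end`, and optional `label`,
#'   `score`.
#' @export
read_bed <- function(path) {
  dt <- as.data.frame(fread_maybe_gz(path, header = FALSE, sep = "\t"))
  if (ncol(dt) < 3L || ncol(dt) > 5L)
    stop("BED must have 3-5 columns, got ", ncol(dt))
  names(dt) <- c("chrom", "start", "end", "label", "score")[seq_len(ncol(dt))]
  if (any(dt$start >= dt$end)) {
    bad <- which(dt$start >= dt$end)[1]
    stop("start >= end at record ", bad)
  }
  dt
}

#' Write regions as BED (sorted by chrom, start)
#' @param regions data.frame with `chrom`, `start`, `end` and optional
#'   `label`, `score`.
#' @param path output path (gzipped if it ends in `.gz`).
#' @export
write_bed <- function(regions, path) {
  if (any(regions$start >= regions$end)) stop("start >= end")
  ord <- order(regions$chrom, regions$start)
  df <- regions[ord, intersect(c("chrom", "start", "end", "label", "score"),
                               names(regions)), drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  lines <- do.call(paste, c(as.list(df), sep = "\t"))
  write_lines_maybe_gz(lines, path)
  invisible(path)
}

#' Read an aligned FASTA file
#' @param path FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- ape::read.FASTA(path)
  toupper(vapply(as.character(x), paste, "", collapse = ""))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}
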