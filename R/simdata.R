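# Forward simulator for an inversion polymorphism in low-coverage data.
#
# Haplotype model: founder mosaics (Li-Stephens-like copying) rather than a
# full coalescent. Standard (STD) chromosome copies are recombinant mosaics
# of a small founder pool; inverted (INV) copies descend from a single
# founder inside the inversion interval (plus a few private mutations) and
# recombine freely outside it. Hard recombination suppression between
# arrangements inside the interval is what produces the haploblock, the
# three-cluster PCA geometry and the H_obs ordering the pipeline detects.

#' Simulation configuration
#'
#' Defaults emulate the study system scale: nine demes of ~21 individuals
#' sequenced at ~3x, a multi-megabase inversion segregating in a western
#' subset of demes, an LD decay scale of ~15 kb on the standard background,
#' and a star-like mitochondrial radiation of 1-7 mutational steps.
#'
#' @param n_demes number of demes.
#' @param n_per_deme individuals per deme.
#' @param chrom_length chromosome length in bp.
#' @param n_sites number of candidate biallelic sites.
#' @param inversion_interval numeric `c(start, end)`, 0-based half-open bp.
#' @param inversion_freq_per_deme arrangement frequency per deme (recycled
#'   or length `n_demes`).
#' @param n_std_founders founder haplotypes behind the standard arrangement.
#' @param n_inv_founder_mutations private (arrangement-diagnostic)
#'   mutations on the inverted founder: new alleles absent from the
#'   standard pool. The default `NULL` scales with the interval (one per
#'   ~50 kb), emulating the divergence a megabase-scale inversion
#'   accumulates.
#' @param recomb_rate expected crossovers (mosaic switch points) per
#'   chromosome copy. Pairwise r2 requires both haplotypes of a pair of
#'   sites to sit on one founder segment, so r2 decays with scale
#'   (segment length)/2; the default segment length of ~30 kb therefore
#'   targets the ~15 kb r2 decay scale.
#' @param mean_depth Poisson mean reads per site per individual.
#' @param seq_error per-read error probability, in (0, 0.5).
#' @param env_effect length-3 association strengths of temperature, pH and
#'   streamflow with deme inversion frequency.
#' @param mito_length mitogenome length in bp.
#' @param n_mito_haplotypes number of mitochondrial haplotypes.
#' @param mito_step_range `c(min, max)` mutational steps from the central
#'   haplotype.
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_demes = 9L,
                       n_per_deme = 21L,
                       chrom_length = 40e6,
                       n_sites = 4000L,
                       inversion_interval = c(14e6, 32e6),
                       inversion_freq_per_deme = c(0.35, 0.3, 0.25, rep(0, 6)),
                       n_std_founders = 8L,
                       n_inv_founder_mutations = NULL,
                       recomb_rate = chrom_length / 30000,
                       mean_depth = 3,
                       seq_error = 0.01,
                       env_effect = c(temperature = 6, pH = -1.2, streamflow = -0.6),
                       mito_length = 16624L,
                       n_mito_haplotypes = 30L,
                       mito_step_range = c(1L, 7L),
                       seed = 42L) {
  freq <- rep_len(inversion_freq_per_deme, n_demes)
  stopifnot(
    n_demes >= 1, n_per_deme >= 1, chrom_length > 0, n_sites >= 2,
    inversion_interval[1] >= 0, inversion_interval[2] > inversion_interval[1],
    inversion_interval[2] <= chrom_length,
    all(freq >= 0 & freq <= 1),
    n_std_founders >= 2,
    is.null(n_inv_founder_mutations) || n_inv_founder_mutations >= 0,
    recomb_rate >= 0, mean_depth > 0,
    seq_error > 0, seq_error < 0.5,
    mito_length >= 1, n_mito_haplotypes >= 2,
    mito_step_range[1] >= 1, mito_step_range[2] >= mito_step_range[1]
  )
  structure(
    list(n_demes = as.integer(n_demes), n_per_deme = as.integer(n_per_deme),
         chrom_length = chrom_length, n_sites = as.integer(n_sites),
         inversion_interval = inversion_interval,
         inversion_freq_per_deme = freq,
         n_std_founders = as.integer(n_std_founders),
         n_inv_founder_mutations =
           if (is.null(n_inv_founder_mutations)) NULL
           else as.integer(n_inv_founder_mutations),
         recomb_rate = recomb_rate, mean_depth = mean_depth,
         seq_error = seq_error, env_effect = env_effect,
         mito_length = as.integer(mito_length),
         n_mito_haplotypes = as.integer(n_mito_haplotypes),
         mito_step_range = as.integer(mito_step_range),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# one mosaic haplotype: founder index per site
mosaic_haplotype <- function(pos, founders, chrom_length, recomb_rate) {
  n_f <- nrow(founders)
  k <- rpois(1L, recomb_rate)
  if (k == 0L) return(founders[sample.int(n_f, 1L), ])
  breaks <- sort(runif(k, 0, chrom_length))
  seg <- findInterval(pos - 1, breaks) + 1L   # segment index per site
  src <- sample.int(n_f, k + 1L, replace = TRUE)
  founders[cbind(src[seg], seq_along(pos))]
}

#' Simulate a low-coverage cohort with a planted inversion polymorphism
#'
#' @param config a [sim_config()].
#' @return list with `gl` (a [gl_dataset()] with depth layer) and `truth`
#'   (class `sim_truth`): true minor-allele genotypes, per-copy arrangement
#'   labels, karyotypes, deme assignment, realised deme inversion
#'   frequencies, and the planted interval.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ind <- config$n_demes * config$n_per_deme
  deme <- rep(seq_len(config$n_demes), each = config$n_per_deme)
  ids <- sprintf("ind_%03d", seq_len(n_ind))

  pos <- sort(sample.int(config$chrom_length, config$n_sites))  # 1-based
  inside <- pos > config$inversion_interval[1] &
    pos <= config$inversion_interval[2]
  if (any(config$inversion_freq_per_deme > 0) && !any(inside))
    stop("inversion interval contains no sites")

  # founder pool: per-site frequency then Bernoulli draws per founder
  p_site <- runif(config$n_sites, 0.1, 0.9)
  founders <- matrix(
    rbinom(config$n_std_founders * config$n_sites, 1L,
           rep(p_site, each = config$n_std_founders)),
    nrow = config$n_std_founders
  )
  # inverted arrangement: one founder plus private mutations, frozen
  # inside the interval. Private mutations are new alleles absent from
  # the standard founder pool, so they are arrangement-diagnostic
  # (r2 ~ 1 among them on arrangement-pure haplotypes).
  inv_core <- founders[1L, ]
  n_mut <- config$n_inv_founder_mutations
  if (is.null(n_mut))
    n_mut <- max(1L, round(diff(config$inversion_interval) / 5e4))
  if (n_mut > 0L && any(inside)) {
    mut <- sample(which(inside), min(n_mut, sum(inside)))
    founders[, mut] <- 0L
    inv_core <- founders[1L, ]
    inv_core[mut] <- 1L
  }

  arr <- matrix("STD", n_ind, 2L)
  hap <- array(0L, dim = c(2L, config$n_sites, n_ind))
  for (i in seq_len(n_ind)) {
    pf <- config$inversion_freq_per_deme[deme[i]]
    for (cpy in 1:2) {
      h <- mosaic_haplotype(pos, founders, config$chrom_length,
                            config$recomb_rate)
      if (runif(1) < pf) {
        arr[i, cpy] <- "INV"
        h[inside] <- inv_core[inside]   # no recombination with STD inside
      }
      hap[cpy, , i] <- h
    }
  }
  g_alt <- hap[1, , ] + hap[2, , ]     # sites x individuals, alt copies

  # orient to the sample minor allele
  alt_freq <- rowMeans(g_alt) / 2
  minor_is_alt <- alt_freq <= 0.5
  g_minor <- ifelse(minor_is_alt, 1, -1) * g_alt +
    ifelse(minor_is_alt, 0, 2)
  g_minor <- matrix(g_minor, nrow = config$n_sites)

  base_pairs <- t(replicate(config$n_sites, sample(c("A", "C", "G", "T"), 2L)))
  major <- ifelse(minor_is_alt, base_pairs[, 1], base_pairs[, 2])
  minor <- ifelse(minor_is_alt, base_pairs[, 2], base_pairs[, 1])

  depth <- matrix(rpois(config$n_sites * n_ind, config$mean_depth),
                  config$n_sites, n_ind)
  p_minor_read <- config$seq_error + (g_minor / 2) * (1 - 2 * config$seq_error)
  n_minor <- matrix(rbinom(length(depth), depth, p_minor_read),
                    config$n_sites, n_ind)
  n_major <- depth - n_minor
  glm <- gl_from_counts(as.vector(n_major), as.vector(n_minor),
                        config$seq_error)
  gl <- array(glm, dim = c(config$n_sites, n_ind, 3L))

  karyo <- apply(arr, 1, function(a) {
    n_inv <- sum(a == "INV")
    c("STD/STD", "STD/INV", "INV/INV")[n_inv + 1L]
  })
  realised <- tapply(rowSums(arr == "INV") / 2, deme, mean)

  truth <- structure(
    list(true_genotypes = g_minor,
         arrangement_labels = arr,
         karyotype = karyo,
         deme = deme,
         individuals = ids,
         positions = pos,
         inversion_interval = config$inversion_interval,
         inside_interval = inside,
         deme_inv_freq = as.numeric(realised),
         minor_is_alt = minor_is_alt,
         config = config),
    class = "sim_truth"
  )
  ds <- gl_dataset(
    sites = data.frame(chrom = "chr_sim", pos = pos, major = major,
                       minor = minor, stringsAsFactors = FALSE),
    individuals = ids, gl = gl, depth = depth
  )
  list(gl = ds, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$individuals), "individuals,",
      length(x$positions), "sites; karyotypes:",
      paste(names(table(x$karyotype)), table(x$karyotype), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate deme-level environmental covariates
#'
#' Each covariate is `base + effect * deme_inversion_frequency + noise`.
#' Generated variables are screened for collinearity (pairwise Pearson
#' |r| < 0.70, the usual constrained-ordination screen); noise is redrawn
#' up to 100 times to satisfy it.
#'
#' @param config a [sim_config()].
#' @param truth the matching `sim_truth` (realised deme frequencies drive
#'   the association).
#' @return data.frame with one row per deme: `deme`, `inv_freq`,
#'   `temperature`, `pH`, `streamflow`.
#' @export
simulate_env <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(derive_seed(config$seed, 1L))
  freq <- truth$deme_inv_freq
  k <- config$n_demes
  base <- c(temperature = 14, pH = 7.5, streamflow = 0.5)
  noise_sd <- c(temperature = 1.0, pH = 0.3, streamflow = 0.15)
  eff <- rep_len(config$env_effect, 3L)
  for (attempt in seq_len(100L)) {
    env <- sapply(1:3, function(v) base[v] + eff[v] * freq + rnorm(k, 0, noise_sd[v]))
    colnames(env) <- names(base)
    if (k < 3L) break
    cors <- cor(env)
    if (max(abs(cors[upper.tri(cors)])) < 0.70) break
    if (attempt == 100L)
      stop("could not satisfy the collinearity bound in 100 attempts")
  }
  data.frame(deme = seq_len(k), inv_freq = freq, env,
             check.names = FALSE)
}

#' Broadcast deme-level environmental values to individuals
#' @param env_table from [simulate_env()].
#' @param truth the matching `sim_truth`.
#' @return data.frame with one row per individual.
#' @export
env_by_individual <- function(env_table, truth) {
  i <- match(truth$deme, env_table$deme)
  data.frame(individual = truth$individuals,
             population = truth$deme,
             env_table[i, c("temperature", "pH", "streamflow")],
             row.names = NULL, check.names = FALSE)
}

#' Simulate a star-like mitochondrial haplotype radiation
#'
#' One central haplotype; every other haplotype differs from it by a
#' uniform number of substitutions at globally distinct positions, so all
#' pairwise distances are bounded by twice the maximum step count.
#' Haplotype frequencies decay with rank; individuals carrying the
#' inversion are spread so that at least two haplotypes contain both
#' carriers and non-carriers (when both exist).
#'
#' @param config a [sim_config()].
#' @param truth the matching `sim_truth`.
#' @return list with `sequences` (per-individual aligned mitogenomes),
#'   `hap_sequences` (per-haplotype), `assignment` (individual ->
#'   haplotype id), `steps` (per-haplotype distance from the centre), and
#'   `central` (id of the central haplotype).
#' @export
simulate_mito <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(derive_seed(config$seed, 2L))
  k <- config$n_mito_haplotypes
  n_ind <- length(truth$individuals)
  steps <- c(0L, sample(seq(config$mito_step_range[1],
                            config$mito_step_range[2]),
                        k - 1L, replace = TRUE))
  if (config$mito_length < sum(steps))
    stop("mito_length too short for the requested mutational steps")
  bases <- c("A", "C", "G", "T")
  central <- sample(bases, config$mito_length, replace = TRUE)
  mut_pos <- sample.int(config$mito_length, sum(steps))
  haps <- matrix(rep(central, k), nrow = k, byrow = TRUE)
  off <- 0L
  for (h in seq_len(k)[-1]) {
    if (steps[h] == 0L) next
    ps <- mut_pos[(off + 1L):(off + steps[h])]
    off <- off + steps[h]
    for (p in ps) haps[h, p] <- sample(setdiff(bases, central[p]), 1L)
  }
  hap_seq <- apply(haps, 1, paste, collapse = "")

  # rank-decaying frequencies
  w <- 1 / seq_len(k)
  assignment <- sample(seq_len(k), n_ind, replace = TRUE, prob = w)
  assignment[sample.int(n_ind, min(k, n_ind))] <- seq_len(min(k, n_ind))

  carriers <- which(truth$karyotype != "STD/STD")
  non_carriers <- setdiff(seq_len(n_ind), carriers)
  if (length(carriers) >= 2L && length(non_carriers) >= 2L && k >= 3L) {
    # carriers sit in a few non-central haplotypes that they share with
    # non-carriers: recently derived arrangements are spread over leaf
    # haplotypes of the radiation, not confined to a clade of their own
    pool <- 2:min(6L, k)
    assignment[carriers] <- sample(pool, length(carriers), replace = TRUE)
    # ensure >= 2 distinct carrier haplotypes, each shared
    if (length(unique(assignment[carriers])) < 2L)
      assignment[carriers[1L]] <- setdiff(pool, assignment[carriers])[1L]
    free_nc <- non_carriers
    for (h in unique(assignment[carriers])) {
      if (!any(assignment[non_carriers] == h) && length(free_nc)) {
        assignment[free_nc[1L]] <- h
        free_nc <- free_nc[-1L]
      }
    }
  }
  names(hap_seq) <- sprintf("hap_%02d", seq_len(k))
  seqs <- hap_seq[assignment]
  names(seqs) <- truth$individuals
  list(sequences = seqs, hap_sequences = hap_seq,
       assignment = setNames(names(hap_seq)[assignment], truth$individuals),
       steps = setNames(steps, names(hap_seq)),
       central = names(hap_seq)[1L])
}

#' Write all simulator outputs to a directory
#'
#' Emits the BEAGLE GL file, the depth table, the truth BED for the
#' inversion interval, the karyotype truth table, the deme environment
#' table and the mitochondrial alignment.
#'
#' @param sim list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param env optional table from [simulate_env()].
#' @param mito optional list from [simulate_mito()].
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, env = NULL, mito = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beagle(sim$gl, file.path(dir, "sim.beagle.gz"))
  write_depth(sim$gl, file.path(dir, "sim.depth.gz"))
  tr <- sim$truth
  write_bed(data.frame(chrom = "chr_sim",
                       start = tr$inversion_interval[1],
                       end = tr$inversion_interval[2],
                       label = "inversion_truth"),
            file.path(dir, "truth_inversion.bed"))
  writeLines(
    c("individual\tdeme\tkaryotype",
      paste(tr$individuals, tr$deme, tr$karyotype, sep = "\t")),
    file.path(dir, "truth_karyotype.tsv")
  )
  if (!is.null(env))
    utils::write.table(env, file.path(dir, "env.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(mito))
    write_fasta(mito$sequences, file.path(dir, "mito.fasta"))
  invisible(dir)
}
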