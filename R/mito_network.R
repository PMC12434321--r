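# Mitochondrial haplotypes: collapse aligned mitogenomes, median-joining
# network (epsilon = 0), neighbour-joining tree with bootstrap, and a
# carrier-distribution summary (are inversion carriers confined to a
# clade of the network?).

#' Collapse aligned sequences into haplotypes
#'
#' Columns containing any gap or ambiguity character are excluded
#' alignment-wide before comparison, so distances between haplotypes are
#' plain Hamming counts on the retained columns. Haplotype ids are ranked
#' by descending frequency (ties: first occurrence).
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (one per individual).
#' @return object of class `haplotype_set`: `seq` (haplotype sequences on
#'   retained columns), `freq`, `members` (list of individual ids),
#'   `retained_columns`.
#' @export
collapse_haplotypes <- function(seqs) {
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  ok_col <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, ok_col, drop = FALSE]
  key <- apply(m, 1, paste, collapse = "")
  first <- !duplicated(key)
  uniq <- key[first]
  freq <- as.integer(table(factor(key, levels = uniq)))
  ord <- order(-freq, seq_along(uniq))
  uniq <- uniq[ord]; freq <- freq[ord]
  ids <- sprintf("hap_%02d", seq_along(uniq))
  members <- lapply(uniq, function(u) names(seqs)[key == u])
  structure(
    list(seq = setNames(uniq, ids), freq = setNames(freq, ids),
         members = setNames(members, ids),
         retained_columns = which(ok_col)),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$seq), "haplotypes from",
      sum(x$freq), "sequences;", length(x$retained_columns),
      "comparable columns\n")
  invisible(x)
}

# minimum spanning network (epsilon = 0): process distances in increasing
# order; at each level connect all pairs whose components were still
# separate before the level (so minimal-cost ties are all kept)
msn_edges <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(matrix(numeric(0), ncol = 3))
  comp <- seq_len(n)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pw <- d[pairs]
  edges <- NULL
  for (lev in sort(unique(pw))) {
    at <- pairs[pw == lev, , drop = FALSE]
    use <- comp[at[, 1]] != comp[at[, 2]]
    if (any(use)) {
      sel <- at[use, , drop = FALSE]
      edges <- rbind(edges, cbind(sel, lev))
      for (r in seq_len(nrow(sel))) {   # merge after the whole level
        ca <- comp[sel[r, 1]]; cb <- comp[sel[r, 2]]
        if (ca != cb) comp[comp == cb] <- ca
      }
    }
    if (length(unique(comp)) == 1L) break
  }
  colnames(edges) <- c("from", "to", "weight")
  edges
}

# MST total cost (Prim) on a distance matrix
mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1, ]
  cost <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    cost <- cost + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  cost
}

# quasi-median(s) of three rows of a character matrix: majority per
# column; columns where all three states differ generate all three
# (capped: more than max_free such columns yields no candidate)
quasi_medians_rows <- function(a, b, c_, max_free = 2L) {
  n <- length(a)
  med <- a
  free <- integer(0)
  for (i in seq_len(n)) {
    x <- c(a[i], b[i], c_[i])
    if (x[2] == x[3]) med[i] <- x[2]
    else if (x[1] == x[2] || x[1] == x[3]) med[i] <- x[1]
    else free <- c(free, i)
  }
  if (!length(free)) return(list(med))
  if (length(free) > max_free) return(list())
  grids <- expand.grid(lapply(free, function(i) c(a[i], b[i], c_[i])),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grids)), function(r) {
    m <- med
    m[free] <- as.character(grids[r, ])
    m
  })
}

# quasi-median closure of a set of sequences (rows of a character
# matrix), capped in size
qm_closure <- function(mat, cap = 128L) {
  key <- function(m) apply(m, 1, paste, collapse = "")
  keys <- key(mat)
  repeat {
    n <- nrow(mat)
    if (n >= cap) break
    added <- FALSE
    for (i in seq_len(n - 2L)) {
      for (j in (i + 1L):(n - 1L)) {
        for (k in (j + 1L):n) {
          for (q in quasi_medians_rows(mat[i, ], mat[j, ], mat[k, ])) {
            kq <- paste(q, collapse = "")
            if (!kq %in% keys) {
              mat <- rbind(mat, q)
              keys <- c(keys, kq)
              added <- TRUE
            }
          }
        }
      }
    }
    if (!added || nrow(mat) >= cap) break
  }
  mat
}

dist_rows <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0L, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    di <- colSums(t(mat[(i + 1L):n, , drop = FALSE]) != mat[i, ])
    d[i, (i + 1L):n] <- di
    d[(i + 1L):n, i] <- di
  }
  d
}

#' Median-joining haplotype network (epsilon = 0)
#'
#' Builds the quasi-median closure of the haplotypes (per-column majority
#' of connected triples, iterated), then selects the set of median
#' vectors that minimises the total spanning cost of the network. A
#' spanning tree over n observed haplotypes never needs more than n - 2
#' Steiner points, so the search enumerates median subsets up to that
#' size exactly whenever the closure is small enough (ties: fewest
#' medians, then lexicographically smallest set); larger inputs fall back
#' to a greedy best-improvement search. The returned network is the
#' epsilon = 0 minimum-spanning network (all minimal-cost ties kept) over
#' the observed haplotypes plus the selected medians.
#'
#' @param haps a `haplotype_set` (or named character vector of unique
#'   equal-length sequences).
#' @param closure_cap maximum closure size before falling back to the
#'   greedy search (default 128).
#' @param subset_budget maximum number of median subsets to enumerate in
#'   the exact search (default 2e5).
#' @return object of class `haplo_network`: `nodes` data.frame (`id`,
#'   `sequence`, `observed`, `freq`), `edges` data.frame (`from`, `to`,
#'   `steps`), and the `igraph` graph.
#' @export
mj_network <- function(haps, closure_cap = 128L, subset_budget = 2e5) {
  if (inherits(haps, "haplotype_set")) {
    seqs <- haps$seq
    freq <- haps$freq
  } else {
    seqs <- haps
    freq <- setNames(rep(1L, length(haps)), names(haps))
  }
  stopifnot(length(seqs) >= 2L)
  obs <- names(seqs)
  n_obs <- length(seqs)
  mat_obs <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))

  closure <- qm_closure(mat_obs, cap = closure_cap)
  all_keys <- apply(closure, 1, paste, collapse = "")
  med_idx <- setdiff(seq_len(nrow(closure)), seq_len(n_obs))
  # order median candidates lexicographically so ties resolve smallest-first
  med_idx <- med_idx[order(all_keys[med_idx])]
  d_all <- dist_rows(closure)

  sub_cost <- function(sel) {
    idx <- c(seq_len(n_obs), sel)
    mst_cost(d_all[idx, idx, drop = FALSE])
  }
  k_max <- min(length(med_idx), max(n_obs - 2L, 0L))
  n_subsets <- sum(choose(length(med_idx), 0:k_max))
  chosen <- integer(0)
  if (nrow(closure) < closure_cap && n_subsets <= subset_budget) {
    # exact: smallest-cost subset; scanning sizes upward makes the first
    # minimum found the fewest-median, lexicographically-smallest one
    best_cost <- sub_cost(integer(0))
    for (k in seq_len(k_max)) {
      if (!length(med_idx) || k > length(med_idx)) break
      sel_list <- utils::combn(med_idx, k, simplify = FALSE)
      for (sel in sel_list) {
        cc <- sub_cost(sel)
        if (cc < best_cost - 1e-9) {
          best_cost <- cc
          chosen <- sel
        }
      }
    }
  } else {
    # greedy best-improvement fallback
    pool <- med_idx
    repeat {
      cur <- sub_cost(chosen)
      gains <- vapply(setdiff(pool, chosen),
                      function(i) cur - sub_cost(c(chosen, i)), numeric(1))
      cand <- setdiff(pool, chosen)
      if (length(cand) && max(gains) > 1e-9) {
        chosen <- c(chosen, cand[which.max(gains)])
        next
      }
      break
    }
  }

  node_idx <- c(seq_len(n_obs), sort(chosen))
  node_seq <- all_keys[node_idx]
  observed <- node_idx <= n_obs
  d <- d_all[node_idx, node_idx, drop = FALSE]
  ed <- msn_edges(d)
  ids <- character(length(node_seq))
  ids[observed] <- obs[match(node_seq[observed], seqs)]
  ids[!observed] <- sprintf("median_%d", seq_len(sum(!observed)))
  nodes <- data.frame(
    id = ids, sequence = node_seq, observed = observed,
    freq = ifelse(observed, freq[ids], 0L),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = ids[ed[, 1]], to = ids[ed[, 2]],
                      steps = ed[, 3], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 total_cost = mst_cost(d)),   # spanning cost (tie edges excluded)
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", sum(x$nodes$observed), "haplotypes,",
      sum(!x$nodes$observed), "median vectors,", nrow(x$edges),
      "edges; total", x$total_cost, "steps\n")
  invisible(x)
}

#' Neighbour-joining tree of haplotypes with bootstrap support
#'
#' Hamming (or p-) distances between haplotype sequences, classical
#' neighbour joining, and nonparametric bootstrap over alignment columns;
#' support values are the fraction of replicates containing each internal
#' bipartition. The tree is rooted on the outgroup.
#'
#' @param haps a `haplotype_set` or named character vector (the outgroup
#'   sequence must be included).
#' @param outgroup haplotype id used to root the tree.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param p_distance use proportion distances instead of counts.
#' @return rooted `phylo` tree; `node.label` holds support fractions.
#' @export
nj_tree <- function(haps, outgroup, n_boot = 1000L, seed = 1L,
                    p_distance = FALSE) {
  seqs <- if (inherits(haps, "haplotype_set")) haps$seq else haps
  if (!outgroup %in% names(seqs)) stop("outgroup id not found: ", outgroup)
  if (length(seqs) < 3L) stop("need at least 3 haplotypes")
  m <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  dfun <- function(mat) {
    d <- hamming_matrix(setNames(apply(mat, 1, paste, collapse = ""),
                                 rownames(mat)))
    if (p_distance) d <- d / ncol(mat)
    stats::as.dist(d)
  }
  tree <- ape::nj(dfun(m))
  if (length(seqs) >= 4L) {
    set.seed(seed)
    bp <- ape::boot.phylo(tree, m, function(xx) ape::nj(dfun(xx)),
                          B = n_boot, quiet = TRUE, trees = FALSE)
    tree$node.label <- bp / n_boot
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Distribution of a marked subset (carriers) over the haplotype network
#'
#' Reports how many haplotypes contain at least one carrier, how many of
#' those are shared with non-carriers, and whether the carrier haplotypes
#' form a connected subnetwork that excludes all non-carrier haplotypes
#' (median vectors may serve as connectors) -- a monophyly proxy.
#'
#' @param net a `haplo_network`.
#' @param haps the `haplotype_set` behind it (for memberships).
#' @param carriers character vector of carrier individual ids.
#' @return list `n_carrier_haplotypes`, `n_shared`, `connected_exclusive`.
#' @export
carrier_clade_test <- function(net, haps, carriers) {
  stopifnot(inherits(net, "haplo_network"), inherits(haps, "haplotype_set"))
  if (!length(carriers)) return(list(n_carrier_haplotypes = 0L,
                                     n_shared = 0L,
                                     connected_exclusive = NA))
  has_car <- vapply(haps$members, function(mm) any(mm %in% carriers), logical(1))
  has_non <- vapply(haps$members, function(mm) any(!mm %in% carriers), logical(1))
  car_haps <- names(haps$members)[has_car]
  n_shared <- sum(has_car & has_non)
  if (!length(car_haps)) return(list(n_carrier_haplotypes = 0L,
                                     n_shared = 0L,
                                     connected_exclusive = NA))
  keep <- net$nodes$id[net$nodes$id %in% car_haps | !net$nodes$observed]
  sub <- igraph::induced_subgraph(net$graph, keep)
  comp <- igraph::components(sub)
  memb <- comp$membership[car_haps]
  connected_exclusive <- length(unique(memb)) == 1L
  list(n_carrier_haplotypes = length(car_haps),
       n_shared = as.integer(n_shared),
       connected_exclusive = connected_exclusive)
}
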