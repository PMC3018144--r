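# Detection filtering, strain profiles, unsupervised clustering, and the
# permutation test of whether expression clustering predicts phenotype.

#' Filter probes by detection calls
#'
#' Mode `"all-replicates"` keeps probes detected on every replicate array of
#' at least `min_strains` strains; strains contributing only a single array
#' are excluded from the requirement (they can neither satisfy nor fail it),
#' mirroring how a strain with one array is handled in replicate-based
#' detection filtering. Mode `"strain-fraction"` keeps probes detected (on
#' at least one array) in at least `fraction` of the strains.
#'
#' @param expr an [expression_matrix].
#' @param min_strains minimum number of fully-detected strains
#'   (all-replicates mode; default 3).
#' @param mode `"all-replicates"` or `"strain-fraction"`.
#' @param fraction minimum fraction of strains (strain-fraction mode;
#'   default 0.25).
#' @return character vector of retained probe ids.
#' @export
detection_filter <- function(expr, min_strains = 3,
                             mode = c("all-replicates", "strain-fraction"),
                             fraction = 0.25) {
  mode <- match.arg(mode)
  bys <- arrays_by_strain(expr)
  det <- expr$detected
  if (mode == "all-replicates") {
    multi <- bys[lengths(bys) >= 2L]
    if (!length(multi)) stop("no strain has replicate arrays")
    all_det <- vapply(multi, function(a)
      rowSums(det[, a, drop = FALSE]) == length(a),
      logical(nrow(det)))
    keep <- rowSums(all_det) >= min_strains
  } else {
    any_det <- vapply(bys, function(a)
      rowSums(det[, a, drop = FALSE]) > 0L,
      logical(nrow(det)))
    keep <- rowMeans(any_det) >= fraction
  }
  rownames(det)[keep]
}

#' Per-strain median expression profiles
#'
#' Collapses replicate arrays to the per-probe median within each strain.
#'
#' @param expr an [expression_matrix].
#' @param probes optional probe subset.
#' @return strain x probe numeric matrix (strains in rows).
#' @export
strain_medians <- function(expr, probes = rownames(expr$values)) {
  bys <- arrays_by_strain(expr)
  v <- expr$values[probes, , drop = FALSE]
  out <- vapply(bys, function(a)
    apply(v[, a, drop = FALSE], 1, stats::median),
    numeric(length(probes)))
  if (length(probes) == 1L) {
    out <- matrix(out, nrow = 1L, dimnames = list(probes, names(bys)))
  }
  t(out)  # strains x probes
}

# per-strain means and replicate counts (the unit for DE and eQTL models)
strain_means <- function(expr, probes = rownames(expr$values)) {
  bys <- arrays_by_strain(expr)
  v <- expr$values[probes, , drop = FALSE]
  m <- vapply(bys, function(a) rowMeans(v[, a, drop = FALSE]),
              numeric(length(probes)))
  if (length(probes) == 1L) m <- matrix(m, nrow = 1L,
                                        dimnames = list(probes, names(bys)))
  list(means = m, n_rep = lengths(bys))  # probes x strains
}

# 1 - Pearson distance between strain profiles (strains in rows)
pearson_distance <- function(profiles) {
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "))
  }
  1 - stats::cor(t(profiles))
}

#' Hierarchical clustering of strain expression profiles
#'
#' Agglomerative clustering with 1 - Pearson correlation as the distance
#' and complete linkage, the standard configuration for grouping strain
#' median profiles.
#'
#' @param profiles strain x probe matrix (e.g. from [strain_medians]).
#' @param method linkage method (default `"complete"`).
#' @return An [stats::hclust] tree.
#' @export
hcluster_profiles <- function(profiles, method = "complete") {
  if (nrow(profiles) < 3L) stop("need >= 3 profiles to cluster")
  stats::hclust(stats::as.dist(pearson_distance(profiles)), method = method)
}

#' Permutation test of phenotype-predictive clustering
#'
#' Measures how tightly susceptible strains cluster in expression space:
#' the statistic is the mean 1 - Pearson distance among susceptible strains
#' divided by the mean distance between susceptible and resistant strains,
#' computed on strain median profiles of known-phenotype strains only.
#' Small values mean susceptible strains sit closer to each other than to
#' resistant strains. Significance is assessed by permuting the phenotype
#' labels across strains; the one-sided p-value (toward tighter clustering)
#' uses the add-one rule, p = (1 + #\{permuted statistic <= observed\}) /
#' (n_perm + 1), so it is never zero.
#'
#' @param profiles strain x probe matrix including at least the
#'   known-phenotype strains.
#' @param panel a [strain_panel]; only susceptible/resistant strains enter.
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list with `statistic`, `p_value`, `n_perm`, `seed`.
#' @export
cluster_permutation_test <- function(profiles, panel, n_perm = 10000,
                                     seed = 1L) {
  cs <- contrast_strains(panel)
  strains <- c(cs$susceptible, cs$resistant)
  missing <- setdiff(strains, rownames(profiles))
  if (length(missing)) stop("profiles missing strain(s): ",
                            paste(missing, collapse = ", "))
  d <- pearson_distance(profiles[strains, , drop = FALSE])
  is_sus <- strains %in% cs$susceptible
  ratio_stat <- function(sus_mask) {
    within <- d[sus_mask, sus_mask, drop = FALSE]
    between <- d[sus_mask, !sus_mask, drop = FALSE]
    mean(within[upper.tri(within)]) / mean(between)
  }
  obs <- ratio_stat(is_sus)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(is_sus)
    if (ratio_stat(perm) <= obs) hits <- hits + 1L
  }
  list(statistic = obs,
       p_value = (1 + hits) / (n_perm + 1),
       n_perm = n_perm,
       seed = seed)
}
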