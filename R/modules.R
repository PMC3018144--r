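# Anchored co-expression modules: anchors are probes both differentially
# expressed between phenotype classes and linked to a cis-eQTL; each anchor
# seeds a module of correlated probes, which is trimmed by replication in
# an independent recombinant inbred panel and scored against phenotype via
# its eigengene.

#' Define anchor probes
#'
#' Anchors are the probes that are differentially expressed (q below `fdr`)
#' and linked to at least one significant cis-eQTL record.
#'
#' @param de_table result of [differential_expression].
#' @param eqtl_records result of [map_cis_eqtls] (uses its `significant`
#'   column).
#' @param fdr DE q-value threshold (default 0.05).
#' @return character vector of anchor probe ids (empty, with a warning,
#'   when the intersection is empty).
#' @export
define_anchors <- function(de_table, eqtl_records, fdr = 0.05) {
  de_hits <- de_table$probe_id[de_table$q_value < fdr]
  eqtl_hits <- unique(eqtl_records$probe_id[eqtl_records$significant])
  anchors <- intersect(de_hits, eqtl_hits)
  if (!length(anchors)) warning("no probes are both DE and eQTL-linked")
  anchors
}

#' Build the initial module around an anchor
#'
#' Correlates every other probe with the anchor across all arrays (Pearson),
#' converts r to a p-value through the t transform with n - 2 degrees of
#' freedom, estimates q-values, and admits probes with q below `fdr`.
#'
#' @param anchor anchor probe id.
#' @param expr an [expression_matrix]; correlation is computed across
#'   arrays by default.
#' @param fdr module-inclusion q-value threshold (default 0.01).
#' @param probes candidate probe universe (default all probes).
#' @param use_strain_medians correlate strain medians instead of arrays.
#' @return character vector of target probe ids (never contains the anchor).
#' @export
build_module <- function(anchor, expr, fdr = 0.01,
                         probes = rownames(expr$values),
                         use_strain_medians = FALSE) {
  mat <- if (use_strain_medians) t(strain_medians(expr, probes))
         else expr$values[probes, , drop = FALSE]
  if (!(anchor %in% rownames(mat))) stop("anchor ", anchor, " not in expression data")
  a <- mat[anchor, ]
  if (stats::sd(a) == 0) stop("anchor ", anchor, " has zero variance")
  others <- setdiff(rownames(mat), anchor)
  keep <- others[apply(mat[others, , drop = FALSE], 1, stats::sd) > 0]
  r <- as.vector(stats::cor(a, t(mat[keep, , drop = FALSE])))
  n <- length(a)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  q <- qvalues(p)
  keep[q < fdr]
}

#' Trim a module by replication in a recombinant inbred panel
#'
#' For each RI compartment, fits a linear model of each target's expression
#' on the anchor's expression across RI lines, adjusts p-values within the
#' compartment by Benjamini-Hochberg, and keeps targets significant (FDR
#' below `fdr`) in at least one compartment.
#'
#' @param anchor anchor probe id.
#' @param targets character vector of target probe ids.
#' @param ri_expr named list of RI [expression_matrix] objects (one per
#'   compartment; a single matrix is accepted).
#' @param fdr within-compartment BH threshold (default 0.25).
#' @return list with `kept` (trimmed target set), `counts` (named integer,
#'   targets replicated per compartment), `untrimmable` (TRUE when the
#'   anchor is absent from every compartment; then `kept` = `targets`).
#' @export
trim_module <- function(anchor, targets, ri_expr, fdr = 0.25) {
  if (inherits(ri_expr, "expression_matrix")) ri_expr <- list(RI = ri_expr)
  counts <- stats::setNames(integer(length(ri_expr)), names(ri_expr))
  kept_any <- stats::setNames(rep(FALSE, length(targets)), targets)
  anchor_seen <- FALSE
  for (comp in names(ri_expr)) {
    ex <- ri_expr[[comp]]
    if (!(anchor %in% rownames(ex$values))) next
    anchor_seen <- TRUE
    present <- intersect(targets, rownames(ex$values))
    if (!length(present)) next
    sm <- strain_means(ex, c(anchor, present))
    a <- sm$means[anchor, ]
    if (stats::sd(a) == 0) next
    # slope t-test of target ~ anchor, via the correlation identity
    # t = r * sqrt(n-2) / sqrt(1-r^2) (same p as the lm slope)
    n <- length(a)
    pvals <- vapply(present, function(tg) {
      y <- sm$means[tg, ]
      if (stats::sd(y) == 0) return(1)
      r <- stats::cor(y, a)
      tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
      2 * stats::pt(-abs(tt), n - 2)
    }, numeric(1))
    bh <- stats::p.adjust(pvals, method = "BH")
    rep_here <- present[bh < fdr]
    counts[comp] <- length(rep_here)
    kept_any[rep_here] <- TRUE
  }
  if (!anchor_seen) {
    warning("anchor ", anchor, " undetected in all RI compartments; module not trimmed")
    return(list(kept = targets, counts = counts, untrimmable = TRUE))
  }
  list(kept = names(kept_any)[kept_any], counts = counts, untrimmable = FALSE)
}

#' Module eigengene
#'
#' The first principal component of the module's probe-standardized
#' expression matrix: each member row is centered and scaled, and the first
#' right singular vector (one value per array, unit norm) is the eigengene.
#' Its sign is fixed so that it correlates positively with the module's
#' mean standardized profile. A single-member module returns that member's
#' standardized profile, rescaled to unit norm.
#'
#' @param module_expr member x array numeric matrix (anchor plus targets).
#' @return list with `eigengene` (named per-array values, unit norm) and
#'   `var_explained` (fraction of variance carried by the first component).
#' @export
eigengene <- function(module_expr) {
  stopifnot(is.matrix(module_expr), nrow(module_expr) >= 1L)
  z <- t(scale(t(module_expr)))
  z <- z[apply(module_expr, 1, stats::sd) > 0, , drop = FALSE]
  if (nrow(z) == 0L) stop("all module members have zero variance")
  if (nrow(z) == 1L) {
    v <- z[1, ] / sqrt(sum(z[1, ]^2))
    return(list(eigengene = v, var_explained = 1))
  }
  sv <- svd(z)
  v <- sv$v[, 1]
  names(v) <- colnames(module_expr)
  if (stats::cor(v, colMeans(z)) < 0) v <- -v
  list(eigengene = v, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Score module eigengenes against susceptibility
#'
#' Packs the module eigengenes into an expression matrix (modules in rows,
#' arrays in columns, same array-to-strain map) and applies the same
#' moderated differential-expression model used for individual probes;
#' modules are ranked by significance.
#'
#' @param modules named list of modules; each must carry an `eigengene`
#'   vector over the arrays of `expr`.
#' @param expr the [expression_matrix] the eigengenes were computed on
#'   (supplies the array-to-strain map).
#' @param panel a [strain_panel].
#' @return data.frame (one row per module, ranked by p): `module_id`,
#'   `effect`, `t_mod`, `p_nominal`, `q_value`.
#' @export
module_susceptibility <- function(modules, expr, panel) {
  if (!length(modules)) {
    return(data.frame(module_id = character(0), effect = numeric(0),
                      t_mod = numeric(0), p_nominal = numeric(0),
                      q_value = numeric(0)))
  }
  em <- do.call(rbind, lapply(modules, function(m)
    m$eigengene[colnames(expr$values)]))
  rownames(em) <- names(modules)
  colnames(em) <- colnames(expr$values)
  eexpr <- expression_matrix(em, array_to_strain = expr$array_to_strain)
  de <- differential_expression(eexpr, panel)
  names(de)[names(de) == "probe_id"] <- "module_id"
  de[order(de$p_nominal), , drop = FALSE]
}

#' Module-module eigengene correlation network
#'
#' Computes all pairwise Pearson correlations between module eigengenes and
#' keeps edges whose correlation strictly exceeds `corr_floor` (low and
#' negative correlations are dropped). Also returns the per-strain-averaged,
#' row-normalized eigengene matrix used for heatmap display.
#'
#' @param modules named list of modules with `eigengene` vectors and
#'   (optionally) `targets_trimmed` for node weights.
#' @param expr the [expression_matrix] supplying the array-to-strain map.
#' @param corr_floor minimum correlation for an edge (default 0.5, strict).
#' @return list with `edges` (data.frame `module_a`, `module_b`, `weight`),
#'   `node_sizes` (post-trim target counts), and `eigengene_by_strain`
#'   (module x strain matrix, rows centered/scaled).
#' @export
module_network <- function(modules, expr, corr_floor = 0.5) {
  ids <- names(modules)
  em <- do.call(rbind, lapply(modules, function(m)
    m$eigengene[colnames(expr$values)]))
  rownames(em) <- ids
  edges <- data.frame(module_a = character(0), module_b = character(0),
                      weight = numeric(0))
  if (length(ids) >= 2L) {
    cc <- stats::cor(t(em))
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        if (cc[i, j] > corr_floor) {
          edges <- rbind(edges, data.frame(module_a = ids[i],
                                           module_b = ids[j],
                                           weight = cc[i, j]))
        }
      }
    }
  }
  strains <- unique(expr$array_to_strain)
  by_strain <- vapply(strains, function(s)
    rowMeans(em[, expr$array_to_strain == s, drop = FALSE]),
    numeric(length(ids)))
  if (length(ids) == 1L) by_strain <- matrix(by_strain, 1L,
                                             dimnames = list(ids, strains))
  by_strain <- t(scale(t(by_strain)))
  node_sizes <- vapply(modules, function(m)
    length(m$targets_trimmed %||% m$targets), integer(1))
  list(edges = edges, node_sizes = node_sizes,
       eigengene_by_strain = by_strain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
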