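# Moderated differential expression between susceptible and resistant
# strains, and Storey q-values for FDR estimation.

#' Storey q-values
#'
#' Estimates the proportion of true nulls pi0 by the smoother method —
#' pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) over the grid
#' `lambda`, smoothed with a cubic spline and read off at the largest
#' lambda — then converts p-values to q-values by the step-up rule
#' q_(i) = min_\{j >= i\} pi0 m p_(j) / j. With `pi0 = 1` this reduces to
#' Benjamini-Hochberg adjusted p-values. For fewer than 100 p-values the
#' smoother is unreliable and pi0 defaults to 1 (conservative).
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @param pi0 optional fixed null proportion; `NULL` (default) estimates it.
#' @param lambda grid for the pi0 smoother.
#' @return q-values, same length and order as `pvals`.
#' @export
qvalues <- function(pvals, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(1, max(pi0, 1e-3))
    }
  }
  o <- order(pvals)
  q_sorted <- pi0 * m * pvals[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Differential expression between susceptible and resistant strains
#'
#' Fits, per probe, a linear model of per-strain mean expression on
#' susceptibility status, weighting each strain by its replicate array
#' count so that strains profiled more deeply carry proportionally more
#' information (the strain, not the array, is the independent genetic
#' unit). With `moderated = TRUE` residual variances are shrunk toward a
#' pooled prior by empirical Bayes (limma's moderated t with augmented
#' degrees of freedom); with `moderated = FALSE` the ordinary per-probe t
#' statistic is returned. FDR is estimated with [qvalues]. Strains of
#' unknown phenotype are excluded, and probes constant across all included
#' strains are dropped with a warning.
#'
#' @param expr an [expression_matrix].
#' @param panel a [strain_panel] with >= 2 strains per phenotype class.
#' @param probes optional probe subset (e.g. from [detection_filter]).
#' @param moderated logical; empirical-Bayes variance moderation.
#' @return data.frame with `probe_id`, `effect` (susceptible minus
#'   resistant, log-expression units), `t_mod`, `p_nominal`, `q_value`.
#' @export
differential_expression <- function(expr, panel,
                                    probes = rownames(expr$values),
                                    moderated = TRUE) {
  cs <- contrast_strains(panel)
  sm <- strain_means(expr, probes)
  strains <- intersect(colnames(sm$means), c(cs$susceptible, cs$resistant))
  if (length(intersect(strains, cs$susceptible)) < 2L ||
      length(intersect(strains, cs$resistant)) < 2L) {
    stop("need expression for >= 2 strains per phenotype class")
  }
  y <- sm$means[, strains, drop = FALSE]
  keep <- apply(y, 1, function(v) stats::var(v) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " probe(s) constant across strains excluded")
    y <- y[keep, , drop = FALSE]
  }
  group <- factor(ifelse(strains %in% cs$susceptible, "susceptible", "resistant"),
                  levels = c("resistant", "susceptible"))
  design <- stats::model.matrix(~group)
  w <- matrix(sm$n_rep[strains], nrow(y), ncol(y), byrow = TRUE)
  fit <- limma::lmFit(y, design, weights = w)
  if (moderated && nrow(y) >= 3L) {
    eb <- limma::eBayes(fit)
    tt <- eb$t[, 2]
    pp <- eb$p.value[, 2]
  } else {
    tt <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * fit$sigma)
    pp <- 2 * stats::pt(-abs(tt), fit$df.residual)
  }
  data.frame(probe_id = rownames(y),
             effect = unname(fit$coefficients[, 2]),
             t_mod = unname(tt),
             p_nominal = unname(pp),
             q_value = qvalues(unname(pp)),
             row.names = NULL)
}

#' Collapse a probe-level DE table to gene level
#'
#' When several probes target the same gene, the most significant probe
#' represents the gene.
#'
#' @param de_table result of [differential_expression].
#' @param probe_to_gene named character vector, probe id -> gene id.
#' @return gene-level data.frame (one row per gene, best probe retained).
#' @export
de_gene_table <- function(de_table, probe_to_gene) {
  de_table$gene <- unname(probe_to_gene[de_table$probe_id])
  de_table <- de_table[!is.na(de_table$gene), , drop = FALSE]
  de_table <- de_table[order(de_table$p_nominal), , drop = FALSE]
  out <- de_table[!duplicated(de_table$gene), , drop = FALSE]
  out[order(out$gene), c("gene", setdiff(names(out), "gene")), drop = FALSE]
}
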