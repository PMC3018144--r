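# End-to-end orchestration: genotypes + expression + phenotype in, anchored
# susceptibility modules out.

#' Run the full anchored-module pipeline
#'
#' Chains every stage: SNP filtering and haplotype-block construction,
#' CNVR tagging, detection filtering, the cluster permutation test,
#' differential expression, cis-eQTL mapping, anchor definition, module
#' building, RI trimming, eigengenes, susceptibility scoring and the
#' module-module network.
#'
#' @param geno a [genotype_matrix].
#' @param cnvrs a [cnvr_set] (optional; used for SNP filtering, tagging and
#'   CNVR-eQTL markers).
#' @param expr an [expression_matrix].
#' @param panel a [strain_panel].
#' @param probe_positions data.frame with `probe_id`, `chrom`, `pos`.
#' @param ri optional list with `geno` (RI [genotype_matrix]) and `expr`
#'   (named list of RI [expression_matrix] per compartment); without it
#'   modules are not trimmed or validated.
#' @param de_fdr anchor DE threshold (default 0.05).
#' @param module_fdr module-inclusion threshold (default 0.01).
#' @param trim_fdr RI replication threshold (default 0.25).
#' @param eqtl_alpha eQTL significance threshold (default 0.05).
#' @param window_bp cis window (default 50000 — roughly one haplotype
#'   block on the simulated miniature genome; use 2e6 at real mouse
#'   genome scale).
#' @param n_perm eQTL permutations (default 1000).
#' @param cluster_n_perm cluster-test permutations (default 10000).
#' @param max_errors block error tolerance (default 1).
#' @param corr_floor module network edge floor (default 0.5).
#' @param eqtl_weights `"kinship"` or `"uniform"`.
#' @param seed RNG seed for every stochastic stage.
#' @return list with `blocks`, `tags`, `kept_probes`, `cluster_test`, `de`,
#'   `eqtl`, `anchors`, `modules` (per anchor: targets, trimmed targets,
#'   per-compartment counts, eigengene), `module_table` (one row per
#'   module: sizes, replication counts, susceptibility p and q),
#'   `susceptibility`, `network`, `validation`.
#' @export
run_anchored_pipeline <- function(geno, cnvrs = NULL, expr, panel,
                                  probe_positions, ri = NULL,
                                  de_fdr = 0.05, module_fdr = 0.01,
                                  trim_fdr = 0.25, eqtl_alpha = 0.05,
                                  window_bp = 50000, n_perm = 1000,
                                  cluster_n_perm = 10000, max_errors = 1,
                                  corr_floor = 0.5,
                                  eqtl_weights = "kinship", seed = 1L) {
  inf <- filter_informative(geno, cnvrs)
  blocks <- build_blocks(inf, max_errors = max_errors)
  tags <- if (!is.null(cnvrs)) tag_cnvrs(blocks, cnvrs) else NULL

  kept <- detection_filter(expr)
  med <- strain_medians(expr, kept)
  ct <- cluster_permutation_test(med, panel, n_perm = cluster_n_perm,
                                 seed = seed)
  de <- differential_expression(expr, panel, probes = kept)
  eqtl <- map_cis_eqtls(expr, probe_positions, blocks = blocks,
                        cnvrs = cnvrs, geno = inf, window_bp = window_bp,
                        n_perm = n_perm, weights = eqtl_weights,
                        alpha = eqtl_alpha, seed = seed)
  anchors <- suppressWarnings(define_anchors(de, eqtl, fdr = de_fdr))

  modules <- list()
  for (a in anchors) {
    tg <- build_module(a, expr, fdr = module_fdr, probes = kept)
    if (!length(tg)) next
    m <- list(anchor = a, targets = tg)
    if (!is.null(ri)) {
      tr <- trim_module(a, tg, ri$expr, fdr = trim_fdr)
      m$targets_trimmed <- tr$kept
      m$replication_counts <- tr$counts
      m$untrimmable <- tr$untrimmable
    } else {
      m$targets_trimmed <- tg
      m$replication_counts <- NULL
      m$untrimmable <- NA
    }
    member_expr <- expr$values[c(a, m$targets_trimmed), , drop = FALSE]
    eg <- eigengene(member_expr)
    m$eigengene <- eg$eigengene
    m$var_explained <- eg$var_explained
    m$minimal <- length(m$targets_trimmed) < 3L
    modules[[paste0("A_", match(a, anchors))]] <- m
  }

  sus <- module_susceptibility(modules, expr, panel)
  net <- if (length(modules)) module_network(modules, expr, corr_floor)
         else NULL
  validation <- NULL
  if (!is.null(ri) && length(anchors)) {
    ap <- probe_positions[probe_positions$probe_id %in% anchors, , drop = FALSE]
    validation <- validate_in_ri(ap, ri$geno, ri$expr, window_bp = window_bp)
  }

  module_table <- do.call(rbind, lapply(names(modules), function(id) {
    m <- modules[[id]]
    row <- data.frame(module_id = id, anchor = m$anchor,
                      n_initial = length(m$targets),
                      n_trimmed = length(m$targets_trimmed),
                      minimal = m$minimal)
    if (!is.null(m$replication_counts)) {
      row <- cbind(row, as.data.frame(as.list(m$replication_counts)))
    }
    i <- match(id, sus$module_id)
    row$susceptibility_p <- sus$p_nominal[i]
    row$susceptibility_q <- sus$q_value[i]
    row
  }))

  list(blocks = blocks, tags = tags, kept_probes = kept,
       cluster_test = ct, de = de, eqtl = eqtl, anchors = anchors,
       modules = modules, module_table = module_table,
       susceptibility = sus, network = net, validation = validation,
       seed = seed)
}
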