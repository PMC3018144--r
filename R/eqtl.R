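# cis-eQTL mapping: expression traits (per-strain means) are associated
# with haplotype-block labels or CNVR genotypes treated as factors in a
# one-way ANOVA, with significance calibrated by a relatedness-weighted
# strain permutation null.

# one-way ANOVA F of y on integer group index g (NAs already removed);
# returns c(F, p, df1, df2) or NULL when fewer than 2 usable classes
anova_f <- function(y, g) {
  tab <- table(g)
  k <- length(tab)
  n <- length(y)
  if (k < 2L || n - k < 1L) return(NULL)
  gm <- tapply(y, g, mean)
  mu <- mean(y)
  ssb <- sum(tab * (gm[names(tab)] - mu)^2)
  ssw <- sum((y - gm[as.character(g)])^2)
  df1 <- k - 1L
  df2 <- n - k
  f <- if (ssw == 0) Inf else (ssb / df1) / (ssw / df2)
  c(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
    df1 = df1, df2 = df2)
}

#' Association of an expression trait with a marker genotype
#'
#' One-way ANOVA of per-strain trait values on the genotype class treated
#' as an unordered factor (haplotype labels and copy-number classes alike).
#'
#' @param trait named numeric per-strain trait values (strain means).
#' @param genotype named genotype class per strain (`NA` = untyped).
#' @return list with `F_stat`, `p_nominal`, `df1`, `df2`, or `NULL` when
#'   fewer than 2 genotype classes are usable (marker not tested).
#' @export
marker_association <- function(trait, genotype) {
  shared <- intersect(names(trait), names(genotype))
  y <- trait[shared]
  g <- genotype[shared]
  ok <- !is.na(y) & !is.na(g)
  res <- anova_f(y[ok], as.character(g[ok]))
  if (is.null(res)) return(NULL)
  list(F_stat = unname(res["F"]), p_nominal = unname(res["p"]),
       df1 = unname(res["df1"]), df2 = unname(res["df2"]))
}

#' Relatedness-derived strain permutation weights
#'
#' Genetically redundant strains should not dominate a permutation null, so
#' each strain s is weighted by the inverse of its total similarity to the
#' rest of the panel: w_s = 1 / (1 + sum_\{t != s\} K_st), with
#' K_st = 1 - (normalized SNP distance). Genetically unique strains are
#' weighted up, near-duplicate strains down; weights are normalized to
#' mean 1.
#'
#' @param geno a [genotype_matrix] (>= 3 strains).
#' @return named numeric weights, one per strain, mean 1.
#' @export
compute_strain_weights <- function(geno) {
  if (n_strains(geno) < 3L) stop("need >= 3 strains")
  k <- 1 - strain_snp_distance(geno, normalized = TRUE)
  tot <- rowSums(k) - diag(k)
  w <- 1 / (1 + tot)
  w / mean(w)
}

#' Weighted strain-permutation p-value for a marker association
#'
#' Builds a permutation null for the ANOVA F by repeatedly re-assigning
#' trait values to genotype classes: each permutation draws a strain order
#' without replacement with probability proportional to `weights`, so
#' related strains (down-weighted) anchor the null less. The p-value is the
#' add-one fraction of permuted F values at or above the observed F.
#' Uniform weights give the plain permutation test.
#'
#' @param trait named numeric per-strain trait values.
#' @param genotype named genotype class per strain.
#' @param weights named positive per-strain weights, or `NULL` for uniform.
#' @param n_perm number of permutations (a warning below 100).
#' @param seed RNG seed.
#' @return permutation p-value in (0, 1\].
#' @export
weighted_permutation_p <- function(trait, genotype, weights = NULL,
                                   n_perm = 1000, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse permutation p-value")
  shared <- intersect(names(trait), names(genotype))
  y <- trait[shared]
  g <- genotype[shared]
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]
  g <- as.character(g[ok])
  obs <- anova_f(y, g)
  if (is.null(obs)) stop("marker not testable (fewer than 2 genotype classes)")
  w <- if (is.null(weights)) NULL else unname(weights[names(y)])
  set.seed(seed)
  n <- length(y)
  # permuting trait values across strains keeps the group sizes fixed, so
  # F reduces to a function of per-group sums (same identity as anova_f)
  gi <- match(g, unique(g))
  ng <- tabulate(gi)
  k <- length(ng)
  sumy <- sum(y)
  sst <- sum(y^2) - sumy^2 / n
  df1 <- k - 1L
  df2 <- n - k
  f_of <- function(yp) {
    s <- rowsum(yp, gi)
    ssb <- sum(s^2 / ng) - sumy^2 / n
    ssw <- sst - ssb
    if (ssw <= 0) Inf else (ssb / df1) / (ssw / df2)
  }
  f_obs <- f_of(y)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, n, replace = FALSE, prob = w)
    if (f_of(y[idx]) >= f_obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Candidate cis probe-marker pairs
#'
#' Pairs each positioned probe with every marker whose midpoint lies within
#' `window_bp` of the probe's gene position on the same chromosome.
#'
#' @param probe_positions data.frame with `probe_id`, `chrom`, `pos`.
#' @param markers data.frame with `marker_id`, `chrom`, `start`, `end`.
#' @param window_bp cis window (default 2 Mb).
#' @return data.frame of `probe_id`, `marker_id` pairs.
#' @export
cis_candidates <- function(probe_positions, markers, window_bp = 2e6) {
  no_pos <- is.na(probe_positions$pos) | is.na(probe_positions$chrom)
  if (any(no_pos)) {
    warning(sum(no_pos), " probe(s) without genomic position skipped")
    probe_positions <- probe_positions[!no_pos, , drop = FALSE]
  }
  mid <- (markers$start + markers$end) / 2
  out <- lapply(seq_len(nrow(probe_positions)), function(i) {
    p <- probe_positions[i, ]
    hit <- markers$chrom == p$chrom & abs(mid - p$pos) <= window_bp
    if (!any(hit)) return(NULL)
    data.frame(probe_id = p$probe_id, marker_id = markers$marker_id[hit])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(probe_id = character(0), marker_id = character(0))
  else out
}

# Merge genotype classes represented by a single strain into the nearest
# class: by consensus-string Hamming distance for haplotype markers, by
# copy-number difference for CNVRs. Avoids zero-df ANOVA cells.
merge_singleton_classes <- function(genotype, consensus = NULL) {
  g <- genotype[!is.na(genotype)]
  repeat {
    tab <- table(g)
    if (length(tab) < 2L || all(tab >= 2L)) break
    s <- names(tab)[tab == 1L][1]
    others <- setdiff(names(tab), s)
    dist_to <- vapply(others, function(o) {
      if (!is.null(consensus) && s %in% names(consensus) && o %in% names(consensus)) {
        a <- strsplit(consensus[[s]], "")[[1]]
        b <- strsplit(consensus[[o]], "")[[1]]
        ok <- a != "?" & b != "?"
        sum(a[ok] != b[ok])
      } else {
        abs(suppressWarnings(as.numeric(s)) - suppressWarnings(as.numeric(o)))
      }
    }, numeric(1))
    if (all(is.na(dist_to))) dist_to[] <- 1
    g[g == s] <- others[which.min(dist_to)]
  }
  genotype[names(g)] <- g
  genotype
}

# Marker views over haplotype blocks and CNVRs: a coordinate table plus
# per-marker strain genotype vectors (and consensus strings for blocks).
marker_set <- function(blocks = NULL, cnvrs = NULL) {
  tabs <- list()
  genos <- list()
  cons <- list()
  if (!is.null(blocks) && length(blocks)) {
    ids <- paste0("B", vapply(blocks, `[[`, integer(1), "block_id"))
    tabs$blocks <- data.frame(
      marker_id = ids,
      chrom = vapply(blocks, `[[`, character(1), "chrom"),
      start = vapply(blocks, `[[`, integer(1), "start_pos"),
      end = vapply(blocks, `[[`, integer(1), "end_pos"),
      marker_type = "haplotype")
    for (i in seq_along(blocks)) {
      genos[[ids[i]]] <- as.character(blocks[[i]]$labels)
      names(genos[[ids[i]]]) <- names(blocks[[i]]$labels)
      cc <- blocks[[i]]$consensus
      cons[[ids[i]]] <- stats::setNames(cc, as.character(seq_along(cc)))
    }
  }
  if (!is.null(cnvrs)) {
    r <- cnvrs$regions
    tabs$cnvrs <- data.frame(marker_id = r$cnvr_id, chrom = r$chrom,
                             start = r$start, end = r$end,
                             marker_type = "cnvr")
    for (j in seq_len(nrow(r))) {
      genos[[r$cnvr_id[j]]] <-
        stats::setNames(as.character(cnvrs$genotype[, r$cnvr_id[j]]),
                        rownames(cnvrs$genotype))
    }
  }
  list(table = do.call(rbind, tabs), genotypes = genos, consensus = cons)
}

#' Flag the most significant association per expression trait
#'
#' Within each probe, the record with the minimum permutation p-value is
#' flagged; ties are broken by the larger F statistic, then by the
#' lexicographically smallest marker id.
#'
#' @param records data.frame of eQTL records with `probe_id`, `marker_id`,
#'   `F_stat`, `p_perm`.
#' @return the same data.frame with a logical `is_best_for_trait` column.
#' @export
select_best_per_trait <- function(records) {
  records$is_best_for_trait <- FALSE
  for (p in unique(records$probe_id)) {
    i <- which(records$probe_id == p)
    o <- i[order(records$p_perm[i], -records$F_stat[i], records$marker_id[i])]
    records$is_best_for_trait[o[1]] <- TRUE
  }
  records
}

#' Map cis-eQTLs against haplotype blocks and CNVR genotypes
#'
#' For every probe-marker pair within the cis window, tests the per-strain
#' mean expression against the marker genotype factor ([marker_association],
#' singleton genotype classes merged into the nearest class first) and
#' computes a relatedness-weighted permutation p-value
#' ([weighted_permutation_p]). The most significant marker per trait is
#' flagged and a record is called significant when its permutation p falls
#' below `alpha`.
#'
#' @param expr an [expression_matrix].
#' @param probe_positions data.frame with `probe_id`, `chrom`, `pos`.
#' @param blocks haplotype blocks from [build_blocks] (optional).
#' @param cnvrs a [cnvr_set] (optional).
#' @param geno [genotype_matrix] used for kinship weights (required when
#'   `weights = "kinship"`).
#' @param window_bp cis window (default 2 Mb).
#' @param n_perm permutations per test (default 1000).
#' @param weights `"kinship"` or `"uniform"`.
#' @param alpha significance threshold (default 0.05).
#' @param significance `"bh"` (default) calls a trait eQTL-linked when the
#'   Benjamini-Hochberg-adjusted permutation p of its best marker falls
#'   below `alpha`, controlling the FDR across the traits tested;
#'   `"nominal"` thresholds each record's raw permutation p.
#' @param seed RNG seed.
#' @return data.frame of eQTL records: `probe_id`, `marker_id`,
#'   `marker_type`, `F_stat`, `p_nominal`, `p_perm`, `is_best_for_trait`,
#'   `significant`.
#' @export
map_cis_eqtls <- function(expr, probe_positions, blocks = NULL, cnvrs = NULL,
                          geno = NULL, window_bp = 2e6, n_perm = 1000,
                          weights = c("kinship", "uniform"), alpha = 0.05,
                          significance = c("bh", "nominal"), seed = 1L) {
  weights <- match.arg(weights)
  significance <- match.arg(significance)
  w <- NULL
  if (weights == "kinship") {
    if (is.null(geno)) stop("kinship weights require `geno`")
    w <- compute_strain_weights(geno)
  }
  ms <- marker_set(blocks, cnvrs)
  probe_positions <- probe_positions[probe_positions$probe_id %in%
                                       rownames(expr$values), , drop = FALSE]
  cand <- cis_candidates(probe_positions, ms$table, window_bp)
  if (!nrow(cand)) {
    return(data.frame(probe_id = character(0), marker_id = character(0),
                      marker_type = character(0), F_stat = numeric(0),
                      p_nominal = numeric(0), p_perm = numeric(0),
                      is_best_for_trait = logical(0), significant = logical(0)))
  }
  sm <- strain_means(expr, unique(cand$probe_id))
  recs <- list()
  for (i in seq_len(nrow(cand))) {
    pid <- cand$probe_id[i]
    mid <- cand$marker_id[i]
    gt <- merge_singleton_classes(ms$genotypes[[mid]], ms$consensus[[mid]])
    tab <- table(gt[!is.na(gt)])
    if (length(tab) < 2L || any(tab < 2L)) next
    trait <- sm$means[pid, ]
    assoc <- marker_association(trait, gt)
    if (is.null(assoc)) next
    pp <- weighted_permutation_p(trait, gt, w, n_perm = n_perm,
                                 seed = seed + i)
    recs[[length(recs) + 1L]] <- data.frame(
      probe_id = pid, marker_id = mid,
      marker_type = ms$table$marker_type[ms$table$marker_id == mid],
      F_stat = assoc$F_stat, p_nominal = assoc$p_nominal, p_perm = pp)
  }
  if (!length(recs)) {
    return(data.frame(probe_id = character(0), marker_id = character(0),
                      marker_type = character(0), F_stat = numeric(0),
                      p_nominal = numeric(0), p_perm = numeric(0),
                      is_best_for_trait = logical(0), significant = logical(0)))
  }
  out <- select_best_per_trait(do.call(rbind, recs))
  out$q_perm <- NA_real_
  out$q_perm[out$is_best_for_trait] <-
    stats::p.adjust(out$p_perm[out$is_best_for_trait], method = "BH")
  out$significant <- if (significance == "bh") {
    out$is_best_for_trait & out$q_perm < alpha
  } else {
    out$p_perm < alpha
  }
  rownames(out) <- NULL
  out
}

#' Validate anchor cis-eQTLs in a recombinant inbred panel
#'
#' For each anchor and each RI expression compartment, every SNP within
#' `window_bp` of the anchor's gene position is tested as a genotype factor
#' against the anchor's expression; p-values are Holm-adjusted within each
#' anchor-compartment family, and the anchor is validated when any adjusted
#' p falls below `alpha` in at least one compartment.
#'
#' @param anchor_positions data.frame with `probe_id`, `chrom`, `pos` for
#'   the anchors.
#' @param ri_geno RI-line [genotype_matrix].
#' @param ri_expr named list of RI [expression_matrix] objects, one per
#'   hematopoietic compartment (a single matrix is also accepted).
#' @param window_bp cis window (default 2 Mb).
#' @param alpha Holm-adjusted significance threshold (default 0.05).
#' @return list with `detail` (per anchor x compartment: markers tested,
#'   minimum Holm-adjusted p, validated flag) and `anchors` (per anchor:
#'   validated in any compartment, untestable flag).
#' @export
validate_in_ri <- function(anchor_positions, ri_geno, ri_expr,
                           window_bp = 2e6, alpha = 0.05) {
  if (inherits(ri_expr, "expression_matrix")) ri_expr <- list(RI = ri_expr)
  detail <- list()
  for (comp in names(ri_expr)) {
    ex <- ri_expr[[comp]]
    present <- intersect(anchor_positions$probe_id, rownames(ex$values))
    sm <- if (length(present)) strain_means(ex, present) else NULL
    for (i in seq_len(nrow(anchor_positions))) {
      a <- anchor_positions[i, ]
      if (!(a$probe_id %in% present)) {
        detail[[length(detail) + 1L]] <- data.frame(
          probe_id = a$probe_id, compartment = comp, n_markers = 0L,
          min_p_holm = NA_real_, validated = NA)
        next
      }
      snps <- which(ri_geno$chrom == a$chrom &
                      abs(ri_geno$pos - a$pos) <= window_bp)
      trait <- sm$means[a$probe_id, ]
      pvals <- numeric(0)
      for (s in snps) {
        gt <- stats::setNames(ri_geno$alleles[, s],
                              rownames(ri_geno$alleles))
        assoc <- marker_association(trait, gt)
        if (!is.null(assoc)) pvals <- c(pvals, assoc$p_nominal)
      }
      if (!length(pvals)) {
        detail[[length(detail) + 1L]] <- data.frame(
          probe_id = a$probe_id, compartment = comp, n_markers = 0L,
          min_p_holm = NA_real_, validated = FALSE)
        next
      }
      holm <- stats::p.adjust(pvals, method = "holm")
      detail[[length(detail) + 1L]] <- data.frame(
        probe_id = a$probe_id, compartment = comp,
        n_markers = length(pvals), min_p_holm = min(holm),
        validated = min(holm) < alpha)
    }
  }
  detail <- do.call(rbind, detail)
  anchors <- do.call(rbind, lapply(unique(detail$probe_id), function(p) {
    d <- detail[detail$probe_id == p, ]
    data.frame(probe_id = p,
               untestable = all(is.na(d$validated)),
               validated = isTRUE(any(d$validated, na.rm = TRUE)))
  }))
  list(detail = detail, anchors = anchors)
}
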