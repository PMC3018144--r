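# Haplotype-block construction for panels of inbred strains.
#
# SNPs are grown left-to-right into blocks; within a candidate block,
# strains are clustered into 2..6 haplotype groups (PAM on the unnormalized
# SNP-difference distance, cluster count chosen by maximum average
# silhouette), a consensus haplotype string is derived per group as the
# modal allele at each position, and the block is accepted while the
# consensus predicts every typed genotype with at most `max_errors`
# mistakes in total.

#' Filter SNPs to the informative set
#'
#' Drops SNPs that fall inside a CNVR, have minor allele frequency below
#' `maf_min` (computed over typed strains; the minor-allele frequency of a
#' multi-allelic site is one minus the major-allele frequency), or are
#' untyped in `max_missing_frac` or more of the strains (the threshold is
#' inclusive: a SNP missing in exactly 25% of strains is dropped at the
#' default). SNP order is preserved.
#'
#' @param geno a [genotype_matrix].
#' @param cnvrs optional [cnvr_set]; SNPs inside any region are dropped.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing_frac missing fraction at or above which a SNP is
#'   dropped (default 0.25).
#' @return A filtered [genotype_matrix].
#' @export
filter_informative <- function(geno, cnvrs = NULL, maf_min = 0.05,
                               max_missing_frac = 0.25) {
  al <- geno$alleles
  n_str <- nrow(al)
  miss_frac <- colMeans(is.na(al))
  maf <- apply(al, 2, function(a) {
    a <- a[!is.na(a)]
    if (!length(a)) return(0)
    1 - max(table(a)) / length(a)
  })
  in_cnvr <- rep(FALSE, ncol(al))
  if (!is.null(cnvrs)) {
    for (i in seq_len(nrow(cnvrs$regions))) {
      r <- cnvrs$regions[i, ]
      in_cnvr <- in_cnvr |
        (geno$chrom == r$chrom & geno$pos >= r$start & geno$pos <= r$end)
    }
  }
  keep <- !in_cnvr & maf >= maf_min & miss_frac < max_missing_frac
  if (!any(keep)) stop("no informative SNPs")
  geno_subset(geno, which(keep))
}

#' Pairwise SNP-based strain distances
#'
#' Unnormalized mode counts, for each strain pair, positions typed in both
#' strains where the alleles differ (the distance used inside block
#' building). Normalized mode divides that count by the number of positions
#' typed in both strains (the distance used for global strain clustering).
#'
#' @param geno a [genotype_matrix], or a strains x SNPs character matrix
#'   with `NA` for untyped calls.
#' @param strains_subset optional character vector restricting the strains.
#' @param normalized logical; divide by co-typed SNP count.
#' @return Symmetric strain x strain distance matrix with zero diagonal.
#' @export
strain_snp_distance <- function(geno, strains_subset = NULL,
                                normalized = FALSE) {
  al <- if (inherits(geno, "genotype_matrix")) geno$alleles else geno
  if (!is.null(strains_subset)) al <- al[strains_subset, , drop = FALSE]
  n <- nrow(al)
  if (n < 2L) stop("need at least 2 strains")
  typed <- !is.na(al)
  # pairwise differences via cross-products: co-typed count minus the
  # count of co-typed equal positions, accumulated per allele character
  cotyped <- tcrossprod(typed * 1)
  eq <- matrix(0, n, n)
  for (v in sort(unique(as.vector(al[typed])))) {
    m <- (typed & al == v) * 1
    eq <- eq + tcrossprod(m)
  }
  d <- cotyped - eq
  off <- cotyped == 0 & !diag(TRUE, n)
  if (any(off)) {
    if (normalized) {
      ij <- which(off, arr.ind = TRUE)[1, ]
      stop("strains ", rownames(al)[ij[1]], " and ", rownames(al)[ij[2]],
           " share no typed SNPs; normalized distance undefined")
    }
    warning("strain pair(s) with no co-typed SNPs; unnormalized distance set to 0")
  }
  if (normalized) {
    d <- d / pmax(cotyped, 1L)
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(al), rownames(al))
  d
}

# Haplotype grouping of strains typed at exactly one SNP: strains sharing
# an allele share a haplotype, so the consensus is exact and error-free.
single_snp_grouping <- function(allele_col) {
  typed <- !is.na(allele_col)
  labels <- rep(NA_integer_, length(allele_col))
  names(labels) <- names(allele_col)
  consensus <- character(0)
  if (any(typed)) {
    lev <- sort(unique(allele_col[typed]))
    labels[typed] <- match(allele_col[typed], lev)
    consensus <- lev
  }
  list(labels = labels, consensus = consensus, k = length(consensus),
       error_count = 0L, mean_silhouette = NA_real_)
}

# modal allele per column among rows of `al`; ties broken by the
# lexicographically smallest allele; all-NA column -> NA
consensus_string <- function(al) {
  typed <- !is.na(al)
  vals <- sort(unique(as.vector(al[typed])))
  if (!length(vals)) return(rep(NA_character_, ncol(al)))
  cnt <- vapply(vals, function(v) colSums(typed & al == v),
                numeric(ncol(al)))
  cnt <- matrix(cnt, ncol = length(vals))
  out <- vals[max.col(cnt, ties.method = "first")]  # vals sorted ascending
  out[rowSums(cnt) == 0L] <- NA_character_
  out
}

# mismatch counts of every row of `alt` against every consensus row:
# comparable positions (both typed) minus co-typed equal positions;
# NA where nothing is comparable
mismatch_matrix <- function(alt, consm) {
  tn <- !is.na(alt)
  tk <- !is.na(consm)
  comp <- (tn * 1) %*% t(tk * 1)
  eq <- matrix(0, nrow(alt), nrow(consm))
  for (v in sort(unique(as.vector(alt[tn])))) {
    eq <- eq + ((tn & alt == v) * 1) %*% t((tk & consm == v) * 1)
  }
  mm <- comp - eq
  mm[comp == 0] <- NA_real_
  mm
}

count_consensus_errors <- function(al, labels, consensus_mat) {
  errs <- 0L
  for (h in seq_len(nrow(consensus_mat))) {
    members <- which(!is.na(labels) & labels == h)
    if (!length(members)) next
    sub <- al[members, , drop = FALSE]
    cons <- matrix(consensus_mat[h, ], nrow(sub), ncol(sub), byrow = TRUE)
    errs <- errs + sum(!is.na(sub) & !is.na(cons) & sub != cons)
  }
  errs
}

# Deterministic second initialization for k haplotype clusters: the k most
# frequent fully-typed allele patterns act as seed haplotypes and every
# strain joins the seed it mismatches least. Catches partitions that PAM's
# BUILD/swap misses when missing calls create zero-information distances.
modal_pattern_start <- function(alt, k) {
  full <- rowSums(is.na(alt)) == 0L
  if (sum(full) < k) return(NULL)
  pats <- apply(alt[full, , drop = FALSE], 1, paste, collapse = "")
  tab <- sort(table(pats), decreasing = TRUE)
  if (length(tab) < k) return(NULL)
  seeds <- do.call(rbind, strsplit(names(tab)[seq_len(k)], ""))
  mm <- mismatch_matrix(alt, seeds)
  cl <- max.col(-mm, ties.method = "first")
  match(cl, sort(unique(cl)))
}

# Refine a clustering against its own consensus: each typed strain joins
# the consensus haplotype it mismatches least (ties keep its current
# cluster), then consensus strings are re-derived; iterate to a fixed
# point. Under missing data the pairwise distance can be uninformative
# for a sparsely typed strain (zero co-typed positions with a medoid)
# while its match against the consensus strings — the quantity the block
# error rule is actually about — stays well defined.
refine_labels <- function(alt, cl) {
  consensus_of <- function(cl, k) {
    consm <- matrix(NA_character_, k, ncol(alt))
    for (h in seq_len(k)) {
      if (any(cl == h)) consm[h, ] <- consensus_string(alt[cl == h, , drop = FALSE])
    }
    consm
  }
  for (iter in 1:4) {
    k <- max(cl)
    consm <- consensus_of(cl, k)
    mm <- mismatch_matrix(alt, consm)
    new_cl <- vapply(seq_len(nrow(alt)), function(i) {
      if (all(is.na(mm[i, ]))) return(cl[i])
      best_h <- which(mm[i, ] == min(mm[i, ], na.rm = TRUE))
      if (cl[i] %in% best_h) cl[i] else best_h[1]
    }, integer(1))
    if (identical(new_cl, cl)) break
    cl <- match(new_cl, sort(unique(new_cl)))  # drop emptied clusters
  }
  k <- max(cl)
  consm <- consensus_of(cl, k)
  list(cl = cl, consm = consm,
       error_count = count_consensus_errors(alt, cl, consm))
}

#' Assign haplotype labels within a candidate block
#'
#' Clusters strains by the unnormalized SNP-difference distance with
#' Partitioning Around Medoids for each cluster count in `k_range`, keeps
#' the clustering with the maximum average silhouette (ties go to the
#' smallest k; a singleton cluster contributes silhouette 0), derives one
#' consensus haplotype per cluster as the modal allele at each position
#' (ties to the lexicographically smallest allele), and counts how many
#' typed genotypes the consensus fails to predict.
#'
#' Strains untyped at every SNP of the block receive a missing label and do
#' not participate in clustering or error counting. The cluster count is
#' capped at the number of distinct observed genotype patterns (and at one
#' less than the number of typed strains, the PAM maximum); when no k >= 2
#' is feasible all typed strains form a single haplotype.
#'
#' @param block_alleles strains x SNPs character matrix (>= 2 SNPs), `NA`
#'   for untyped calls.
#' @param k_range integer candidate haplotype counts (default 2:6).
#' @return list with `labels` (named integer, `NA` = untyped strain),
#'   `consensus` (character vector of haplotype strings), `k`,
#'   `error_count`, `mean_silhouette`.
#' @export
assign_haplotypes <- function(block_alleles, k_range = 2:6) {
  al <- block_alleles
  stopifnot(is.matrix(al), ncol(al) >= 2L)
  labels <- rep(NA_integer_, nrow(al))
  names(labels) <- rownames(al)
  typed_any <- rowSums(!is.na(al)) > 0L
  alt <- al[typed_any, , drop = FALSE]
  pat <- apply(alt, 1, function(a) paste(ifelse(is.na(a), ".", a), collapse = ""))
  k_cap <- min(max(k_range), length(unique(pat)), nrow(alt) - 1L)
  ks <- k_range[k_range <= k_cap]
  if (length(ks) == 0L || nrow(alt) < 2L) {
    # degenerate: one haplotype covers all typed strains
    labels[typed_any] <- 1L
    cons <- consensus_string(alt)
    consm <- matrix(cons, 1L, ncol(al))
    return(list(labels = labels,
                consensus = paste(ifelse(is.na(cons), "?", cons), collapse = ""),
                k = 1L,
                error_count = count_consensus_errors(alt, labels[typed_any], consm),
                mean_silhouette = 0))
  }
  d <- strain_snp_distance(alt)
  best <- NULL
  for (k in ks) {
    fit <- cluster::pam(d, k = k, diss = TRUE)
    ref <- refine_labels(alt, fit$clustering)
    alt_start <- modal_pattern_start(alt, k)
    if (!is.null(alt_start)) {
      ref2 <- refine_labels(alt, alt_start)
      if (ref2$error_count < ref$error_count) ref <- ref2
    }
    sil <- if (max(ref$cl) < 2L) 0 else
      mean(cluster::silhouette(ref$cl, dmatrix = d)[, "sil_width"])
    if (is.null(best) || sil > best$sil + 1e-12) {
      best <- c(ref, list(sil = sil))
    }
  }
  cl <- best$cl
  consm <- best$consm
  k <- max(cl)
  labels[typed_any] <- cl
  list(labels = labels,
       consensus = apply(consm, 1, function(s)
         paste(ifelse(is.na(s), "?", s), collapse = "")),
       k = k,
       error_count = count_consensus_errors(alt, cl, consm),
       mean_silhouette = best$sil)
}

finalize_block <- function(geno, snp_idx, res, block_id) {
  list(block_id = block_id,
       chrom = geno$chrom[snp_idx[1]],
       snp_start = snp_idx[1], snp_end = snp_idx[length(snp_idx)],
       start_pos = geno$pos[snp_idx[1]],
       end_pos = geno$pos[snp_idx[length(snp_idx)]],
       length_bp = geno$pos[snp_idx[length(snp_idx)]] - geno$pos[snp_idx[1]] + 1L,
       n_snps = length(snp_idx),
       k = as.integer(res$k),
       labels = res$labels,
       consensus = as.character(res$consensus),
       error_count = as.integer(res$error_count),
       mean_silhouette = res$mean_silhouette)
}

#' Grow haplotype blocks along each chromosome
#'
#' Greedy left-to-right block growth: starting from a single SNP (whose
#' haplotypes are exact genotype groups), the next consecutive SNP is
#' appended and [assign_haplotypes] re-run; when the best consensus makes
#' more than `max_errors` prediction errors, the most recently added SNP is
#' removed, the stored result of the previous iteration becomes the
#' finalized block, and a new block starts at the offending SNP. Blocks
#' therefore tile the informative SNPs of each chromosome contiguously and
#' every emitted block satisfies the error bound.
#'
#' @param geno a [genotype_matrix], normally pre-filtered with
#'   [filter_informative].
#' @param max_errors maximum consensus prediction errors per block
#'   (default 1).
#' @param k_range candidate haplotype counts per block (default 2:6;
#'   single-SNP blocks instead use exact genotype groups, whose count may
#'   exceed the range).
#' @return list of haplotype blocks; each has `block_id`, `chrom`,
#'   `snp_start`/`snp_end` (column indices into `geno`), `start_pos`/
#'   `end_pos`, `length_bp`, `n_snps`, `k`, named per-strain `labels`,
#'   `consensus` strings, `error_count` and `mean_silhouette`.
#' @export
build_blocks <- function(geno, max_errors = 1, k_range = 2:6) {
  blocks <- list()
  bid <- 0L
  for (cc in unique(geno$chrom)) {
    idx <- which(geno$chrom == cc)
    start <- 1L
    prev <- single_snp_grouping(geno$alleles[, idx[1]])
    j <- 2L
    while (j <= length(idx)) {
      res <- assign_haplotypes(geno$alleles[, idx[start:j], drop = FALSE],
                               k_range = k_range)
      if (res$error_count > max_errors) {
        bid <- bid + 1L
        blocks[[bid]] <- finalize_block(geno, idx[start:(j - 1L)], prev, bid)
        start <- j
        prev <- single_snp_grouping(geno$alleles[, idx[j]])
      } else {
        prev <- res
      }
      j <- j + 1L
    }
    bid <- bid + 1L
    blocks[[bid]] <- finalize_block(geno, idx[start:length(idx)], prev, bid)
  }
  blocks
}

#' Pooled multi-allelic R-squared between a haplotype block and a CNVR
#'
#' The linkage between a multi-allelic haplotype system and a copy-number
#' genotype is summarized as the haplotype-frequency-weighted average of
#' squared Pearson correlations between each haplotype's indicator variable
#' and the copy-number genotype: sum_h p_h * r^2_h. Copy-number classes are
#' unordered, so r^2_h is taken against the indicator of the copy-number
#' class the haplotype tags best (for a biallelic haplotype system and a
#' two-class CNVR this is the classical r^2, and haplotype labels that
#' coincide with the copy-number classes give exactly 1). Strains missing
#' either value are excluded; tiny negative round-off is clamped to zero.
#'
#' @param block_labels named integer haplotype labels per strain.
#' @param cnvr_genotype named integer copy-number class per strain.
#' @return pooled R-squared in \[0, 1\].
#' @export
pooled_r2 <- function(block_labels, cnvr_genotype) {
  shared <- intersect(names(block_labels), names(cnvr_genotype))
  lab <- block_labels[shared]
  cn <- cnvr_genotype[shared]
  ok <- !is.na(lab) & !is.na(cn)
  lab <- lab[ok]; cn <- cn[ok]
  if (length(lab) < 2L) stop("need >= 2 strains typed for both block and CNVR")
  if (length(unique(cn)) < 2L) {
    warning("monomorphic CNVR genotype; pooled R^2 set to 0")
    return(0)
  }
  haps <- sort(unique(lab))
  if (length(haps) < 2L) {
    warning("single haplotype among co-typed strains; pooled R^2 set to 0")
    return(0)
  }
  cn_classes <- sort(unique(cn))
  r2 <- 0
  for (h in haps) {
    ind <- as.numeric(lab == h)
    p_h <- mean(ind)
    r2_h <- max(vapply(cn_classes, function(cc) {
      ic <- as.numeric(cn == cc)
      if (stats::sd(ic) == 0) return(0)
      stats::cor(ind, ic)^2
    }, numeric(1)))
    r2 <- r2 + p_h * r2_h
  }
  min(max(r2, 0), 1)
}

#' Tag CNVRs with nearby haplotype blocks
#'
#' For each CNVR, candidate blocks are those on the same chromosome whose
#' interval lies within `window_bp` of the CNVR (the minimum gap between
#' the two intervals, an overlap counting as distance 0). The block with the
#' maximum pooled R-squared is reported and the CNVR is called tagged when
#' that value strictly exceeds `r2_threshold`.
#'
#' @param blocks list of blocks from [build_blocks].
#' @param cnvrs a [cnvr_set].
#' @param window_bp candidate window around each CNVR (default 250000).
#' @param r2_threshold tagging threshold, strict (default 0.80).
#' @return data.frame with `cnvr_id`, `best_block_id`, `pooled_r2`,
#'   `tagged`; CNVRs with no candidate block get `NA` block and R-squared.
#' @export
tag_cnvrs <- function(blocks, cnvrs, window_bp = 250000, r2_threshold = 0.80) {
  out <- lapply(seq_len(nrow(cnvrs$regions)), function(i) {
    r <- cnvrs$regions[i, ]
    cn <- cnvrs$genotype[, r$cnvr_id]
    best_r2 <- NA_real_
    best_id <- NA_integer_
    if (length(unique(cn[!is.na(cn)])) < 2L) {
      warning("monomorphic CNVR genotype for ", r$cnvr_id, "; not taggable")
      return(data.frame(cnvr_id = r$cnvr_id, best_block_id = best_id,
                        pooled_r2 = best_r2, tagged = FALSE))
    }
    for (b in blocks) {
      if (b$chrom != r$chrom) next
      gap <- max(0, b$start_pos - r$end, r$start - b$end_pos)
      if (gap > window_bp) next
      if (b$k < 2L) next
      r2 <- suppressWarnings(pooled_r2(b$labels, cn))
      if (is.na(best_r2) || r2 > best_r2) {
        best_r2 <- r2
        best_id <- b$block_id
      }
    }
    data.frame(cnvr_id = r$cnvr_id, best_block_id = best_id,
               pooled_r2 = best_r2,
               tagged = !is.na(best_r2) && best_r2 > r2_threshold)
  })
  do.call(rbind, out)
}
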