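# Synthetic strain panels with planted ground truth.
#
# The generator emulates the structure the pipeline is built to recover:
# genomes are mosaics of ancestral haplotype blocks shared among inbred
# strains; CNVRs sit in or out of linkage with those blocks; expression
# arrays carry planted cis effects at anchor genes, trans effects from
# anchors onto targets, and a strain phenotype driven by a latent
# susceptibility bipartition that the anchor loci refine.

# number of classes in the common refinement of two partitions
refinement_size <- function(a, b) length(unique(paste(a, b)))

# random assignment of strains to n_cls ancestral classes, every class
# holding >= min_cls strains (>= 2, and enough that any class-group split
# clears the minor allele frequency floor)
random_assignment <- function(n_strains, n_cls, min_cls = 2L) {
  if (floor(n_strains / n_cls) < min_cls) {
    stop("cannot hold every ancestral class at >= ", min_cls, " strains")
  }
  # balanced classes: a spurious merge of two classes then costs the most
  # consensus errors and has the weakest silhouette
  sample(rep_len(seq_len(n_cls), n_strains))
}

# assignment that refines the susceptibility bipartition: classes
# 1..(n_cls/2) live on side 0, the rest on side 1
refining_assignment <- function(side, n_cls, min_cls = 2L) {
  lo <- seq_len(floor(n_cls / 2))
  hi <- setdiff(seq_len(n_cls), lo)
  if (min(floor(sum(side == 0L) / length(lo)), floor(sum(side == 1L) / length(hi))) < min_cls) {
    stop("cannot hold every ancestral class at >= ", min_cls, " strains")
  }
  a <- integer(length(side))
  a[side == 0L] <- sample(rep_len(lo, sum(side == 0L)))
  a[side == 1L] <- sample(rep_len(hi, sum(side == 1L)))
  a
}

# ancestral allele patterns for one block: k classes x len SNPs, biallelic
# per SNP. Classes are given binary codes (randomly permuted per block);
# the first ceil(log2(k)) SNPs lay the code bits down in order, so the k
# consensus strings are guaranteed distinct, and later SNPs draw from the
# code bits plus their parity. Appending the parity bit makes every pair
# of class codes differ on at least 2 of the available bipartitions, so
# all pairwise class distances keep growing with block length — haplotypes
# stay separable in every window even under missing data.
block_patterns <- function(n_cls, len, codes = sample.int(2^max(1L, ceiling(log2(n_cls))), n_cls) - 1L,
                           exclude_split = NULL) {
  bases <- c("A", "C", "G", "T")
  n_code <- max(1L, ceiling(log2(n_cls)))
  stopifnot(len >= n_code)
  same_split <- function(a, b) identical(a, b) || identical(a, !b)
  splits <- lapply(seq_len(n_code), function(b)
    bitwAnd(codes, bitwShiftL(1L, b - 1L)) > 0L)
  if (n_code > 1L) {
    parity <- Reduce(`+`, splits) %% 2L == 1L
    if (any(parity) && !all(parity) &&
        (is.null(exclude_split) || !same_split(parity, exclude_split))) {
      splits <- c(splits, list(parity))
    }
  }
  # head: the code bits in order (distinctness), then the parity split —
  # once the parity SNP is laid down every class pair differs at >= 2
  # SNPs (the extended code has minimum distance 2), so clusters stay
  # separable under sporadic missing calls
  order_head <- seq_len(length(splits))
  # after the head, cycle through the splits in order: every class pair
  # then separates at exactly 2 of any 3 consecutive SNPs (no weak runs)
  order_full <- c(order_head,
                  rep_len(seq_len(length(splits)), max(0L, len - length(order_head))))
  pat <- matrix(NA_character_, n_cls, len)
  for (j in seq_len(len)) {
    ab <- sample(bases, 2L)
    pat[, j] <- ifelse(splits[[order_full[j]]], ab[1], ab[2])
  }
  pat
}

#' Simulate a genotyped inbred strain panel with planted haplotype blocks
#'
#' The simulated genome is a concatenation of haplotype blocks. Within a
#' block each strain carries one of `n_ancestral` consensus strings (each
#' ancestral class held by at least two strains, so every SNP's minor
#' allele frequency is at least 2/`n_strains`); per-cell mutations at
#' `mutation_rate` and missing calls at `missing_rate` are then overlaid so
#' the bounded-error block rule is actually exercised. Adjacent blocks are
#' given strain assignments whose common refinement has more than six
#' classes, which makes the planted boundaries identifiable under the
#' 2-6-haplotype clustering cap. `n_susceptibility_blocks` of the blocks
#' refine a latent balanced susceptibility bipartition of the strains;
#' [simulate_expression] later places its phenotype-linked anchors there.
#'
#' CNVRs are generated in two classes: LD-linked regions whose copy-number
#' class is a deterministic relabelling of the local block's ancestral
#' assignment, and LD-free regions with copy numbers independent of any
#' haplotype. Regions are placed in the gaps between SNPs so they never
#' swallow an informative SNP.
#'
#' @param n_strains number of strains (>= 2 * `n_ancestral`; default 20).
#' @param n_snps number of SNPs across the genome (default 120).
#' @param n_ancestral ancestral haplotypes per block, in 2..6 (default 4).
#' @param mean_block_len mean SNPs per planted block (default 6).
#' @param missing_rate per-cell probability of an untyped call
#'   (default 0.05; must be < 0.25).
#' @param maf_min minimum minor allele frequency the construction must be
#'   able to guarantee (default 0.05).
#' @param mutation_rate per-cell probability of a discordant allele
#'   (default 0.005).
#' @param n_cnvr number of CNVRs, half LD-linked (default 8).
#' @param n_chrom number of chromosomes (default 2).
#' @param n_susceptibility_blocks blocks refining the susceptibility
#'   bipartition (default 5).
#' @param seed RNG seed.
#' @return list with `geno` (a [genotype_matrix]), `cnvrs` (a [cnvr_set])
#'   and `truth` (planted block boundaries, per-SNP block index, ancestral
#'   assignments, consensus patterns, clean alleles, susceptibility sides,
#'   CNVR linkage flags, seed and parameters).
#' @export
simulate_panel <- function(n_strains = 20, n_snps = 120, n_ancestral = 4,
                           mean_block_len = 6, missing_rate = 0.05,
                           maf_min = 0.05, mutation_rate = 0.005,
                           n_cnvr = 8, n_chrom = 5,
                           n_susceptibility_blocks = 5, seed = 1L) {
  stopifnot(n_ancestral >= 2, n_ancestral <= 6,
            missing_rate >= 0, missing_rate < 0.25)
  min_cls <- max(2L, as.integer(ceiling(maf_min * n_strains)))
  if (n_strains < min_cls * n_ancestral) {
    stop("cannot hold every ancestral class at >= ", min_cls,
         " strains (the MAF floor) with ", n_strains, " strains; ",
         "all SNPs would fall below maf_min")
  }
  set.seed(seed)
  strains <- sprintf("S%02d", seq_len(n_strains))
  min_len <- max(2L, 2L * ceiling(log2(n_ancestral)))

  # block lengths tiling n_snps
  lens <- integer(0)
  while (sum(lens) < n_snps) {
    lens <- c(lens, min_len + stats::rpois(1, max(mean_block_len - min_len, 0.5)))
  }
  excess <- sum(lens) - n_snps
  lens[length(lens)] <- lens[length(lens)] - excess
  if (lens[length(lens)] < min_len) {
    lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  n_blocks <- length(lens)

  # contiguous split of blocks over chromosomes
  chrom_of_block <- sort(rep_len(seq_len(n_chrom), n_blocks))
  block_end <- cumsum(lens)
  block_start <- block_end - lens + 1L
  snp_block <- rep(seq_len(n_blocks), lens)
  chrom <- paste0("chr", chrom_of_block[snp_block])
  pos <- integer(n_snps)
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    pos[i] <- cumsum(sample(10000:15000, length(i), replace = TRUE))
  }

  # Latent susceptibility bipartition (balanced). The blocks refining it —
  # the loci where phenotype-linked anchors will sit — are placed one per
  # chromosome (the middle block), so that in a recombinant inbred cross
  # they segregate independently and module trimming can tell the anchors'
  # target sets apart.
  side <- stats::setNames(rep(0:1, length.out = n_strains)[sample.int(n_strains)],
                          strains)
  n_sus <- min(n_susceptibility_blocks, n_chrom)
  sus_blocks <- vapply(seq_len(n_sus), function(cc) {
    bl <- which(chrom_of_block == cc)
    bl[ceiling(length(bl) / 2)]
  }, integer(1))

  # Per-block strain assignments and class codes. Planted boundaries are
  # identifiable only when merging two adjacent blocks cannot be done
  # within the 2-6 haplotype cap at <= 1 consensus error, so (for
  # n_ancestral >= 3) adjacent assignments must refine to > 6 joint
  # classes, and the leading bipartition of each block must split enough
  # of the previous block's classes, each side with >= 2 strains — a
  # one-SNP overshoot of the boundary then always costs > 1 error.
  n_code <- max(1L, ceiling(log2(n_ancestral)))
  assign <- matrix(0L, n_strains, n_blocks,
                   dimnames = list(strains, NULL))
  codes_list <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    ok <- FALSE
    for (try in 1:1000) {
      if (b %in% sus_blocks) {
        a <- refining_assignment(side, n_ancestral, min_cls)
        # Codes such that no single code bit reproduces the susceptibility
        # bipartition: every SNP of a susceptibility block then splits
        # classes from both sides, so no SNP (or short block fragment) is
        # phenotype-aligned on its own — the side signal lives only in the
        # full multi-SNP haplotype.
        lo_classes <- seq_len(floor(n_ancestral / 2))
        for (ctry in 1:200) {
          codes <- sample.int(2^n_code, n_ancestral) - 1L
          bit_sets <- lapply(seq_len(n_code), function(bb)
            which(bitwAnd(codes, bitwShiftL(1L, bb - 1L)) > 0L))
          side_like <- vapply(bit_sets, function(ss)
            setequal(ss, lo_classes) ||
              setequal(ss, setdiff(seq_len(n_ancestral), lo_classes)),
            logical(1))
          if (!any(side_like)) break
        }
      } else {
        a <- random_assignment(n_strains, n_ancestral, min_cls)
        codes <- sample.int(2^n_code, n_ancestral) - 1L
      }
      same_chrom <- b > 1L && chrom_of_block[b] == chrom_of_block[b - 1L]
      if (!same_chrom || n_ancestral < 3L) { ok <- TRUE; break }
      if (refinement_size(assign[, b - 1L], a) <= 6L) next
      if (n_ancestral < 4L) { ok <- TRUE; break }
      # cost for the grower to absorb this block's first SNP into the
      # previous block: with r refinement cells, merging down to <= 6
      # clusters costs >= 2 consensus errors iff r >= 8, or r == 7 with
      # every split class's smaller side >= 2
      b0_strain <- (bitwAnd(codes, 1L) > 0L)[a]
      pa <- assign[, b - 1L]
      nsplit <- 0L
      min_split <- Inf
      for (cc in unique(pa)) {
        n1 <- sum(b0_strain[pa == cc])
        n0 <- sum(pa == cc) - n1
        if (n0 > 0L && n1 > 0L) {
          nsplit <- nsplit + 1L
          min_split <- min(min_split, n0, n1)
        }
      }
      r <- length(unique(pa)) + nsplit
      if (r >= 8L || (r == 7L && min_split >= 2)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not plant an identifiable boundary before block ", b)
    assign[, b] <- a
    codes_list[[b]] <- codes
  }

  side_split <- seq_len(n_ancestral) > floor(n_ancestral / 2)
  patterns <- lapply(seq_len(n_blocks), function(b)
    block_patterns(n_ancestral, lens[b], codes_list[[b]],
                   exclude_split = if (b %in% sus_blocks) side_split))

  clean <- matrix(NA_character_, n_strains, n_snps,
                  dimnames = list(strains, NULL))
  for (b in seq_len(n_blocks)) {
    cols <- block_start[b]:block_end[b]
    clean[, cols] <- patterns[[b]][assign[, b], , drop = FALSE]
  }

  al <- clean
  mut <- matrix(stats::runif(length(al)) < mutation_rate, n_strains, n_snps)
  if (any(mut)) {
    bases <- c("A", "C", "G", "T")
    al[mut] <- vapply(al[mut], function(x) sample(setdiff(bases, x), 1L),
                      character(1))
  }
  miss <- matrix(stats::runif(length(al)) < missing_rate, n_strains, n_snps)
  # keep the container invariant: every SNP typed in >= 1 strain
  gone <- colSums(!miss) == 0L
  if (any(gone)) miss[1L, gone] <- FALSE
  al[miss] <- NA_character_

  geno <- genotype_matrix(chrom, pos, al)

  # CNVRs in the gaps between SNPs of a host block
  n_ld <- floor(n_cnvr / 2)
  # LD-linked regions stay off the susceptibility blocks: a copy number
  # tracking a phenotype-linked haplotype would cis-associate with every
  # phenotype-driven probe nearby, blurring planted anchor status
  non_sus <- setdiff(seq_len(n_blocks), sus_blocks)
  host <- c(sample(non_sus, n_ld, replace = n_ld > length(non_sus)),
            sample(seq_len(n_blocks), n_cnvr - n_ld,
                   replace = (n_cnvr - n_ld) > n_blocks))
  regions <- list()
  gt <- matrix(NA_integer_, n_strains, n_cnvr,
               dimnames = list(strains, NULL))
  for (i in seq_len(n_cnvr)) {
    b <- host[i]
    j <- sample(block_start[b]:(block_end[b] - 1L), 1L)
    start <- pos[j] + 1L
    end <- start + min(499L, pos[j + 1L] - pos[j] - 2L)
    regions[[i]] <- data.frame(cnvr_id = sprintf("CNVR%02d", i),
                               chrom = chrom[j], start = start, end = end)
    if (i <= n_ld) {
      gt[, i] <- assign[, b]  # copy number deterministically tracks haplotype
    } else {
      repeat {
        g <- sample(1:3, n_strains, replace = TRUE)
        if (length(unique(g)) >= 2L && min(table(g)) >= 2L) break
      }
      gt[, i] <- g
    }
  }
  regions <- do.call(rbind, regions)
  cnvrs <- cnvr_set(regions, gt)

  truth <- structure(list(
    seed = seed,
    params = list(n_strains = n_strains, n_snps = n_snps,
                  n_ancestral = n_ancestral, mean_block_len = mean_block_len,
                  missing_rate = missing_rate, mutation_rate = mutation_rate,
                  maf_min = maf_min, n_chrom = n_chrom),
    strains = strains,
    chrom = chrom, pos = pos,
    snp_block = snp_block,
    block_boundaries = data.frame(block = seq_len(n_blocks),
                                  chrom = paste0("chr", chrom_of_block),
                                  start_snp = block_start, end_snp = block_end,
                                  start_pos = pos[block_start],
                                  end_pos = pos[block_end]),
    ancestral_assignment = assign,
    consensus_patterns = patterns,
    clean_alleles = clean,
    sus_side = side,
    sus_blocks = sus_blocks,
    cnvr_truth = data.frame(cnvr_id = regions$cnvr_id,
                            ld_linked = seq_len(n_cnvr) <= n_ld,
                            block = host)),
    class = "sim_truth")
  list(geno = geno, cnvrs = cnvrs, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d strains, %d SNPs in %d planted blocks (seed %d)\n",
              x$params$n_strains, x$params$n_snps,
              nrow(x$block_boundaries), x$seed))
  invisible(x)
}

#' Simulate replicate expression arrays with planted cis and trans effects
#'
#' Anchor probes sit at the midpoints of planted blocks and receive a
#' genetic score: the per-class effect of the strain's ancestral haplotype
#' at that block, standardized across strains and scaled by `beta_cis`.
#' Phenotype-linked anchors use the susceptibility blocks of
#' [simulate_panel], whose class effects differ by bipartition side, so
#' those anchors are differentially expressed between the phenotype classes
#' as well as cis-linked — the two defining properties of an anchor.
#' Target probes follow their anchor's standardized genetic score with
#' coefficient `beta_trans` (sign random per target); remaining probes are
#' pure noise. Every array value gets independent Normal(0, `noise_sd`)
#' noise; detection calls are values above the global `det_quantile`
#' quantile; the phenotype is the deterministic bipartition side with
#' `n_unknown` strains masked as unknown.
#'
#' @param sim result of [simulate_panel] (or its `truth` element).
#' @param n_probes total probes (must cover anchors and targets;
#'   default 150).
#' @param replicates_per_strain biological replicate arrays per strain
#'   (>= 2; default 3).
#' @param noise_sd array-level noise standard deviation, log-expression
#'   units (default 0.5).
#' @param n_anchors planted anchors (default 5).
#' @param n_targets_per_anchor trans targets per anchor (default 20).
#' @param beta_cis cis effect size (default 2 * `noise_sd`).
#' @param beta_trans trans effect size (default 2 * `noise_sd`); 0 gives a
#'   null anchor-target structure.
#' @param n_unknown strains whose phenotype is masked as unknown
#'   (default 5, as in a panel where a quarter of strains lack phenotype).
#' @param det_quantile global quantile below which a value is called
#'   undetected (default 0.02).
#' @param cis_exclusion_bp non-anchor probes are placed at least this far
#'   from every anchor/susceptibility block interval (default 50000,
#'   matching the pipeline's cis window on this genome scale).
#' @param seed RNG seed.
#' @return list with `expr` (an [expression_matrix]), `panel` (a
#'   [strain_panel]) and `truth` (the input truth extended with probe
#'   positions, anchors, per-anchor target sets, genetic scores, effect
#'   sizes and the unmasked phenotype).
#' @export
simulate_expression <- function(sim, n_probes = 150,
                                replicates_per_strain = 3, noise_sd = 0.5,
                                n_anchors = 5, n_targets_per_anchor = 20,
                                beta_cis = 2 * noise_sd,
                                beta_trans = 2 * noise_sd,
                                n_unknown = 5, det_quantile = 0.02,
                                cis_exclusion_bp = 50000, seed = 1L) {
  truth <- if (inherits(sim, "sim_truth")) sim else sim$truth
  stopifnot(replicates_per_strain >= 2)
  if (n_probes < n_anchors * (1 + n_targets_per_anchor)) {
    stop("n_probes too small for ", n_anchors, " anchors with ",
         n_targets_per_anchor, " targets each")
  }
  set.seed(seed + 1000L)
  strains <- truth$strains
  n_str <- length(strains)
  bb <- truth$block_boundaries
  n_blocks <- nrow(bb)

  # anchor blocks: susceptibility blocks first, then other spaced blocks
  extra <- setdiff(seq_len(n_blocks), unlist(lapply(truth$sus_blocks,
                                                    function(b) (b - 1):(b + 1))))
  anchor_blocks <- c(truth$sus_blocks,
                     sample(extra, max(0, n_anchors - length(truth$sus_blocks))))
  anchor_blocks <- anchor_blocks[seq_len(min(n_anchors, length(anchor_blocks)))]
  n_anchors <- length(anchor_blocks)

  probe_ids <- sprintf("P%04d", seq_len(n_probes))
  anchors <- probe_ids[seq_len(n_anchors)]
  targets <- split(
    probe_ids[n_anchors + seq_len(n_anchors * n_targets_per_anchor)],
    rep(seq_len(n_anchors), each = n_targets_per_anchor))
  names(targets) <- anchors

  # genetic score per anchor: class effects at the anchor's block,
  # standardized across strains
  score <- matrix(0, n_anchors, n_str, dimnames = list(anchors, strains))
  for (i in seq_len(n_anchors)) {
    b <- anchor_blocks[i]
    a <- truth$ancestral_assignment[, b]
    n_cls <- max(a)
    if (b %in% truth$sus_blocks) {
      # class effects split by bipartition side (the anchor is strongly
      # differentially expressed) with clear within-side spread, so each
      # anchor also carries a component unique to its own locus — without
      # it all susceptibility modules would collapse into one
      lo <- seq_len(floor(n_cls / 2))
      n_lo <- length(lo)
      e <- numeric(n_cls)
      e[lo] <- seq(-1.5, -0.5, length.out = n_lo)
      e[-lo] <- seq(0.5, 1.5, length.out = n_cls - n_lo)
      e <- e + stats::rnorm(n_cls, 0, 0.1)
    } else {
      e <- stats::rnorm(n_cls)
    }
    g <- e[a]
    score[i, ] <- (g - mean(g)) / stats::sd(g)
  }

  # Probe positions: every probe at the midpoint of some block; anchors at
  # their own cis block. Non-anchor probes are kept more than
  # `cis_exclusion_bp` away from every anchor/susceptibility block
  # interval, so that planted anchor status stays unambiguous: a
  # phenotype-driven target within cis reach of a phenotype-linked locus
  # (or of a fragment of one) would be genuinely cis-associated and
  # indistinguishable from an anchor.
  bb_mid <- (bb$start_pos + bb$end_pos) / 2
  protected <- union(anchor_blocks, truth$sus_blocks)
  clear_of_protected <- vapply(seq_len(n_blocks), function(b) {
    if (b %in% protected) return(FALSE)
    for (p in protected) {
      if (bb$chrom[p] != bb$chrom[b]) next
      gap <- max(0, bb$start_pos[p] - bb_mid[b], bb_mid[b] - bb$end_pos[p])
      if (gap <= cis_exclusion_bp) return(FALSE)
    }
    TRUE
  }, logical(1))
  free_blocks <- which(clear_of_protected)
  if (!length(free_blocks)) free_blocks <- setdiff(seq_len(n_blocks), protected)
  probe_block <- sample(free_blocks, n_probes, replace = TRUE)
  probe_block[seq_len(n_anchors)] <- anchor_blocks
  probe_positions <- data.frame(
    probe_id = probe_ids,
    chrom = bb$chrom[probe_block],
    pos = as.integer(round((bb$start_pos[probe_block] +
                              bb$end_pos[probe_block]) / 2)))

  mu <- stats::setNames(stats::rnorm(n_probes, 8, 1), probe_ids)
  tgt_sign <- stats::setNames(
    sample(c(-1, 1), n_anchors * n_targets_per_anchor, replace = TRUE),
    unlist(targets))

  # strain-level signal per probe
  signal <- matrix(0, n_probes, n_str, dimnames = list(probe_ids, strains))
  for (aid in anchors) {
    signal[aid, ] <- beta_cis * score[aid, ]
    for (tid in targets[[aid]]) {
      signal[tid, ] <- beta_trans * tgt_sign[tid] * score[aid, ]
    }
  }

  array_ids <- paste0(rep(strains, each = replicates_per_strain), "_r",
                      seq_len(replicates_per_strain))
  a2s <- stats::setNames(rep(strains, each = replicates_per_strain), array_ids)
  vals <- matrix(mu, n_probes, length(array_ids)) +
    signal[, a2s, drop = FALSE] +
    matrix(stats::rnorm(n_probes * length(array_ids), 0, noise_sd),
           n_probes, length(array_ids))
  dimnames(vals) <- list(probe_ids, array_ids)
  detected <- vals > stats::quantile(vals, det_quantile)

  expr <- expression_matrix(vals, detected, a2s)

  phenotype <- ifelse(truth$sus_side[strains] == 1L, "susceptible", "resistant")
  unknown <- sample(strains, min(n_unknown, n_str))
  phenotype[strains %in% unknown] <- "unknown"
  panel <- strain_panel(strains, phenotype)

  truth$expression <- list(
    probe_positions = probe_positions,
    anchors = anchors, anchor_blocks = anchor_blocks,
    targets = targets, target_sign = tgt_sign,
    genetic_score = score, mu = mu,
    beta_cis = beta_cis, beta_trans = beta_trans,
    noise_sd = noise_sd, replicates = replicates_per_strain,
    det_quantile = det_quantile,
    phenotype_full = stats::setNames(
      ifelse(truth$sus_side[strains] == 1L, "susceptible", "resistant"),
      strains))
  list(expr = expr, panel = panel, truth = truth)
}

#' Simulate a recombinant inbred (RI) panel from two parental strains
#'
#' Each RI line is a mosaic of the two parental genomes: per chromosome,
#' Poisson(`expected_recomb`) breakpoints are dropped uniformly and parental
#' origin alternates across them (clean parental alleles, no missingness).
#' Expression is regenerated from the same planted cis and trans effects
#' with independent noise in each of `n_compartments` compartments — so
#' true eQTLs and anchor-target links replicate across compartments while
#' chance correlations from the original panel do not. Parents default to
#' the pair of strains on opposite susceptibility sides with the largest
#' normalized SNP distance, which guarantees every susceptibility-block
#' anchor segregates in the cross.
#'
#' @param truth extended truth from [simulate_expression].
#' @param n_lines number of RI lines (default 50).
#' @param parents length-2 character vector of parental strain ids, or
#'   `NULL` for the default choice.
#' @param n_compartments independent expression compartments (default 2).
#' @param expected_recomb expected breakpoints per chromosome per line
#'   (default 3; 0 forces non-recombinant lines).
#' @param seed RNG seed.
#' @return list with `geno` (RI [genotype_matrix]), `expr` (named list of
#'   [expression_matrix], one per compartment, one array per line) and
#'   `parent_of_block` (line x block parental-origin matrix).
#' @export
simulate_ri_panel <- function(truth, n_lines = 50, parents = NULL,
                              n_compartments = 2, expected_recomb = 3,
                              seed = 1L) {
  if (is.null(truth$expression)) {
    stop("truth must come from simulate_expression (needs planted effects)")
  }
  set.seed(seed + 2000L)
  strains <- truth$strains
  if (is.null(parents)) {
    d <- strain_snp_distance(truth$clean_alleles, normalized = TRUE)
    side <- truth$sus_side[strains]
    best <- c(NA, NA); bestd <- -1
    for (i in which(side == 0L)) {
      for (j in which(side == 1L)) {
        if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
      }
    }
    parents <- strains[best]
  }
  stopifnot(length(parents) == 2L, all(parents %in% strains))
  pa <- truth$clean_alleles[parents[1], ]
  pb <- truth$clean_alleles[parents[2], ]
  if (all(pa == pb)) stop("parents are monomorphic at every marker")

  lines <- sprintf("RI%03d", seq_len(n_lines))
  n_snps <- length(truth$pos)
  origin <- matrix(NA_integer_, n_lines, n_snps)  # 1 = parent A, 2 = parent B
  for (l in seq_len(n_lines)) {
    for (cc in unique(truth$chrom)) {
      i <- which(truth$chrom == cc)
      nb <- stats::rpois(1, expected_recomb)
      bp <- sort(stats::runif(nb, min(truth$pos[i]), max(truth$pos[i])))
      seg <- findInterval(truth$pos[i], bp)
      start <- sample(1:2, 1L)
      origin[l, i] <- 1L + (start + seg) %% 2L
    }
  }
  al <- matrix(NA_character_, n_lines, n_snps, dimnames = list(lines, NULL))
  al[origin == 1L] <- matrix(pa, n_lines, n_snps, byrow = TRUE)[origin == 1L]
  al[origin == 2L] <- matrix(pb, n_lines, n_snps, byrow = TRUE)[origin == 2L]
  ri_geno <- genotype_matrix(truth$chrom, truth$pos, al)

  # parental origin at each block midpoint -> ancestral class -> genetic score
  ex <- truth$expression
  bb <- truth$block_boundaries
  mid_snp <- as.integer(round((bb$start_snp + bb$end_snp) / 2))
  parent_of_block <- origin[, mid_snp, drop = FALSE]
  dimnames(parent_of_block) <- list(lines, NULL)

  probe_ids <- ex$probe_positions$probe_id
  signal <- matrix(0, length(probe_ids), n_lines,
                   dimnames = list(probe_ids, lines))
  for (i in seq_along(ex$anchors)) {
    aid <- ex$anchors[i]
    # the line inherits the parent's standardized score at the anchor block
    par_score <- ex$genetic_score[aid, parents]
    g <- par_score[parent_of_block[, ex$anchor_blocks[i]]]
    if (stats::sd(g) > 0) gs <- (g - mean(g)) / stats::sd(g) else gs <- g * 0
    signal[aid, ] <- ex$beta_cis * gs
    for (tid in ex$targets[[aid]]) {
      signal[tid, ] <- ex$beta_trans * ex$target_sign[tid] * gs
    }
  }

  expr_list <- list()
  comp_names <- paste0("comp", seq_len(n_compartments))
  for (k in seq_len(n_compartments)) {
    vals <- matrix(ex$mu, length(probe_ids), n_lines) + signal +
      matrix(stats::rnorm(length(probe_ids) * n_lines, 0, ex$noise_sd),
             length(probe_ids), n_lines)
    dimnames(vals) <- list(probe_ids, paste0(lines, "_", comp_names[k]))
    a2s <- stats::setNames(lines, colnames(vals))
    expr_list[[comp_names[k]]] <- expression_matrix(
      vals, vals > stats::quantile(vals, ex$det_quantile), a2s)
  }
  list(geno = ri_geno, expr = expr_list, parents = parents,
       parent_of_block = parent_of_block)
}
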