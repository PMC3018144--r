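test_that("filter_informative applies the MAF, missingness and CNVR rules", {
  # 8 strains x 10 SNPs with hand-decided fates
  strains <- paste0("s", 1:8)
  mk <- function(...) c(...)
  al <- rbind(
    snp1 = mk("A", "A", "A", "A", "A", "C", "C", "C"),   # MAF 3/8: keep
    snp2 = mk("A", "A", "A", "A", "A", "A", "A", "A"),   # monomorphic: drop
    snp3 = mk("A", "A", "A", "A", "A", "A", "A", "C"),   # MAF 1/8 > 0.05: keep
    snp4 = mk("A", "C", NA, "C", "A", "C", "A", "C"),    # 1/8 missing: keep
    snp5 = mk("A", "C", "A", "C", "A", "C", "A", "C"),   # inside CNVR: drop
    snp6 = mk(NA, NA, "A", "C", "A", "C", "A", "C"),     # 25% missing: drop
    snp7 = mk(NA, NA, NA, "C", "A", "C", "A", "C"),      # 37.5% missing: drop
    snp8 = mk("G", "G", "G", "G", "T", "T", "T", "T"),   # keep
    snp9 = mk("A", "A", "A", "A", "A", "A", "A", NA),    # monomorphic among typed: drop
    snp10 = mk("C", "C", "C", "C", "G", "G", "G", "G"))  # keep
  colnames(al) <- strains
  geno <- genotype_matrix(rep("chr1", 10), seq_len(10) * 1000L, t(al))
  cnvrs <- cnvr_set(data.frame(cnvr_id = "c1", chrom = "chr1",
                               start = 4500L, end = 5500L),
                    matrix(1L, 8, 1, dimnames = list(strains, NULL)))
  out <- filter_informative(geno, cnvrs)
  expect_identical(out$pos, c(1000L, 3000L, 4000L, 8000L, 10000L))

  # a low MAF floor on its own keeps the low-frequency SNP
  out2 <- filter_informative(geno, cnvrs, maf_min = 0.2)
  expect_false(3000L %in% out2$pos)

  expect_error(filter_informative(geno, maf_min = 0.9), "no informative")
})

test_that("strain distances count allele differences over co-typed positions", {
  al <- rbind(s1 = c("A", "A", "T", "T"),
              s2 = c("A", "A", "C", "T"))
  d <- strain_snp_distance(al)
  expect_equal(d["s1", "s2"], 1)
  expect_equal(strain_snp_distance(al, normalized = TRUE)["s1", "s2"], 0.25)
  expect_equal(d["s1", "s1"], 0)

  # masking the discordant site drops the unnormalized distance by 1
  al2 <- al
  al2["s2", 3] <- NA
  expect_equal(strain_snp_distance(al2)["s1", "s2"], 0)

  # identical strains are at distance zero
  expect_equal(strain_snp_distance(rbind(a = c("G", "G"), b = c("G", "G")))["a", "b"], 0)

  # no co-typed SNPs: undefined; error when normalized, 0 + warning otherwise
  al3 <- rbind(x = c("A", NA), y = c(NA, "C"))
  expect_error(strain_snp_distance(al3, normalized = TRUE), "no typed SNPs")
  expect_warning(d3 <- strain_snp_distance(al3), "co-typed")
  expect_equal(d3["x", "y"], 0)
})

test_that("haplotype assignment separates identical strain pairs perfectly", {
  al <- rbind(s1 = c("A", "T"), s2 = c("A", "T"),
              s3 = c("C", "G"), s4 = c("C", "G"))
  res <- assign_haplotypes(al)
  expect_equal(res$k, 2L)
  expect_equal(res$error_count, 0L)
  expect_equal(res$mean_silhouette, 1)
  expect_equal(unname(res$labels[c("s1", "s2")]),
               rep(unname(res$labels["s1"]), 2))
  expect_false(res$labels["s1"] == res$labels["s3"])
  expect_setequal(res$consensus, c("AT", "CG"))

  # fully untyped strain gets a missing label
  al2 <- rbind(al, s5 = c(NA_character_, NA_character_))
  res2 <- assign_haplotypes(al2)
  expect_true(is.na(res2$labels["s5"]))
})

test_that("chosen haplotype labels reach the exhaustive minimum error for their k", {
  # brute-force oracle: minimal consensus errors over all partitions of the
  # strains into exactly k groups (independent re-implementation)
  brute_min_errors <- function(al, k) {
    n <- nrow(al)
    parts <- anchornet:::set_partitions(n)
    best <- Inf
    for (p in parts) {
      if (max(p) != k) next
      errs <- 0L
      for (h in seq_len(k)) {
        sub <- al[p == h, , drop = FALSE]
        cons <- apply(sub, 2, function(a) {
          a <- a[!is.na(a)]
          if (!length(a)) return(NA_character_)
          names(sort(table(a), decreasing = TRUE))[1]
        })
        cmp <- sweep(sub, 2, cons, FUN = "!=")
        errs <- errs + sum(cmp, na.rm = TRUE)
      }
      best <- min(best, errs)
    }
    best
  }
  set.seed(42)
  agree <- 0L
  n_cases <- 30L
  for (i in seq_len(n_cases)) {
    al <- matrix(sample(c("A", "C"), 18, replace = TRUE), 6, 3,
                 dimnames = list(paste0("s", 1:6), NULL))
    res <- assign_haplotypes(al)
    if (res$error_count == brute_min_errors(al, res$k)) agree <- agree + 1L
  }
  expect_gte(agree / n_cases, 0.8)
})

test_that("block growth recovers planted boundaries exactly on clean data", {
  sim <- simulate_panel(n_strains = 16, n_snps = 60, n_chrom = 2,
                        n_susceptibility_blocks = 2,
                        missing_rate = 0, mutation_rate = 0, seed = 3)
  blocks <- build_blocks(sim$geno)
  got <- vapply(blocks, `[[`, integer(1), "snp_start")
  expect_equal(got, sim$truth$block_boundaries$start_snp,
               ignore_attr = TRUE)
  expect_true(all(vapply(blocks, `[[`, integer(1), "error_count") == 0L))
})

test_that("blocks tile the SNPs contiguously and respect the error bound", {
  sim <- simulate_panel(seed = 9)
  inf <- suppressWarnings(filter_informative(sim$geno, sim$cnvrs))
  blocks <- suppressWarnings(build_blocks(inf))
  covered <- unlist(lapply(blocks, function(b) b$snp_start:b$snp_end))
  expect_identical(covered, seq_len(n_snps_cols <- ncol(inf$alleles)))
  expect_true(all(vapply(blocks, `[[`, integer(1), "error_count") <= 1L))
  # per-chromosome contiguity: each block lies on one chromosome
  for (b in blocks) {
    expect_equal(length(unique(inf$chrom[b$snp_start:b$snp_end])), 1L)
  }
})

test_that("a single-SNP chromosome yields one genotype-group block", {
  al <- matrix(c("A", "A", "C", "G"), 4, 1,
               dimnames = list(paste0("s", 1:4), NULL))
  geno <- genotype_matrix("chr1", 500L, al)
  blocks <- build_blocks(geno)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$k, 3L)  # distinct alleles, may exceed the 2-6 range
  expect_equal(blocks[[1]]$error_count, 0L)
  expect_equal(blocks[[1]]$n_snps, 1L)
})

test_that("one discordant cell is tolerated, two in adjacent SNPs split the block", {
  # six ancestral classes saturate the haplotype cap, so extra errors
  # cannot be absorbed by opening new clusters
  sim <- simulate_panel(n_strains = 18, n_snps = 36, n_ancestral = 6,
                        mean_block_len = 8, n_chrom = 2,
                        n_susceptibility_blocks = 2,
                        missing_rate = 0, mutation_rate = 0, seed = 21)
  base <- build_blocks(sim$geno)
  base_starts <- vapply(base, `[[`, integer(1), "snp_start")
  expect_equal(base_starts, sim$truth$block_boundaries$start_snp,
               ignore_attr = TRUE)

  bb <- sim$truth$block_boundaries[1, ]
  mid <- bb$start_snp + 3L
  flip <- function(x) c(A = "C", C = "G", G = "T", T = "A")[[x]]

  g1 <- sim$geno
  g1$alleles[2, mid] <- flip(g1$alleles[2, mid])
  b1 <- build_blocks(g1)
  expect_identical(vapply(b1, `[[`, integer(1), "snp_start"), base_starts)
  hit <- which(vapply(b1, function(b) b$snp_start <= mid && b$snp_end >= mid,
                      logical(1)))
  expect_equal(b1[[hit]]$error_count, 1L)

  g2 <- g1
  g2$alleles[5, mid + 1L] <- flip(g2$alleles[5, mid + 1L])
  b2 <- build_blocks(g2)
  expect_gt(length(b2), length(base))
})
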