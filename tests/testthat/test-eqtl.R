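test_that("marker association equals the one-way ANOVA from lm", {
  set.seed(1)
  strains <- paste0("s", 1:15)
  for (i in 1:10) {
    trait <- stats::setNames(rnorm(15), strains)
    geno <- stats::setNames(sample(c("a", "b", "c"), 15, replace = TRUE),
                            strains)
    res <- marker_association(trait, geno)
    if (is.null(res)) next
    fit <- anova(lm(trait ~ factor(geno)))
    expect_equal(res$F_stat, fit$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_nominal, fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("the two-class F statistic equals the squared pooled t statistic", {
  set.seed(2)
  strains <- paste0("s", 1:12)
  trait <- stats::setNames(rnorm(12), strains)
  geno <- stats::setNames(rep(c("a", "b"), each = 6), strains)
  res <- marker_association(trait, geno)
  tt <- t.test(trait[1:6], trait[7:12], var.equal = TRUE)
  expect_equal(res$F_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  # and an extreme separation is essentially certain
  res2 <- marker_association(stats::setNames(c(rep(0, 6), rep(10, 6)) +
                                               rnorm(12, 0, 1), strains), geno)
  expect_lt(res2$p_nominal, 1e-4)
})

test_that("monomorphic markers are not tested", {
  trait <- stats::setNames(rnorm(6), paste0("s", 1:6))
  expect_null(marker_association(trait,
                                 stats::setNames(rep("a", 6), names(trait))))
})

test_that("cis candidate pairs match a brute-force distance scan", {
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       chrom = c("chr1", "chr1", "chr2"),
                       pos = c(1e6, 4e6, 1e6))
  markers <- data.frame(marker_id = c("m1", "m2", "m3", "m4"),
                        chrom = c("chr1", "chr1", "chr2", "chr2"),
                        start = c(9e5, 35e5, 1e6, 45e5),
                        end = c(11e5, 36e5, 1e6, 46e5))
  got <- cis_candidates(probes, markers, window_bp = 2e6)
  brute <- expand.grid(i = 1:3, j = 1:4)
  brute <- brute[probes$chrom[brute$i] == markers$chrom[brute$j] &
                   abs((markers$start[brute$j] + markers$end[brute$j]) / 2 -
                         probes$pos[brute$i]) <= 2e6, ]
  expect_equal(nrow(got), nrow(brute))
  expect_setequal(paste(got$probe_id, got$marker_id),
                  paste(probes$probe_id[brute$i], markers$marker_id[brute$j]))
  # a marker 2.5 Mb away is excluded at the default window
  expect_false("m4" %in% got$marker_id[got$probe_id == "p3"])

  probes$pos[2] <- NA
  expect_warning(got2 <- cis_candidates(probes, markers), "without genomic position")
  expect_false("p2" %in% got2$probe_id)
})

test_that("strain weights reflect genetic redundancy", {
  # three strains pairwise equidistant -> uniform weights
  al <- rbind(s1 = c("A", "C", "C"),
              s2 = c("C", "A", "C"),
              s3 = c("C", "C", "A"))
  g <- genotype_matrix(rep("chr1", 3), c(1L, 2L, 3L) * 100L, al)
  w <- compute_strain_weights(g)
  expect_equal(unname(w), rep(1, 3))

  # a duplicated pair is down-weighted relative to distinct strains
  al2 <- rbind(s1 = c("A", "A", "A", "A"),
               s2 = c("A", "A", "A", "A"),
               s3 = c("C", "C", "A", "A"),
               s4 = c("A", "A", "C", "C"))
  g2 <- genotype_matrix(rep("chr1", 4), (1:4) * 100L, al2)
  w2 <- compute_strain_weights(g2)
  expect_lt(w2["s1"], min(w2["s3"], w2["s4"]))
  expect_equal(unname(w2["s1"]), unname(w2["s2"]))
  expect_equal(mean(w2), 1)
})

test_that("weighted permutation p behaves like the plain permutation under uniform weights", {
  set.seed(3)
  strains <- paste0("s", 1:16)
  geno <- stats::setNames(rep(c("a", "b"), each = 8), strains)
  for (i in 1:3) {
    trait <- stats::setNames(rnorm(16) + 0.8 * (geno == "a"), strains)
    p_plain <- weighted_permutation_p(trait, geno, NULL, n_perm = 500,
                                      seed = 100 + i)
    p_unif <- weighted_permutation_p(trait, geno,
                                     stats::setNames(rep(1, 16), strains),
                                     n_perm = 500, seed = 200 + i)
    se <- sqrt(p_plain * (1 - p_plain) / 500)
    expect_lt(abs(p_plain - p_unif), 4 * se + 0.02)
  }
})

test_that("a perfect genotype-trait correspondence reaches the permutation floor", {
  strains <- paste0("s", 1:12)
  geno <- stats::setNames(rep(c("a", "b"), each = 6), strains)
  trait <- stats::setNames(c(rep(0, 6), rep(5, 6)) + rnorm(12, 0, 0.01),
                           strains)
  p <- weighted_permutation_p(trait, geno, n_perm = 199, seed = 4)
  expect_equal(p, 1 / 200)
  expect_warning(weighted_permutation_p(trait, geno, n_perm = 50, seed = 4),
                 "n_perm")
})

test_that("permutation p converges to the nominal ANOVA p under uniform weights", {
  set.seed(5)
  strains <- paste0("s", 1:20)
  geno <- stats::setNames(rep(c("a", "b"), each = 10), strains)
  devs <- vapply(1:8, function(i) {
    trait <- stats::setNames(rnorm(20) + 0.5 * (geno == "a"), strains)
    nominal <- marker_association(trait, geno)$p_nominal
    perm <- weighted_permutation_p(trait, geno, n_perm = 4000, seed = 500 + i)
    abs(perm - nominal)
  }, numeric(1))
  expect_lt(mean(devs), 0.02)
})

test_that("best-per-trait selection applies the p, F, then marker-id tie rules", {
  rec <- data.frame(
    probe_id = c("p1", "p1", "p1", "p2"),
    marker_id = c("mB", "mA", "mC", "mZ"),
    F_stat = c(5, 5, 9, 2),
    p_perm = c(0.01, 0.01, 0.02, 0.5))
  out <- select_best_per_trait(rec)
  expect_equal(out$marker_id[out$is_best_for_trait & out$probe_id == "p1"],
               "mA")  # tie in p and F -> lexicographically smallest id
  expect_true(out$is_best_for_trait[out$probe_id == "p2"])
  rec2 <- rec
  rec2$F_stat[1] <- 7
  out2 <- select_best_per_trait(rec2)
  expect_equal(out2$marker_id[out2$is_best_for_trait & out2$probe_id == "p1"],
               "mB")  # tie in p -> larger F wins
})

test_that("singleton genotype classes merge into the nearest class", {
  g <- stats::setNames(c("1", "1", "1", "2", "2", "3"), paste0("s", 1:6))
  cons <- c("1" = "AAAA", "2" = "AACC", "3" = "ACCC")
  merged <- anchornet:::merge_singleton_classes(g, cons)
  expect_equal(unname(merged["s6"]), "2")  # ACCC is 1 mismatch from AACC

  gn <- stats::setNames(c("1", "1", "3", "3", "7"), paste0("s", 1:5))
  merged_n <- anchornet:::merge_singleton_classes(gn)
  expect_equal(unname(merged_n["s5"]), "3")  # numeric distance
})

test_that("Holm with a single tested marker is the identity and validates at alpha", {
  sim <- simulate_panel(n_chrom = 1, n_snps = 20,
                        n_susceptibility_blocks = 1,
                        missing_rate = 0, mutation_rate = 0, seed = 6)
  se <- simulate_expression(sim, n_anchors = 1, n_targets_per_anchor = 3,
                            n_probes = 10, seed = 6)
  ri <- simulate_ri_panel(se$truth, n_lines = 30, n_compartments = 1,
                          seed = 6)
  pp <- se$truth$expression$probe_positions
  ap <- pp[pp$probe_id == se$truth$expression$anchors[1], ]
  # shrink the window until exactly one polymorphic marker is in range
  poly <- apply(ri$geno$alleles, 2, function(a) length(unique(a[!is.na(a)])) > 1)
  snp_d <- abs(ri$geno$pos - ap$pos)
  snp_d[!poly] <- Inf
  w <- sort(snp_d)[1]
  val <- validate_in_ri(ap, ri$geno, ri$expr, window_bp = w + 1)
  expect_equal(val$detail$n_markers, 1L)
  raw <- marker_association(
    anchornet:::strain_means(ri$expr[[1]], ap$probe_id)$means[1, ],
    stats::setNames(ri$geno$alleles[, which.min(snp_d)],
                    rownames(ri$geno$alleles)))
  expect_equal(val$detail$min_p_holm, raw$p_nominal, tolerance = 1e-10)
  expect_equal(val$detail$validated, raw$p_nominal < 0.05)
})
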