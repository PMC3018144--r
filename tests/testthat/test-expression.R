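test_that("detection filtering follows the all-replicates and strain-fraction rules", {
  strains <- c("sA", "sB", "sC", "sD", "sE")
  arrays <- c("sA_1", "sA_2", "sB_1", "sB_2", "sC_1", "sC_2", "sD_1", "sD_2",
              "sE_1")  # sE has a single array
  a2s <- stats::setNames(c("sA", "sA", "sB", "sB", "sC", "sC", "sD", "sD", "sE"),
                         arrays)
  vals <- matrix(0, 4, 9, dimnames = list(paste0("p", 1:4), arrays))
  det <- matrix(FALSE, 4, 9, dimnames = dimnames(vals))
  det["p1", ] <- TRUE                      # everywhere: kept
  det["p2", 1:6] <- TRUE                   # all replicates of exactly 3 strains: kept
  det["p3", c(1:4, 9)] <- TRUE             # 2 replicate strains + single-array strain: dropped
  det["p4", c(1, 3, 5, 7)] <- TRUE         # one replicate each: dropped
  expr <- expression_matrix(vals, det, a2s)
  expect_setequal(detection_filter(expr, min_strains = 3), c("p1", "p2"))
  # hand count agrees with brute force over multi-array strains
  brute <- sapply(rownames(det), function(p) {
    full <- sapply(c("sA", "sB", "sC", "sD"), function(s)
      all(det[p, a2s == s]))
    sum(full) >= 3
  })
  expect_setequal(detection_filter(expr, min_strains = 3),
                  names(brute)[brute])

  # strain-fraction mode: any detected array counts the strain
  # (p1: 5/5 strains, p4: 4/5; p2 and p3 reach only 3/5)
  expect_setequal(detection_filter(expr, mode = "strain-fraction",
                                   fraction = 0.7),
                  c("p1", "p4"))
  expect_error(detection_filter(expr, mode = "bogus"))
})

test_that("strain medians collapse replicates per probe", {
  means <- matrix(1:6, 2, 3,
                  dimnames = list(c("p1", "p2"), c("sA", "sB", "sC")))
  ex1 <- expr_from_means(means, replicates = 1)
  expect_equal(strain_medians(ex1), t(means))

  arrays <- c("sA_1", "sA_2", "sA_3")
  vals <- matrix(c(1, 2, 9), 1, 3, dimnames = list("p1", arrays))
  ex <- expression_matrix(vals, array_to_strain = stats::setNames(rep("sA", 3), arrays))
  expect_equal(strain_medians(ex)["sA", "p1"], 2)

  # random fixture against a sort-and-pick oracle
  set.seed(3)
  ex2 <- expr_from_means(matrix(rnorm(12), 4, 3,
                                dimnames = list(paste0("p", 1:4),
                                                c("sA", "sB", "sC"))),
                         replicates = 3, noise_sd = 1, seed = 3)
  med <- strain_medians(ex2)
  for (s in c("sA", "sB", "sC")) {
    for (p in paste0("p", 1:4)) {
      v <- sort(ex2$values[p, ex2$array_to_strain == s])
      expect_equal(med[s, p], unname(v[2]))
    }
  }
})

test_that("hierarchical clustering uses 1-Pearson with complete linkage", {
  set.seed(4)
  base <- rnorm(20)
  profiles <- rbind(sA = base, sB = base + rnorm(20, 0, 1e-8),
                    sC = -base, sD = rnorm(20))
  hc <- hcluster_profiles(profiles)
  # the identical pair merges first at height ~0
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("sA", "sB"))
  expect_lt(hc$height[1], 1e-10)

  # merge heights equal a hand-trace of complete linkage on 1-cor
  d <- 1 - cor(t(profiles))
  manual <- hclust(as.dist(d), method = "complete")
  expect_equal(hc$height, manual$height)

  # reordering the strains leaves the merge heights unchanged
  hc2 <- hcluster_profiles(profiles[c(3, 1, 4, 2), ])
  expect_equal(sort(hc2$height), sort(hc$height))

  flat <- rbind(profiles, sE = rep(1, 20))
  expect_error(hcluster_profiles(flat), "sE")
  expect_error(hcluster_profiles(profiles[1:2, ]), ">= 3")
})

test_that("extreme phenotype clustering gives the minimal add-one p-value", {
  set.seed(5)
  base <- rnorm(40)
  # six near-duplicate susceptible profiles, six mutually independent
  # resistant ones: only the true labeling has a near-zero within/between
  # ratio, so the add-one p sits at the resolution floor
  profiles <- rbind(
    do.call(rbind, lapply(1:6, function(i) base + rnorm(40, 0, 0.01))),
    do.call(rbind, lapply(1:6, function(i) rnorm(40))))
  rownames(profiles) <- c(paste0("s", 1:6), paste0("r", 1:6))
  panel <- strain_panel(rownames(profiles),
                        rep(c("susceptible", "resistant"), each = 6))
  ct <- cluster_permutation_test(profiles, panel, n_perm = 999, seed = 5)
  expect_lt(ct$statistic, 0.1)
  expect_lt(ct$p_value, 0.01)
})

test_that("the permutation p-value matches exhaustive enumeration on a small panel", {
  set.seed(6)
  profiles <- matrix(rnorm(7 * 25), 7, 25,
                     dimnames = list(paste0("s", 1:7), NULL))
  panel <- strain_panel(rownames(profiles),
                        c(rep("susceptible", 3), rep("resistant", 4)))
  exact <- cluster_test_exact(profiles, panel)
  ct <- cluster_permutation_test(profiles, panel, n_perm = 4000, seed = 6)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(ct$p_value - exact), 4 * se + 0.01)
  expect_gt(ct$p_value, 0)
})

test_that("phenotype-contrast preconditions are enforced", {
  profiles <- matrix(rnorm(3 * 10), 3, 10,
                     dimnames = list(c("a", "b", "c"), NULL))
  panel <- strain_panel(c("a", "b", "c"),
                        c("susceptible", "resistant", "resistant"))
  expect_error(cluster_permutation_test(profiles, panel), "2 susceptible")
})
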