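test_that("anchors are the probes both DE and eQTL-linked", {
  de <- data.frame(probe_id = c("p1", "p2", "p3"),
                   q_value = c(0.01, 0.2, 0.01))
  eqtl <- data.frame(probe_id = c("p1", "p2"),
                     significant = c(TRUE, TRUE))
  expect_equal(define_anchors(de, eqtl), "p1")
  expect_warning(a <- define_anchors(de[2, , drop = FALSE], eqtl),
                 "no probes")
  expect_length(a, 0L)
})

test_that("module building admits true targets and controls null inclusion", {
  set.seed(1)
  n_arr <- 60
  anchor <- rnorm(n_arr)
  vals <- rbind(anchor = anchor,
                echo = anchor + rnorm(n_arr, 0, 0.2),
                t(replicate(300, rnorm(n_arr))))
  rownames(vals) <- c("anchor", "echo", sprintf("null%03d", 1:300))
  colnames(vals) <- paste0("a", seq_len(n_arr))
  a2s <- stats::setNames(rep(paste0("s", 1:20), each = 3), colnames(vals))
  expr <- expression_matrix(vals, array_to_strain = a2s)
  targets <- build_module("anchor", expr, fdr = 0.01)
  expect_true("echo" %in% targets)
  expect_false("anchor" %in% targets)
  expect_lt(mean(grepl("null", targets)), 0.02)

  flat <- expr
  flat$values["anchor", ] <- 1
  expect_error(build_module("anchor", flat), "zero variance")
})

test_that("trimming keeps targets replicating in at least one compartment", {
  set.seed(2)
  lines <- paste0("L", 1:40)
  mk_comp <- function(link_t1, link_t2) {
    a <- rnorm(40)
    vals <- rbind(anchor = a,
                  t1 = if (link_t1) a + rnorm(40, 0, 0.3) else rnorm(40),
                  t2 = if (link_t2) a + rnorm(40, 0, 0.3) else rnorm(40),
                  t3 = rnorm(40))
    colnames(vals) <- lines
    expression_matrix(vals, array_to_strain = stats::setNames(lines, lines))
  }
  ri <- list(stem = mk_comp(TRUE, FALSE), prog = mk_comp(FALSE, FALSE))
  tr <- trim_module("anchor", c("t1", "t2", "t3"), ri, fdr = 0.25)
  expect_true("t1" %in% tr$kept)      # replicates in one compartment
  expect_false("t3" %in% tr$kept)     # replicates nowhere
  expect_false(tr$untrimmable)

  # raising the FDR threshold never shrinks the kept set
  tr_lo <- trim_module("anchor", c("t1", "t2", "t3"), ri, fdr = 0.05)
  tr_hi <- trim_module("anchor", c("t1", "t2", "t3"), ri, fdr = 0.5)
  expect_true(all(tr_lo$kept %in% tr_hi$kept))

  # anchor absent everywhere -> untrimmable, targets passed through
  ri_missing <- lapply(ri, function(ex) {
    expression_matrix(ex$values[-1, , drop = FALSE],
                      array_to_strain = ex$array_to_strain)
  })
  expect_warning(tr2 <- trim_module("anchor", c("t1", "t2"), ri_missing),
                 "undetected")
  expect_true(tr2$untrimmable)
  expect_equal(tr2$kept, c("t1", "t2"))
})

test_that("the trim p-values equal the lm slope p-values", {
  set.seed(3)
  lines <- paste0("L", 1:25)
  a <- rnorm(25)
  y <- a * 0.5 + rnorm(25, 0, 0.8)
  vals <- rbind(anchor = a, tgt = y)
  colnames(vals) <- lines
  ri <- list(c1 = expression_matrix(vals,
                                    array_to_strain = stats::setNames(lines, lines)))
  p_lm <- summary(lm(y ~ a))$coefficients[2, 4]
  tr <- trim_module("anchor", "tgt", ri, fdr = p_lm + 1e-6)
  expect_equal(tr$kept, "tgt")
  tr2 <- trim_module("anchor", "tgt", ri, fdr = p_lm - 1e-6)
  expect_length(tr2$kept, 0L)
})

test_that("eigengenes equal the SVD first component with a fixed sign", {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                1, 1, 2, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("x", 1:4)))
  eg <- eigengene(m)
  z <- t(scale(t(m)))
  v <- svd(z)$v[, 1]
  if (cor(v, colMeans(z)) < 0) v <- -v
  expect_equal(unname(eg$eigengene), v, tolerance = 1e-10)
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-10)

  # k identical profiles: eigengene proportional to the profile, all variance
  ident <- matrix(rep(c(1, 3, 2, 5), each = 4), 4, 4, byrow = FALSE,
                  dimnames = list(paste0("p", 1:4), paste0("x", 1:4)))
  egi <- eigengene(ident)
  expect_equal(egi$var_explained, 1, tolerance = 1e-10)
  expect_gt(cor(egi$eigengene, ident[1, ]), 0.999)

  # flipping every member's sign flips the eigengene sign only
  egf <- eigengene(-m)
  expect_equal(unname(egf$eigengene), -unname(eg$eigengene), tolerance = 1e-10)

  one <- eigengene(m[1, , drop = FALSE])
  expect_equal(sum(one$eigengene^2), 1, tolerance = 1e-10)
})

test_that("module susceptibility ranks a separating eigengene first", {
  set.seed(4)
  strains <- paste0("s", 1:10)
  arrays <- paste0(rep(strains, each = 2), "_r", 1:2)
  a2s <- stats::setNames(rep(strains, each = 2), arrays)
  vals <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(paste0("p", 1:5), arrays))
  expr <- expression_matrix(vals, array_to_strain = a2s)
  panel <- strain_panel(strains, rep(c("susceptible", "resistant"), each = 5))
  sep <- ifelse(a2s %in% strains[1:5], 1, -1) + rnorm(20, 0, 0.1)
  modules <- list(
    A_sep = list(eigengene = stats::setNames(sep / sqrt(sum(sep^2)), arrays),
                 targets = paste0("p", 1:3)),
    A_null = list(eigengene = stats::setNames(rnorm(20), arrays),
                  targets = paste0("p", 4:5)))
  sus <- module_susceptibility(modules, expr, panel)
  expect_equal(sus$module_id[1], "A_sep")
  expect_lt(sus$p_nominal[1], 0.01)
})

test_that("the module network keeps only strong positive eigengene correlations", {
  arrays <- paste0("a", 1:12)
  a2s <- stats::setNames(rep(paste0("s", 1:6), each = 2), arrays)
  vals <- matrix(rnorm(24), 2, 12, dimnames = list(c("p1", "p2"), arrays))
  expr <- expression_matrix(vals, array_to_strain = a2s)
  e1 <- rnorm(12)
  modules <- list(
    A = list(eigengene = stats::setNames(e1, arrays), targets = "p1"),
    B = list(eigengene = stats::setNames(e1, arrays), targets = "p2"),
    C = list(eigengene = stats::setNames(-e1, arrays), targets = "p2"))
  net <- module_network(modules, expr, corr_floor = 0.5)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$module_a, net$edges$module_b), c("A", "B"))
  expect_equal(net$edges$weight, 1, tolerance = 1e-10)
  # brute-force all-pairs check
  em <- rbind(A = e1, B = e1, C = -e1)
  cc <- cor(t(em))
  for (i in 1:2) for (j in (i + 1):3) {
    inlist <- any((net$edges$module_a == rownames(em)[i] &
                     net$edges$module_b == rownames(em)[j]))
    expect_equal(inlist, cc[i, j] > 0.5)
  }
  expect_equal(dim(net$eigengene_by_strain), c(3L, 6L))
})
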