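# helpers to build small in-memory cohorts without the full pipeline
toy_models <- function(values_list, groups = NULL, mesh = NULL,
                       unassigned = NULL) {
  mesh <- mesh %||% box_mesh(2, 2, 2)
  n <- nrow(mesh$elements)
  lapply(seq_along(values_list), function(i) {
    un <- if (is.null(unassigned)) rep(FALSE, n) else unassigned[[i]]
    subject_model(mesh, list(FA = values_list[[i]]),
                  subject_id = sprintf("s%02d", i),
                  group_label = if (is.null(groups)) "g" else groups[i],
                  unassigned = un)
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cohort matrix assembly: metric mode, intersection rule, shape mode", {
  mesh <- box_mesh(2, 2, 2)
  vals <- lapply(1:3, function(i) seq_len(8) * i / 10)
  models <- toy_models(vals, mesh = mesh)
  cm <- assemble_cohort_matrix(models, "FA")
  expect_identical(dim(cm$matrix), c(3L, 8L))
  expect_equal(cm$matrix[2, ], vals[[2]])

  un <- list(rep(FALSE, 8), c(TRUE, rep(FALSE, 6), TRUE), rep(FALSE, 8))
  m2 <- toy_models(vals, mesh = mesh, unassigned = un)
  cm2 <- assemble_cohort_matrix(m2, "FA")
  expect_identical(dim(cm2$matrix), c(3L, 6L))
  expect_identical(cm2$dropped_features, c(1L, 8L))
  expect_identical(cm2$feature_index, c(2L, 3L, 4L, 5L, 6L, 7L))

  cs <- assemble_cohort_matrix(models, "shape")
  expect_identical(dim(cs$matrix), c(3L, 3L * nrow(mesh$nodes)))
  expect_equal(cs$matrix[1, 1:3], mesh$nodes[1, ], ignore_attr = TRUE)

  other <- toy_models(lapply(vals, function(v) v[1:4]), mesh = box_mesh(1, 2, 2))
  expect_error(assemble_cohort_matrix(c(models[1:2], other[3]), "FA"),
               "topology mismatch.*s03")
  expect_error(assemble_cohort_matrix(models[1:2], "FA"), "at least 3")
})

test_that("standardization: exact small case, zero-variance drop, recomputation", {
  cm <- cohort_matrix(cbind(c(1, 2, 3)))
  z <- standardize(cm)
  expect_equal(as.vector(z$matrix), c(-1, 0, 1))

  cm2 <- cohort_matrix(cbind(a = c(1, 2, 3), b = c(0.5, 0.5, 0.5)))
  z2 <- standardize(cm2)
  expect_identical(ncol(z2$matrix), 1L)
  expect_identical(z2$dropped_features, 2L)

  withr::with_seed(19, X <- matrix(rnorm(50, mean = 3, sd = 2), 5, 10))
  z3 <- standardize(cohort_matrix(X))
  expect_lt(max(abs(colMeans(z3$matrix))), 1e-10)
  expect_lt(max(abs(apply(z3$matrix, 2, sd) - 1)), 1e-10)

  expect_error(standardize(cohort_matrix(matrix(1, 1, 3))), "2 rows")
})

test_that("PCA: rank-1 exact scores, completeness, determinism properties", {
  z <- standardize(cohort_matrix(rbind(c(0, 0), c(1, 1), c(2, 2))))
  p <- run_pca(z, 2)
  expect_equal(p$explained_variance_ratio[1], 1)
  expect_equal(as.vector(p$scores[, 1]), c(-sqrt(2), 0, sqrt(2)))
  expect_equal(as.vector(p$scores[, 2]), c(0, 0, 0))

  withr::with_seed(29, X <- matrix(rnorm(8 * 40), 8, 40))
  z2 <- standardize(cohort_matrix(X))
  k <- 7
  p2 <- run_pca(z2, k)
  # completeness: full-rank reconstruction
  expect_lt(max(abs(p2$scores %*% t(p2$loadings) - z2$matrix)), 1e-8)
  # orthogonality of score columns
  G <- crossprod(p2$scores)
  expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
  # explained variance ratios: non-increasing, in [0,1], sum <= 1
  evr <- p2$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1))
  expect_lte(sum(evr), 1 + 1e-12)
  expect_error(run_pca(z2, 8), "n_components")

  # identical rows get identical scores
  X3 <- rbind(X[1:3, ], X[2, ])
  p3 <- run_pca(standardize(cohort_matrix(X3)), 2)
  expect_equal(p3$scores[2, ], p3$scores[4, ], ignore_attr = TRUE)
})

test_that("shape PCA of identical geometries is reported as degenerate", {
  mesh <- box_mesh(2, 2, 2)
  models <- toy_models(lapply(1:4, function(i) runif(8)), mesh = mesh)
  cs <- standardize(assemble_cohort_matrix(models, "shape"))
  expect_identical(ncol(cs$matrix), 0L)      # all columns constant
  p <- run_pca(cs, 2)
  expect_true(p$degenerate)
  expect_true(all(p$scores == 0))
  expect_error(cluster_report(p, c("a", "a", "b", "b")), "degenerate")
})

test_that("element-wise t-test: exact cases and the closed-form oracle", {
  A <- cohort_matrix(cbind(c(1, 2), c(1, 2)))
  B <- cohort_matrix(cbind(c(4, 6), c(1, 2)))
  st <- elementwise_ttest(A, B)
  expect_equal(st$t[1], -3.130495, tolerance = 1e-6)
  expect_equal(st$p[1], 0.089, tolerance = 5e-3)
  expect_equal(st$df[1], 2)
  expect_equal(st$t[2], 0)
  expect_equal(st$p[2], 1)

  # exhaustive small-group oracle: all group-size pairs 2..5, integer data
  withr::with_seed(37, {
    for (n1 in 2:5) for (n2 in 2:5) {
      a <- matrix(sample(0:9, n1 * 6, replace = TRUE), n1, 6)
      b <- matrix(sample(0:9, n2 * 6, replace = TRUE), n2, 6)
      st <- elementwise_ttest(cohort_matrix(a), cohort_matrix(b))
      for (jcol in 1:6) {
        if (st$flagged[jcol]) {
          expect_true(var(a[, jcol]) == 0 && var(b[, jcol]) == 0)
          expect_identical(st$p[jcol], 1)
        } else if (var(a[, jcol]) + var(b[, jcol]) > 0) {
          o <- ttest_oracle(a[, jcol], b[, jcol])
          expect_equal(st$t[jcol], o$t, tolerance = 1e-12)
          expect_equal(st$p[jcol], o$p, tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("t-test flavours: welch, paired, zero-variance flagging, errors", {
  withr::with_seed(41, {
    a <- matrix(rnorm(5 * 4), 5, 4); b <- matrix(rnorm(7 * 4, sd = 3), 7, 4)
  })
  stw <- elementwise_ttest(cohort_matrix(a), cohort_matrix(b), "welch")
  for (j in 1:4) {
    o <- stats::t.test(a[, j], b[, j])
    expect_equal(stw$t[j], unname(o$statistic), tolerance = 1e-12)
    expect_equal(stw$p[j], o$p.value, tolerance = 1e-12)
  }
  stp <- elementwise_ttest(cohort_matrix(a), cohort_matrix(b[1:5, ]), "paired")
  for (j in 1:4) {
    o <- stats::t.test(a[, j], b[1:5, j], paired = TRUE)
    expect_equal(stp$t[j], unname(o$statistic), tolerance = 1e-12)
    expect_equal(stp$p[j], o$p.value, tolerance = 1e-12)
  }
  expect_error(elementwise_ttest(cohort_matrix(a), cohort_matrix(b), "paired"),
               "equal subject counts")
  expect_error(elementwise_ttest(cohort_matrix(a[1, , drop = FALSE]),
                                 cohort_matrix(b)), "at least 2")

  zv <- elementwise_ttest(cohort_matrix(matrix(1, 3, 2)),
                          cohort_matrix(matrix(2, 3, 2)))
  expect_true(all(zv$flagged))
  expect_true(all(is.na(zv$t)))
  expect_true(all(zv$p == 1))
})

test_that("null p-values are uniform over 2000 elements (KS at alpha 0.01)", {
  withr::with_seed(43, {
    a <- matrix(rnorm(10 * 2000), 10)
    b <- matrix(rnorm(10 * 2000), 10)
  })
  st <- elementwise_ttest(cohort_matrix(a), cohort_matrix(b))
  ks <- suppressWarnings(ks.test(st$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH q-values: monotone in p and invariant to element ordering", {
  withr::with_seed(47, {
    a <- matrix(rnorm(6 * 300), 6); b <- matrix(rnorm(6 * 300, 0.5), 6)
  })
  st <- elementwise_ttest(cohort_matrix(a), cohort_matrix(b), fdr = TRUE)
  o <- order(st$p)
  expect_true(all(diff(st$q[o]) >= -1e-15))
  perm <- sample(300)
  st2 <- elementwise_ttest(cohort_matrix(a[, perm]), cohort_matrix(b[, perm]),
                           fdr = TRUE)
  expect_equal(st2$q, st$q[perm])
})

test_that("group pattern fields: SD limits and elementwise ordering", {
  mesh <- box_mesh(2, 2, 2)
  same <- toy_models(rep(list(seq(0.1, 0.8, 0.1)), 3), mesh = mesh)
  pat <- group_pattern_fields(same, "FA")
  for (f in c("mean", "lo1", "hi1", "lo2", "hi2"))
    expect_equal(pat$groups$g[[f]], seq(0.1, 0.8, 0.1))

  two <- toy_models(list(rep(0.4, 8), rep(0.6, 8)), mesh = mesh)
  p2 <- group_pattern_fields(two, "FA")
  expect_equal(p2$groups$g$mean, rep(0.5, 8))
  expect_equal(p2$groups$g$hi1, rep(0.5 + 0.1414, 8), tolerance = 1e-3)
  expect_equal(p2$groups$g$lo1, rep(0.5 - 0.1414, 8), tolerance = 1e-3)

  withr::with_seed(53, vals <- lapply(1:6, function(i) runif(8)))
  p3 <- group_pattern_fields(toy_models(vals, mesh = mesh), "FA")
  g <- p3$groups$g
  expect_true(all(g$lo2 <= g$lo1 & g$lo1 <= g$mean &
                  g$mean <= g$hi1 & g$hi1 <= g$hi2))
  expect_error(group_pattern_fields(same[1], "FA"), "at least 2")
})

test_that("cluster report: disjoint separation, permutation null, table shape", {
  scores <- cbind(c(1, 2, 3, 10, 11, 12), c(0, 1, 0, 1, 0, 1))
  pca <- structure(list(scores = scores, n_components = 2L, degenerate = FALSE,
                        subject_ids = sprintf("s%d", 1:6),
                        group_labels = rep(c("case", "control"), each = 3)),
                   class = "pca_result")
  rep1 <- cluster_report(pca)
  expect_equal(rep1$auc_pc1, 1.0)
  expect_identical(nrow(rep1$table), 6L)

  # permuted labels: raw AUC averages ~0.5
  withr::with_seed(59, {
    aucs <- replicate(300, {
      cluster_report(pca, sample(pca$group_labels))$auc_pc1_raw
    })
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  expect_error(cluster_report(pca, rep("one", 6)), "2 groups")
})
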