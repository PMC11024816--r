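# Cohort-level statistics on corresponded subject models: feature matrices,
# centred/scaled PCA, element-wise t-test fields, mean +/- SD pattern fields
# and a descriptive cluster-separation report.

#' Assemble the subjects x features cohort matrix
#'
#' Metric mode: row s, column e = subject s's metric value at element e,
#' dropping every element flagged unassigned (or NA) in any subject, so the
#' retained columns are strictly corresponded. Shape mode: row s = flattened
#' node coordinates (x1, y1, z1, x2, ...) of subject s's morphed mesh.
#'
#' @param models list of `subject_model`s sharing the template topology
#' @param what one of "FA", "MD", "AD", "RD" or "shape"
#' @return an object of class `cohort_matrix`
#' @export
assemble_cohort_matrix <- function(models, what) {
  what <- match.arg(what, c(METRICS, "shape"))
  if (length(models) < 3) stop("need at least 3 subjects")
  ref <- models[[1]]$mesh$elements
  bad <- vapply(models, function(m)
    !identical(dim(m$mesh$elements), dim(ref)) || !all(m$mesh$elements == ref),
    TRUE)
  if (any(bad))
    stop(sprintf("template topology mismatch for subject(s): %s",
                 paste(vapply(models[bad], function(m) m$subject_id, ""),
                       collapse = ", ")))
  ids <- vapply(models, function(m) m$subject_id, "")
  groups <- vapply(models, function(m) m$group_label, "")
  if (what == "shape") {
    mat <- t(vapply(models, function(m) as.vector(t(m$mesh$nodes)),
                    numeric(3 * nrow(models[[1]]$mesh$nodes))))
    dropped <- integer(0)
  } else {
    rows <- lapply(models, function(m) {
      if (is.null(m$fields[[what]]))
        stop(sprintf("subject '%s' has no '%s' field", m$subject_id, what))
      m$fields[[what]]
    })
    full <- do.call(rbind, rows)
    dropped <- which(colSums(!is.finite(full)) > 0 |
                     Reduce(`|`, lapply(models, function(m) m$unassigned)))
    mat <- if (length(dropped)) full[, -dropped, drop = FALSE] else full
  }
  structure(list(matrix = mat, subject_ids = ids, group_labels = groups,
                 what = what, dropped_features = as.integer(dropped),
                 feature_index = setdiff(seq_len(ncol(mat) + length(dropped)),
                                         dropped),
                 standardized = FALSE),
            class = "cohort_matrix")
}

#' Construct a cohort matrix directly (for matrix-level analyses)
#'
#' @param matrix subjects x features numeric matrix
#' @param subject_ids,group_labels per-row identifiers
#' @param what metric label
#' @export
cohort_matrix <- function(matrix, subject_ids = NULL, group_labels = NULL,
                          what = "FA") {
  matrix <- as.matrix(matrix)
  structure(list(matrix = matrix,
                 subject_ids = subject_ids %||% sprintf("s%03d", seq_len(nrow(matrix))),
                 group_labels = group_labels %||% rep(NA_character_, nrow(matrix)),
                 what = what, dropped_features = integer(0),
                 feature_index = seq_len(ncol(matrix)),
                 standardized = FALSE),
            class = "cohort_matrix")
}

#' Centre and scale a cohort matrix
#'
#' Each column is transformed to (x - mean) / sd (sd with the n - 1
#' denominator). Columns with sd below 1e-12 carry no between-subject
#' information and are dropped, recorded in `dropped_features`.
#'
#' @param cm a `cohort_matrix` with at least 2 rows
#' @return the standardized `cohort_matrix`
#' @export
standardize <- function(cm) {
  stopifnot(inherits(cm, "cohort_matrix"))
  X <- cm$matrix
  if (nrow(X) < 2) stop("cannot standardize a matrix with fewer than 2 rows")
  mu <- colMeans(X)
  sdv <- sqrt(colSums(sweep(X, 2, mu)^2) / (nrow(X) - 1))
  keep <- sdv >= 1e-12
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], `/`)
  cm$dropped_features <- sort(c(cm$dropped_features, cm$feature_index[!keep]))
  cm$feature_index <- cm$feature_index[keep]
  cm$matrix <- Z
  cm$standardized <- TRUE
  cm
}

#' Principal component analysis of a standardized cohort matrix
#'
#' Computed by singular value decomposition of the subjects x features
#' matrix (the features x features covariance is never formed). Scores are
#' the row projections; explained variance ratios are sigma_i^2 / sum
#' sigma^2. Each loading column is oriented so its largest-magnitude entry
#' is positive, making runs comparable across platforms.
#'
#' @param cm a standardized `cohort_matrix`
#' @param n_components number of components, at most min(subjects - 1,
#'   features)
#' @return an object of class `pca_result` with `scores`, `loadings`,
#'   `explained_variance_ratio`, `n_components`; `degenerate` is TRUE when
#'   total variance is zero (e.g. identical subjects), in which case scores
#'   are all zero
#' @export
run_pca <- function(cm, n_components = 2L) {
  stopifnot(inherits(cm, "cohort_matrix"))
  X <- cm$matrix
  n <- nrow(X); p <- ncol(X)
  if (p == 0 || sum(X^2) < 1e-20) {
    k <- max(0L, as.integer(n_components))
    return(structure(list(scores = matrix(0, n, k,
                                          dimnames = list(cm$subject_ids, NULL)),
                          loadings = matrix(0, p, k),
                          explained_variance_ratio = rep(0, k),
                          singular_values = numeric(0),
                          n_components = k, degenerate = TRUE,
                          subject_ids = cm$subject_ids,
                          group_labels = cm$group_labels),
                     class = "pca_result"))
  }
  kmax <- min(n - 1, p)
  if (n_components > kmax)
    stop(sprintf("n_components = %d exceeds min(subjects - 1, features) = %d",
                 n_components, kmax))
  sv <- svd(X, nu = n_components, nv = n_components)
  d <- sv$d
  evr_all <- d^2 / sum(d^2)
  U <- sv$u; V <- sv$v
  for (j in seq_len(n_components)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(d[seq_len(n_components)], n_components)
  rownames(scores) <- cm$subject_ids
  structure(list(scores = scores, loadings = V,
                 explained_variance_ratio = evr_all[seq_len(n_components)],
                 singular_values = d, n_components = as.integer(n_components),
                 degenerate = FALSE, subject_ids = cm$subject_ids,
                 group_labels = cm$group_labels),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  if (x$degenerate) {
    cat("pca_result: degenerate (zero total variance)\n")
  } else {
    cat(sprintf("pca_result: %d components, variance ratios %s\n",
                x$n_components,
                paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", ")))
  }
  invisible(x)
}

#' Element-wise two-sample (or paired) t-test field
#'
#' Runs a t-test independently at every retained feature across subjects,
#' yielding t and two-sided p fields over the template. Default is the
#' pooled-variance Student's test; Welch and paired variants via
#' `test_type`. Multiple-testing correction is OFF by default (the maps are
#' uncorrected p-values); `fdr = TRUE` adds Benjamini-Hochberg q-values.
#' Features where both groups have zero variance are undefined: t is NA,
#' p is set to 1 and the feature is flagged.
#'
#' @param cmA,cmB `cohort_matrix` objects with identical retained features
#' @param test_type "pooled", "welch" or "paired"
#' @param fdr also compute BH-FDR q-values
#' @return an object of class `stat_field`: `t`, `p`, optional `q`,
#'   `flagged`, `df`, `feature_index`
#' @export
elementwise_ttest <- function(cmA, cmB, test_type = c("pooled", "welch", "paired"),
                              fdr = FALSE) {
  test_type <- match.arg(test_type)
  stopifnot(inherits(cmA, "cohort_matrix"), inherits(cmB, "cohort_matrix"))
  if (!identical(cmA$feature_index, cmB$feature_index))
    stop("cohort matrices have different retained features")
  A <- cmA$matrix; B <- cmB$matrix
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  eps <- 1e-24
  if (test_type == "paired") {
    if (n1 != n2) stop("paired test requires equal subject counts in matched order")
    D <- A - B
    m <- colMeans(D)
    s2 <- colSums(sweep(D, 2, m)^2) / (n1 - 1)
    se <- sqrt(s2 / n1)
    df <- rep(n1 - 1, ncol(A))
    flagged <- s2 < eps
    t <- ifelse(flagged, NA_real_, m / se)
  } else {
    m1 <- colMeans(A); m2 <- colMeans(B)
    s1 <- colSums(sweep(A, 2, m1)^2) / (n1 - 1)
    s2 <- colSums(sweep(B, 2, m2)^2) / (n2 - 1)
    flagged <- s1 < eps & s2 < eps
    if (test_type == "pooled") {
      sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- rep(n1 + n2 - 2, ncol(A))
    } else {
      se <- sqrt(s1 / n1 + s2 / n2)
      df <- (s1 / n1 + s2 / n2)^2 /
        ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
      df[flagged] <- NA_real_
    }
    t <- ifelse(flagged, NA_real_, (m1 - m2) / se)
  }
  p <- ifelse(flagged, 1, 2 * pt(-abs(t), df))
  out <- list(t = t, p = p, test_type = test_type, flagged = flagged, df = df,
              feature_index = cmA$feature_index)
  if (fdr) out$q <- p.adjust(p, method = "BH")
  structure(out, class = "stat_field")
}

#' Group mean and +/- SD pattern fields
#'
#' Per element and group: mean, mean +/- 1 SD and mean +/- 2 SD (SD with the
#' n - 1 denominator), the fields used to visualise within-cohort variation
#' patterns on the template.
#'
#' @param models list of `subject_model`s (>= 2)
#' @param metric_name one of FA, MD, AD, RD
#' @return an object of class `pattern_fields`: per group a list of five
#'   per-element fields `mean`, `lo1`, `hi1`, `lo2`, `hi2` (NA where fewer
#'   than 2 subjects have an assigned value)
#' @export
group_pattern_fields <- function(models, metric_name) {
  metric_name <- match.arg(metric_name, METRICS)
  if (length(models) < 2) stop("need at least 2 subjects")
  groups <- vapply(models, function(m) m$group_label, "")
  out <- list()
  for (g in unique(groups)) {
    sel <- models[groups == g]
    if (length(sel) < 2) {
      warning(sprintf("group '%s' has fewer than 2 subjects; skipped", g))
      next
    }
    X <- do.call(rbind, lapply(sel, function(m) m$fields[[metric_name]]))
    nobs <- colSums(is.finite(X))
    mu <- ifelse(nobs >= 2, colMeans(X, na.rm = TRUE), NA_real_)
    sdv <- apply(X, 2, function(col) {
      v <- col[is.finite(col)]
      if (length(v) >= 2) sd(v) else NA_real_
    })
    out[[g]] <- list(mean = mu, lo1 = mu - sdv, hi1 = mu + sdv,
                     lo2 = mu - 2 * sdv, hi2 = mu + 2 * sdv)
  }
  structure(list(groups = out, metric_name = metric_name),
            class = "pattern_fields")
}

# Mann-Whitney AUC of x as a ranker of `positive` membership
rank_auc <- function(x, positive) {
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(x)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Cluster-separation report for a two-group PCA
#'
#' Purely descriptive: emits the PC1/PC2 score table keyed by subject and
#' group, the raw AUC of PC1 as a ranker of group membership (orientation as
#' given; 0.5 under label permutation), its orientation-free counterpart
#' `max(a, 1 - a)` used as the separation score (PCA signs carry no group
#' meaning), and the same for the best linear combination of PC1/PC2
#' (Fisher discriminant direction). No significance claim is attached.
#'
#' @param pca a `pca_result` carrying group labels (or pass `group_labels`)
#' @param group_labels optional replacement group labels, two groups
#' @return list with `table`, `positive_class`, `auc_pc1_raw`, `auc_pc1`,
#'   `auc_best_linear`
#' @export
cluster_report <- function(pca, group_labels = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  labels <- group_labels %||% pca$group_labels
  ug <- sort(unique(labels))
  if (length(ug) < 2) stop("cluster report needs at least 2 groups")
  if (length(ug) > 2) stop("cluster report supports exactly 2 groups")
  if (pca$n_components < 1 || pca$degenerate)
    stop("PCA is degenerate (zero variance); no separation to report")
  pos <- labels == ug[1]
  S <- pca$scores
  tab <- data.frame(subject_id = pca$subject_ids, group = labels,
                    PC1 = S[, 1],
                    PC2 = if (ncol(S) >= 2) S[, 2] else NA_real_,
                    row.names = NULL)
  a1 <- rank_auc(S[, 1], pos)
  res <- list(table = tab, positive_class = ug[1],
              auc_pc1_raw = a1, auc_pc1 = max(a1, 1 - a1))
  if (ncol(S) >= 2) {
    S2 <- S[, 1:2, drop = FALSE]
    mu1 <- colMeans(S2[pos, , drop = FALSE])
    mu2 <- colMeans(S2[!pos, , drop = FALSE])
    Cw <- (crossprod(sweep(S2[pos, , drop = FALSE], 2, mu1)) +
           crossprod(sweep(S2[!pos, , drop = FALSE], 2, mu2))) /
      (nrow(S2) - 2)
    Cw <- Cw + diag(1e-10 * max(diag(Cw), 1), 2)
    w <- solve(Cw, mu1 - mu2)
    al <- rank_auc(as.numeric(S2 %*% w), pos)
    res$auc_best_linear <- max(al, 1 - al)
  } else {
    res$auc_best_linear <- res$auc_pc1
  }
  res
}
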