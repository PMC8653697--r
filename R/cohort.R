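# Cohort-level analysis: factor-matrix PCA, projection of new recordings,
# centroid distances, clustergram and nonparametric group statistics.

#' Fit a PCA model to a factor matrix
#'
#' Columns are z-scored by default (the recurrence factors span orders of
#' magnitude), the covariance eigendecomposed via [stats::prcomp()], and a
#' deterministic sign convention applied: in each component the loading of
#' largest magnitude is made positive.  Zero-variance columns cannot be
#' standardized and are dropped with a warning.
#'
#' @param x Numeric matrix or data frame, rows = observations (epochs).
#' @param standardize Z-score columns before the eigendecomposition.
#' @return An object of class `rqa_pca`: list with `rotation` (orthonormal
#'   loadings), `center`, `scale`, `explained` (non-increasing variance
#'   fractions summing to 1 over kept columns), `scores` (training scores)
#'   and `dropped` (names of zero-variance columns).
#' @export
pca_fit <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_input("`x` must be numeric")
  if (nrow(x) < 2L) stop_input("PCA needs at least 2 rows")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance columns: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 1L) stop_input("no columns with positive variance")
  pr <- stats::prcomp(x, center = TRUE, scale. = standardize)
  rot <- pr$rotation
  scores <- pr$x
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(
    list(rotation = rot,
         center = pr$center,
         scale = if (standardize) pr$scale else
           stats::setNames(rep(1, ncol(x)), colnames(x)),
         explained = pr$sdev^2 / sum(pr$sdev^2),
         scores = scores,
         dropped = dropped),
    class = "rqa_pca"
  )
}

#' @export
print.rqa_pca <- function(x, ...) {
  ev <- round(100 * x$explained, 1)
  cat(sprintf("<rqa_pca: %d components; explained %% = %s>\n",
              length(ev), paste(ev, collapse = ", ")))
  invisible(x)
}

#' Project new observations onto a fitted PCA space
#'
#' Applies the stored standardization and loadings of the fitted model; the
#' model is never refit, so projections of independent recordings land in
#' the training coordinate frame.  Projection is affine in the input.
#'
#' @param model An [pca_fit()] object.
#' @param newdata Matrix or data frame carrying at least the fitted columns
#'   (matched by name when named, by position otherwise).
#' @return Score matrix (rows = observations, columns = components).
#' @export
pca_project <- function(model, newdata) {
  stopifnot(inherits(model, "rqa_pca"))
  newdata <- as.matrix(newdata)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  fitted_cols <- rownames(model$rotation)
  if (!is.null(colnames(newdata))) {
    if (!all(fitted_cols %in% colnames(newdata))) {
      stop_input("`newdata` lacks fitted columns: %s",
                 paste(setdiff(fitted_cols, colnames(newdata)),
                       collapse = ", "))
    }
    newdata <- newdata[, fitted_cols, drop = FALSE]
  } else if (ncol(newdata) != length(fitted_cols)) {
    stop_input("`newdata` has %d columns; the model was fitted on %d",
               ncol(newdata), length(fitted_cols))
  }
  z <- sweep(sweep(newdata, 2L, model$center, "-"), 2L, model$scale, "/")
  z %*% model$rotation
}

#' Euclidean distances between cluster centroids in PC space
#'
#' Computes the per-label centroid of the scores (by default in the
#' PC1-PC2 plane) and its Euclidean distance to the centroid of
#' `reference_label`.
#'
#' @param scores Score matrix from [pca_fit()] or [pca_project()].
#' @param labels Vector of cluster labels, one per score row.
#' @param reference_label Label whose centroid anchors the distances.
#' @param dims Integer vector of score columns used (default `1:2`).
#' @return Data frame with one row per label: centroid coordinates and
#'   `distance` to the reference centroid (0 for the reference itself).
#' @export
centroid_distances <- function(scores, labels, reference_label, dims = 1:2) {
  scores <- as.matrix(scores)
  if (length(labels) != nrow(scores)) {
    stop_input("`labels` must have one entry per score row")
  }
  if (!reference_label %in% labels) {
    stop_input("reference label '%s' not present", reference_label)
  }
  dims <- as.integer(dims)
  if (any(dims < 1L | dims > ncol(scores))) {
    stop_input("`dims` out of range")
  }
  sub <- scores[, dims, drop = FALSE]
  sums <- rowsum(sub, group = labels)
  cent <- sums / as.vector(table(labels)[rownames(sums)])
  ref <- cent[reference_label, ]
  d <- sqrt(rowSums(sweep(cent, 2L, ref, "-")^2))
  out <- data.frame(label = rownames(cent), cent, distance = as.numeric(d),
                    row.names = NULL, check.names = FALSE)
  names(out)[1 + seq_along(dims)] <- paste0("pc", dims)
  out[order(out$distance), ]
}

#' Two-way clustergram of a factor matrix
#'
#' Agglomerative hierarchical clustering of the rows and columns of the
#' standardized matrix with Euclidean distance and average linkage, the
#' usual heatmap companion of recurrence-factor tables.  Leaf order is
#' deterministic (tie-breaks follow the input order).
#'
#' @param x Numeric matrix or data frame, rows = observations.
#' @param standardize Z-score columns first (zero-variance columns are left
#'   unscaled).
#' @return An object of class `clustergram`: list with `row_hclust`,
#'   `col_hclust` and `matrix` (the standardized matrix reordered by both
#'   dendrograms).
#' @export
clustergram <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_input("`x` must be numeric")
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  z <- x
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1
    z <- sweep(sweep(x, 2L, colMeans(x), "-"), 2L, sds, "/")
  }
  single_row <- nrow(z) < 2L
  single_col <- ncol(z) < 2L
  rh <- if (single_row) NULL else
    stats::hclust(stats::dist(z), method = "average")
  ch <- if (single_col) NULL else
    stats::hclust(stats::dist(t(z)), method = "average")
  ro <- if (single_row) 1L else rh$order
  co <- if (single_col) 1L else ch$order
  structure(list(row_hclust = rh, col_hclust = ch,
                 matrix = z[ro, co, drop = FALSE]),
            class = "clustergram")
}

#' @export
print.clustergram <- function(x, ...) {
  cat(sprintf("<clustergram: %d x %d standardized matrix, average linkage>\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Plot a clustergram as a dendrogram-ordered heatmap
#'
#' @param x A [clustergram()] object.
#' @param ... Passed to [stats::heatmap()].
#' @export
plot.clustergram <- function(x, ...) {
  stats::heatmap(
    x$matrix,
    Rowv = if (is.null(x$row_hclust)) NA else
      stats::as.dendrogram(x$row_hclust),
    Colv = if (is.null(x$col_hclust)) NA else
      stats::as.dendrogram(x$col_hclust),
    scale = "none", ...)
  invisible(x)
}

# Tukey-Kramer (Nemenyi-type) comparison of mean ranks after a
# Kruskal-Wallis test: the studentized-range statistic on rank means with
# infinite degrees of freedom.
tukey_kramer_ranks <- function(values, groups, alpha) {
  N <- length(values)
  r <- rank(values)
  gs <- split(r, groups)
  k <- length(gs)
  rbar <- vapply(gs, mean, numeric(1))
  ns <- lengths(gs)
  pairs <- utils::combn(names(gs), 2L)
  res <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    diff_rank_mean = NA_real_, q = NA_real_,
                    p_value = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    se <- sqrt(N * (N + 1) / 12 * (1 / ns[[a]] + 1 / ns[[b]]))
    delta <- abs(rbar[[a]] - rbar[[b]])
    q <- delta / se * sqrt(2)
    res$diff_rank_mean[i] <- delta
    res$q[i] <- q
    res$p_value[i] <- 1 - stats::ptukey(q, k, Inf)
  }
  res$significant <- res$p_value < alpha
  res
}

#' Nonparametric group comparison report
#'
#' For each group a Kolmogorov-Smirnov normality check (against a normal
#' with the group's moments) is reported.  Two groups are compared with the
#' Mann-Whitney (Wilcoxon rank-sum) test; more than two with the
#' Kruskal-Wallis test followed by Tukey-Kramer pairwise comparisons on rank
#' means (an approximation to the rank-based post hoc of common stats
#' environments).  Groups with fewer than 2 observations are excluded with
#' a warning.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label for each observation.
#' @param alpha Significance level for flags (default 0.05).
#' @return An object of class `group_test_report`: list with `normality`
#'   (per-group KS results), `omnibus` (Mann-Whitney U or Kruskal-Wallis H
#'   with p-value), `posthoc` (pairwise table, `NULL` for 2 groups) and
#'   `alpha`.
#' @export
group_tests <- function(values, groups, alpha = 0.05) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop_input("`values` and `groups` must have equal length")
  }
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("excluding groups with < 2 observations: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  gs <- split(values, groups)
  k <- length(gs)
  if (k < 2L) stop_input("need at least 2 groups with >= 2 observations")

  normality <- do.call(rbind, lapply(names(gs), function(g) {
    x <- gs[[g]]
    if (stats::sd(x) == 0) {
      return(data.frame(group = g, n = length(x), ks_stat = NA_real_,
                        p_value = NA_real_, normal = NA))
    }
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(group = g, n = length(x), ks_stat = unname(ks$statistic),
               p_value = ks$p.value, normal = ks$p.value >= alpha)
  }))

  posthoc <- NULL
  if (k == 2L) {
    wt <- suppressWarnings(
      stats::wilcox.test(gs[[1L]], gs[[2L]], exact = NULL))
    # report the classical (direction-free) U: the smaller of the two
    w <- unname(wt$statistic)
    u <- min(w, length(gs[[1L]]) * length(gs[[2L]]) - w)
    omnibus <- list(test = "mann_whitney", statistic = u,
                    p_value = wt$p.value,
                    significant = wt$p.value < alpha)
  } else {
    if (stats::sd(values) == 0) {
      omnibus <- list(test = "kruskal_wallis", statistic = 0, p_value = 1,
                      significant = FALSE)
    } else {
      kw <- stats::kruskal.test(values, factor(groups))
      omnibus <- list(test = "kruskal_wallis",
                      statistic = unname(kw$statistic),
                      p_value = kw$p.value,
                      significant = kw$p.value < alpha)
      posthoc <- tukey_kramer_ranks(values, groups, alpha)
    }
  }
  structure(list(normality = normality, omnibus = omnibus,
                 posthoc = posthoc, alpha = alpha),
            class = "group_test_report")
}

#' @export
print.group_test_report <- function(x, ...) {
  cat(sprintf("Group comparison (alpha = %g)\n", x$alpha))
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n",
              x$omnibus$test, x$omnibus$statistic, x$omnibus$p_value,
              if (isTRUE(x$omnibus$significant)) " *" else ""))
  cat("Normality (KS):\n")
  print(x$normality, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("Tukey-Kramer on rank means:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
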