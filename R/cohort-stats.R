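# Staging statistics over morphometric profile cohorts: per-variable
# Z-scores of class means against the control reference, PCA, and Ward
# hierarchical clustering that recovers the innervation groups.

profileMatrix <- function(profiles) {
  vars <- profileVariableNames()
  miss <- setdiff(vars, names(profiles))
  if (length(miss))
    stop("profiles lack variables: ", paste(miss, collapse = ", "))
  m <- as.matrix(profiles[, vars])
  rownames(m) <- profiles$sample_id
  m
}

#' Z-score matrix of class means against the control reference
#'
#' For each variable, z = (xbar - xbar_c) / sigma_c, where xbar is the mean
#' of the variable in a tissue class and xbar_c, sigma_c are the mean and
#' sample standard deviation (n - 1 denominator) in the control class. The
#' control row is identically zero; variables with sigma_c = 0 or with
#' undefined (NA) cells get flagged `NA` entries.
#'
#' @param profiles profile data.frame ([morphometricProfile()] layout) with
#'   a `class` column; every class must be non-empty and the control class
#'   needs at least 2 samples.
#' @param controlClass label of the reference class.
#' @return numeric matrix classes x 12 with attributes `controlMean` and
#'   `controlSd`.
#' @export
zscoreMatrix <- function(profiles, controlClass = "control") {
  m <- profileMatrix(profiles)
  cls <- profiles$class
  if (!controlClass %in% cls) stop("control class not present")
  ctrl <- m[cls == controlClass, , drop = FALSE]
  if (nrow(ctrl) < 2)
    stop("need at least 2 control samples to estimate sigma_c")
  xc <- colMeans(ctrl)
  sc <- apply(ctrl, 2, stats::sd)
  classes <- unique(cls)
  z <- t(vapply(classes, function(cl) {
    xbar <- colMeans(m[cls == cl, , drop = FALSE])
    out <- (xbar - xc) / sc
    out[sc == 0] <- NA_real_
    out
  }, numeric(ncol(m))))
  rownames(z) <- classes
  # control row is zero by definition wherever sigma_c > 0
  z[controlClass, sc > 0] <- 0
  attr(z, "controlMean") <- xc
  attr(z, "controlSd") <- sc
  z
}

dropUndefined <- function(m, what) {
  bad <- colSums(is.na(m)) > 0
  if (any(bad))
    message(sum(bad), " variable(s) with undefined cells excluded from ",
            what, ": ", paste(colnames(m)[bad], collapse = ", "))
  m[, !bad, drop = FALSE]
}

#' PCA embedding of a profile cohort
#'
#' Centres (and, with `standardize`, unit-variance scales) the 12 profile
#' variables and decomposes them; components are ordered by decreasing
#' variance and the sign of each component is fixed so that its
#' largest-magnitude loading is positive. Variables containing undefined
#' cells are excluded with a message; constant variables are dropped with a
#' warning when standardizing.
#'
#' @param profiles profile data.frame (>= 2 samples).
#' @param standardize scale variables to unit variance (default TRUE).
#' @return list with `scores`, `loadings`, `explainedVariance` (fractions
#'   summing to 1) and `dropped` (excluded variable names).
#' @export
pcaEmbed <- function(profiles, standardize = TRUE) {
  m <- profileMatrix(profiles)
  if (nrow(m) < 2) stop("need at least 2 samples")
  m <- dropUndefined(m, "PCA")
  dropped <- setdiff(profileVariableNames(), colnames(m))
  if (standardize) {
    cst <- apply(m, 2, stats::sd) == 0
    if (any(cst)) {
      warning("constant variable(s) dropped: ",
              paste(colnames(m)[cst], collapse = ", "))
      dropped <- c(dropped, colnames(m)[cst])
      m <- m[, !cst, drop = FALSE]
    }
  }
  if (ncol(m) < 2) stop("need at least 2 usable variables")
  pc <- stats::prcomp(m, center = TRUE, scale. = standardize)
  # sign convention: largest-|loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       explainedVariance = pc$sdev^2 / sum(pc$sdev^2),
       dropped = dropped)
}

#' Ward hierarchical clustering of a profile cohort
#'
#' Agglomerative clustering (Ward's criterion, `ward.D2`, on Euclidean
#' distances of per-variable standardized profiles) cut at `k` clusters;
#' mirrors the three-group staging of tissue samples into
#' control/asymptomatic, noninvasive neoplastic and invasive classes. When
#' reference labels are given the adjusted Rand index of the recovered
#' partition is reported.
#'
#' @param profiles profile data.frame.
#' @param k number of clusters (1 <= k <= n samples), default 3.
#' @param referenceLabels optional vector of true labels for ARI scoring.
#' @return list with `labels` (1..k, named by sample), `tree` (the
#'   [stats::hclust] object, merge heights in `tree$height`), `ari`
#'   (adjusted Rand index or `NA`).
#' @export
hierarchicalCluster <- function(profiles, k = 3, referenceLabels = NULL) {
  m <- profileMatrix(profiles)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nrow(m))
    stop("k must be between 1 and the number of samples")
  m <- dropUndefined(m, "clustering")
  keep <- apply(m, 2, stats::sd) > 0
  ms <- scale(m[, keep, drop = FALSE])
  tree <- stats::hclust(stats::dist(ms), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  ari <- if (!is.null(referenceLabels))
    mclust::adjustedRandIndex(labels, referenceLabels) else NA_real_
  list(labels = labels, tree = tree, ari = ari)
}
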