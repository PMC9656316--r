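#' Pearson chi-square test on a cross table
#'
#' Plain Pearson chi-square without continuity correction (the counts this
#' package feeds it are genome-scale, where a correction is negligible);
#' `df = (r - 1)(k - 1)`, p-value from the upper tail. Tables with any
#' expected cell below 1 are flagged but still computed.
#'
#' @param tab a matrix (or coercible) of non-negative counts, at least 2x2.
#' @return A list of class `scub_chisq`: `statistic`, `df`, `p.value`,
#'   `expected`, `low_expected`.
#' @export
chisq_crosstable <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(!is.finite(tab)) || any(tab < 0)) stop("cells must be finite and non-negative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("row and column totals must be positive")
  n <- sum(tab)
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = expected,
                 low_expected = any(expected < 1)),
            class = "scub_chisq")
}

#' @export
print.scub_chisq <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g%s\n", x$statistic, x$df,
              x$p.value, if (x$low_expected) " [low expected counts]" else ""))
  invisible(x)
}

#' Two-sample t-test (Welch by default)
#'
#' Implements the unequal-variance (Welch) t statistic with
#' Welch-Satterthwaite degrees of freedom, or the pooled-variance variant.
#' Two zero-variance samples with equal means return `t = 0, p = 1` by
#' convention.
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return A list of class `scub_ttest`: `t`, `df`, `p.value`, `mean_x`,
#'   `mean_y`.
#' @export
two_sample_t <- function(x, y, var_equal = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs n >= 2")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) {
      res <- list(t = 0, df = nx + ny - 2L, p.value = 1)
    } else {
      res <- list(t = sign(mx - my) * Inf, df = nx + ny - 2L, p.value = 0)
    }
    return(structure(c(res, mean_x = mx, mean_y = my), class = "scub_ttest"))
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  structure(list(t = t, df = df,
                 p.value = 2 * stats::pt(-abs(t), df),
                 mean_x = mx, mean_y = my), class = "scub_ttest")
}

#' @export
print.scub_ttest <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.2f, p = %.4g\n", x$t, x$df, x$p.value))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean.
#'
#' @param x numeric vector.
#' @return The CV as a single number; errors on a zero mean.
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(x) / m
}

.prepare_feature_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  drop <- colSums(is.na(m)) > 0
  if (any(drop)) {
    message("dropping ", sum(drop), " feature column(s) with missing values")
    m <- m[, !drop, drop = FALSE]
  }
  m
}

#' Average-linkage clustering on correlation distance
#'
#' Agglomerative clustering of the rows of a feature matrix with average
#' linkage on the distance `d = 1 - r`, `r` the Pearson correlation between
#' row vectors. Merge heights are also reported on the similarity scale
#' `100 * (1 - d / 2)` used by classic clustering software. Feature columns
#' containing missing values are dropped with a message.
#'
#' @param m numeric matrix; rows are scopes/species, columns named features.
#' @return A list of class `scub_dendrogram`: `hclust` (the [stats::hclust()]
#'   object), `distance_heights`, `similarity_heights`, `newick` (Newick
#'   string with distance-scale branch lengths), `n_features`.
#' @export
cluster_profiles <- function(m) {
  m <- .prepare_feature_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  if (ncol(m) < 2L) stop("need at least 2 complete feature columns")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant row(s): ", paste(rownames(m)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "average")
  structure(list(
    hclust = hc,
    distance_heights = hc$height,
    similarity_heights = 100 * (1 - hc$height / 2),
    newick = ape::write.tree(ape::as.phylo(hc)),
    n_features = ncol(m)), class = "scub_dendrogram")
}

#' @export
print.scub_dendrogram <- function(x, ...) {
  cat("average-linkage correlation-distance dendrogram over",
      length(x$hclust$labels), "rows\n", x$newick, "\n")
  invisible(x)
}

#' PCA scores of a feature matrix
#'
#' Principal component analysis of the (row-wise) feature matrix, centered by
#' column and optionally standardized. A deterministic sign convention is
#' applied: each component's loading vector is flipped so that its
#' largest-magnitude loading is positive. If the matrix has fewer than two
#' non-degenerate components, only the available ones are returned.
#'
#' @param m numeric matrix; rows are scopes/species.
#' @param standardize scale columns to unit variance (constant columns are
#'   dropped first when set).
#' @return A list of class `scub_pca`: `scores` (rows x up to 2 components),
#'   `loadings`, `var_explained` (fractions over all components),
#'   `n_components`.
#' @export
pca_scores <- function(m, standardize = FALSE) {
  m <- .prepare_feature_matrix(m)
  if (nrow(m) < 3L) stop("need at least 3 rows for a PC1-PC2 plane")
  if (standardize) {
    const <- apply(m, 2L, stats::sd) == 0
    if (any(const)) {
      message("dropping ", sum(const), " constant column(s) before scaling")
      m <- m[, !const, drop = FALSE]
    }
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = standardize)
  tol <- max(pc$sdev) * 1e-10
  navail <- sum(pc$sdev > tol)
  k <- min(2L, navail)
  if (k < 2L) message("only ", k, " non-degenerate component(s) available")
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    var_explained = ve,
    n_components = k), class = "scub_pca")
}

#' @export
print.scub_pca <- function(x, ...) {
  cat(sprintf("PCA: %d component(s); var explained: %s\n", x$n_components,
              paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(x$n_components)]),
                    collapse = ", ")))
  invisible(x)
}
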