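# Intratumoral heterogeneity from cancer-cell-fraction (CCF) distributions:
# the AUC of the empirical CCF CDF, pairwise Kolmogorov-Smirnov distances,
# and Ward clustering into clonal groups.

#' Heterogeneity score: area under the empirical CCF CDF
#'
#' The exact integral over [0, 1] of the right-continuous empirical CDF of
#' the tumor's CCF values, computed as the sum of the rectangles between
#' consecutive sorted values (no numerical quadrature). A fully clonal tumor
#' (all CCF = 1) scores 0; mass concentrated near 0 pushes the score toward
#' 1.
#'
#' @param ccfs numeric vector of cancer cell fractions in (0, 1].
#' @return score in `[0, 1]`.
#' @export
heterogeneity_score <- function(ccfs) {
  if (!length(ccfs)) stop("need >= 1 CCF value")
  if (any(ccfs <= 0 | ccfs > 1)) stop("CCF values must lie in (0, 1]")
  s <- sort(ccfs)
  n <- length(s)
  # F(x) = i/n on [s_i, s_{i+1}); 0 before s_1; rectangle sum up to 1
  sum((c(s[-1L], 1) - s) * seq_len(n) / n)
}

# Empirical-CDF KS distance between two samples, exact sup over the pooled
# breakpoints.
ks_distance <- function(x, y) {
  br <- sort(unique(c(x, y)))
  fx <- findInterval(br, sort(x)) / length(x)
  fy <- findInterval(br, sort(y)) / length(y)
  max(abs(fx - fy))
}

#' Pairwise Kolmogorov-Smirnov D matrix of CCF distributions
#'
#' @param tables named list, tumor -> CCF vector (each non-empty), or a
#'   data frame with `tumor_id` and `ccf` columns.
#' @return symmetric tumors x tumors matrix of D statistics with zero
#'   diagonal.
#' @export
pairwise_ks <- function(tables) {
  if (is.data.frame(tables)) tables <- split(tables$ccf, tables$tumor_id)
  if (length(tables) < 2L) stop("need >= 2 tumors")
  if (any(!lengths(tables))) stop("empty CCF table")
  ids <- names(tables)
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)[-1L]) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- ks_distance(tables[[i]], tables[[j]])
    }
  }
  d
}

#' Cluster tumors into clonal groups from the KS-D matrix
#'
#' Rows of the D matrix are treated as feature vectors and clustered
#' agglomeratively with the Ward criterion on Euclidean distances
#' (`method = "rows"`, default, honoring both the Euclidean measure and the
#' Ward agglomeration); `method = "direct"` instead uses D itself as the
#' distance with average linkage.
#'
#' @param d symmetric KS-D matrix from [pairwise_ks()].
#' @param k number of groups (default 4).
#' @param method `"rows"` or `"direct"` (see above).
#' @return named integer vector, tumor -> group label.
#' @export
cluster_clonal_groups <- function(d, k = 4L, method = c("rows", "direct")) {
  method <- match.arg(method)
  if (k < 1L || k > nrow(d)) stop("k must be in 1..n tumors")
  hc <- switch(method,
               rows = stats::hclust(stats::dist(d), method = "ward.D2"),
               direct = stats::hclust(stats::as.dist(d), method = "average"))
  stats::cutree(hc, k = k)
}
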