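# Lasso-regularized model of tumor immunogenicity: predict cytotoxic-cell
# presence from tumor-intrinsic and -extrinsic feature blocks.

#' Cytotoxicity score: mean of the CD8, NK and Tgd summaries
#'
#' @param x patients x components matrix or data frame containing all three
#'   named components.
#' @param components the three column names to average.
#' @return named numeric vector, patient -> score.
#' @export
cytotoxicity_score <- function(x, components = c("Tem_CD8", "NK", "Tgd")) {
  missing_c <- setdiff(components, colnames(x))
  if (length(missing_c))
    stop("missing cytotoxicity component(s): ",
         paste(missing_c, collapse = ", "))
  rowMeans(as.matrix(x[, components, drop = FALSE]))
}

#' Assemble and standardize the immunogenicity feature matrix
#'
#' Column-binds the configured feature blocks over their shared patients
#' (complete-case: patients missing from any block are listed and excluded),
#' drops zero-variance columns with a warning, and standardizes every
#' feature to mean 0 / sd 1, recording the standardization metadata and the
#' block provenance per column.
#'
#' @param blocks named list of patients x features matrices or data frames
#'   (rownames are patient IDs).
#' @return list with `X` (standardized matrix), `center`, `scale`,
#'   `provenance` (block of origin per column), `excluded_patients`.
#' @export
assemble_features <- function(blocks) {
  if (!length(blocks) || is.null(names(blocks)))
    stop("blocks must be a non-empty named list")
  blocks <- lapply(blocks, function(b) as.matrix(b))
  shared <- Reduce(intersect, lapply(blocks, rownames))
  all_pat <- unique(unlist(lapply(blocks, rownames)))
  excluded <- setdiff(all_pat, shared)
  if (length(excluded))
    warning("excluding ", length(excluded),
            " patient(s) missing from some block(s)")
  if (!length(shared)) stop("no patients shared by all blocks")

  X <- do.call(cbind, lapply(blocks, function(b) b[shared, , drop = FALSE]))
  provenance <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    provenance <- provenance[sds > 0]
    X <- X[, sds > 0, drop = FALSE]
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Xs <- scale(X, center = ctr, scale = scl)
  list(X = Xs, center = ctr, scale = scl,
       provenance = stats::setNames(provenance, colnames(X)),
       excluded_patients = excluded)
}

#' Fit the lasso immunogenicity model with post-selection refit
#'
#' The lasso path is fit with `glmnet`; lambda is chosen by inner
#' cross-validation on mean squared error. Features with nonzero lasso
#' coefficients are refit by ordinary least squares, their p-values
#' BH-adjusted, and the final model keeps features with adjusted
#' p < `p_threshold` (default 0.005). When `outer_cv` is `TRUE`, a seeded
#' outer 10-fold cross-validation (nested: lambda re-chosen within each
#' training fold) reports per-fold and mean R-squared and MSE on held-out
#' patients.
#'
#' @param X standardized patients x features matrix.
#' @param y response (cytotoxicity score).
#' @param n_folds folds for both CV layers (default 10).
#' @param p_threshold adjusted-p threshold for the final model.
#' @param seed fold-assignment and glmnet seed.
#' @param outer_cv run the outer CV loop (default TRUE).
#' @param lambda optional fixed penalty overriding the cross-validated
#'   choice.
#' @return list with `lambda`, `lambda_path`, `coefficients` (lasso,
#'   at the chosen lambda), `refit` (feature, estimate, p, adj_p),
#'   `selected` (features passing the adjusted-p filter, with signs),
#'   `cv` (per-fold and mean R2/MSE; `NULL` when `outer_cv = FALSE`).
#' @export
fit_lasso_model <- function(X, y, n_folds = 10L, p_threshold = 0.005,
                            seed = 1L, outer_cv = TRUE, lambda = NULL) {
  n <- nrow(X)
  if (n_folds < 2L || n_folds > n) stop("n_folds must be in 2..n patients")
  set.seed(seed)

  cvfit <- glmnet::cv.glmnet(X, y, nfolds = n_folds)
  if (is.null(lambda)) lambda <- cvfit$lambda.min
  beta <- stats::coef(cvfit, s = lambda, exact = FALSE)
  beta <- stats::setNames(as.numeric(beta)[-1L], rownames(beta)[-1L])
  nonzero <- names(beta)[beta != 0]

  refit <- data.frame(feature = character(0), estimate = numeric(0),
                      p = numeric(0), adj_p = numeric(0))
  selected <- character(0)
  if (length(nonzero)) {
    df <- data.frame(y = y, X[, nonzero, drop = FALSE], check.names = FALSE)
    fit <- stats::lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    feat <- sub("^`|`$", "", rownames(sm))
    refit <- data.frame(feature = feat, estimate = sm[, 1L],
                        p = sm[, 4L],
                        adj_p = stats::p.adjust(sm[, 4L], "BH"),
                        row.names = NULL)
    selected <- refit$feature[refit$adj_p < p_threshold]
  }

  cv <- NULL
  if (outer_cv) {
    fold <- sample(rep(seq_len(n_folds), length.out = n))
    r2 <- mse <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      cf <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], nfolds = n_folds)
      pred <- as.numeric(stats::predict(cf, X[!tr, , drop = FALSE],
                                        s = "lambda.min"))
      mse[f] <- mean((y[!tr] - pred)^2)
      r2[f] <- 1 - sum((y[!tr] - pred)^2) / sum((y[!tr] - mean(y[tr]))^2)
    }
    cv <- list(fold_r2 = r2, fold_mse = mse,
               mean_r2 = mean(r2), mean_mse = mean(mse))
  }
  list(lambda = lambda, lambda_path = cvfit$lambda,
       coefficients = beta, refit = refit, selected = selected,
       cv = cv)
}
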