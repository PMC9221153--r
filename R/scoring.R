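.designMatrix <- function(features) {
  need <- c("n_a", "n_t", "n_c", "n_g", "g3")
  miss <- setdiff(need, colnames(features))
  if (length(miss))
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  X <- cbind(as.matrix(features[, need]), 1)
  colnames(X) <- .MODEL_TERMS
  X
}

#' Fit the weighted linear sequence-score model
#'
#' Estimates the weights `p_A, p_T, p_C, p_G, p_3` and intercept `I` of the
#' sequence score
#' `score = p_A*n_A + p_T*n_T + p_C*n_C + p_G*n_G + p_3*g_3 + I`
#' by ordinary least squares against measured calcium oscillation scores
#' (percent of untreated control), via QR decomposition as implemented in
#' [stats::lm()].  Per-term significance is assessed with the t statistic on
#' the residual degrees of freedom, two-sided.
#'
#' Scores are used raw (uncapped) by default; display-style capping of
#' extreme scores can be requested via `cap` but is not applied when fitting
#' unless asked for.
#'
#' @param features feature table from [featureTable()] (or any data.frame
#'   with columns `n_a`, `n_t`, `n_c`, `n_g`, `g3`).
#' @param scores numeric calcium oscillation score per row of `features`.
#' @param cap optional upper cap applied to `scores` before fitting
#'   (default `NULL`, no capping).
#' @return a [ScoreModel-class].
#' @examples
#' target <- simulateTargetPremrna(2000, seed = 1)
#' panel <- tileAsos(target, 50, seed = 1)
#' truth <- c(p_A = 3, p_T = 1, p_C = 1, p_G = -8, p_3 = 1, I = 20)
#' y <- simulateCalciumScores(panel, truth, noiseSd = 0, seed = 1)
#' fitScoreModel(featureTable(panel), y)
#' @export
fitScoreModel <- function(features, scores, cap = NULL) {
  X <- .designMatrix(features)
  y <- as.numeric(scores)
  if (length(y) != nrow(X))
    stop("'scores' must have one value per feature row")
  if (anyNA(X) || anyNA(y)) stop("features and scores must be complete")
  if (nrow(X) < 7L)
    stop("need at least 7 observations to fit the 6-parameter model; got ",
         nrow(X))
  if (!is.null(cap)) y <- pmin(y, cap)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- data.frame(y = y, n_a = X[, 1], n_t = X[, 2], n_c = X[, 3],
                   n_g = X[, 4], g3 = X[, 5])
  fit <- stats::lm(y ~ n_a + n_t + n_c + n_g + g3, data = df)
  # noiseless inputs fit exactly; summary()'s perfect-fit warning is expected
  sfit <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- sfit$coefficients
  ord <- c("n_a", "n_t", "n_c", "n_g", "g3", "(Intercept)")
  sm <- sm[ord, , drop = FALSE]
  new("ScoreModel",
      coefficients = stats::setNames(sm[, "Estimate"], .MODEL_TERMS),
      se = unname(sm[, "Std. Error"]),
      tval = unname(sm[, "t value"]),
      pval = unname(sm[, "Pr(>|t|)"]),
      nObs = nrow(X),
      sigma2 = sfit$sigma^2)
}

#' Extract model coefficients
#'
#' @param object a [ScoreModel-class].
#' @param ... ignored.
#' @return named numeric vector `p_A, p_T, p_C, p_G, p_3, I`.
#' @export
setMethod("coef", "ScoreModel", function(object, ...) object@coefficients)

#' Coefficient summary table
#'
#' @param model a [ScoreModel-class].
#' @return data.frame with columns `term`, `estimate`, `std_error`,
#'   `t_value`, `p_value`.
#' @export
coefTable <- function(model) {
  stopifnot(is(model, "ScoreModel"))
  data.frame(term = .MODEL_TERMS, estimate = unname(model@coefficients),
             std_error = model@se, t_value = model@tval,
             p_value = model@pval, stringsAsFactors = FALSE)
}

setMethod("show", "ScoreModel", function(object) {
  cat(sprintf(
    "ScoreModel (ordinary least squares, n = %d, residual sd = %.3f)\n",
    object@nObs, sqrt(object@sigma2)))
  print(coefTable(object), row.names = FALSE, digits = 4)
})

#' Calculate the sequence score
#'
#' Applies a fitted (or manually specified) linear model to sequence
#' features: the exact weighted sum
#' `p_A*n_A + p_T*n_T + p_C*n_C + p_G*n_G + p_3*g_3 + I`.
#' Higher scores predict safer ASOs (weaker reduction of spontaneous
#' calcium oscillations).
#'
#' @param model a [ScoreModel-class], or a named numeric vector with
#'   elements `p_A, p_T, p_C, p_G, p_3, I`.
#' @param features a feature table ([featureTable()]) or an
#'   [AsoPanel-class] (features are computed on the fly).
#' @param rounded if `TRUE`, round scores to integers (the convention used
#'   when printing design tables).  Default `FALSE` (raw scores).
#' @return named numeric vector of scores on the calcium-score scale.
#' @export
calculateScore <- function(model, features, rounded = FALSE) {
  beta <- if (is(model, "ScoreModel")) model@coefficients else model
  if (!all(.MODEL_TERMS %in% names(beta)))
    stop("model coefficients must be named ",
         paste(.MODEL_TERMS, collapse = ", "))
  if (is(features, "AsoPanel")) features <- featureTable(features)
  X <- .designMatrix(features)
  s <- drop(X %*% beta[.MODEL_TERMS])
  if (!is.null(features$id)) names(s) <- features$id
  if (rounded) s <- round(s)
  s
}

#' Write scores as TSV
#'
#' @param scores named numeric vector from [calculateScore()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeScores <- function(scores, path) {
  utils::write.table(
    data.frame(id = names(scores), calculated_score = unname(scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist / restore a fitted model as JSON
#'
#' @param model a [ScoreModel-class].
#' @param path JSON file.
#' @return `writeScoreModel` returns `path` invisibly; `readScoreModel`
#'   returns the restored [ScoreModel-class].
#' @export
writeScoreModel <- function(model, path) {
  stopifnot(is(model, "ScoreModel"))
  jsonlite::write_json(
    list(coefficients = as.list(model@coefficients),
         standard_errors = model@se, t_values = model@tval,
         p_values = model@pval, n_obs = model@nObs,
         residual_variance = model@sigma2),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScoreModel
#' @export
readScoreModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ScoreModel",
      coefficients = stats::setNames(
        as.numeric(x$coefficients[.MODEL_TERMS]), .MODEL_TERMS),
      se = as.numeric(x$standard_errors),
      tval = as.numeric(x$t_values),
      pval = as.numeric(x$p_values),
      nObs = as.integer(x$n_obs),
      sigma2 = as.numeric(x$residual_variance))
}

#' Spearman rank correlation with t-approximation
#'
#' Spearman's rho computed as the Pearson correlation of mid-ranks
#' (average ranks for ties), with significance from the asymptotic
#' Student-t approximation: `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom, two-sided.  For `|rho| = 1` the p value
#' is exactly 0 under this approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearmanTest <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("rank correlation is undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Per-feature Spearman correlations with scores
#'
#' For each feature column, the Spearman rank correlation (and its
#' t-approximation p value) between the feature and the score, together
#' with median scores per distinct feature value — the count-versus-median
#' summaries used to judge approximate linearity of each association.
#'
#' @param features feature table from [featureTable()].
#' @param scores numeric score per row.
#' @param columns feature columns to analyze; defaults to all numeric
#'   feature columns.
#' @return list with `correlations` (data.frame: `feature`, `rho`,
#'   `p_value`) and `medians` (named list of data.frames `value`,
#'   `median_score`, `n`).  Constant columns are excluded with a warning.
#' @export
featureScoreCorrelations <- function(features, scores,
                                     columns = c("length", "n_lna",
                                                 "gap_length", "n_a", "n_t",
                                                 "n_c", "n_g", "g3", "g5")) {
  columns <- intersect(columns, colnames(features))
  scores <- as.numeric(scores)
  stopifnot(length(scores) == nrow(features))
  keep <- character(); rows <- list(); med <- list()
  for (col in columns) {
    v <- as.numeric(features[[col]])
    if (length(unique(v)) < 2L) {
      warning("feature '", col, "' is constant; excluded from correlations")
      next
    }
    st <- spearmanTest(v, scores)
    keep <- c(keep, col)
    rows[[col]] <- data.frame(feature = col, rho = st$rho,
                              p_value = st$p_value,
                              stringsAsFactors = FALSE)
    agg <- stats::aggregate(scores, by = list(value = v),
                            FUN = stats::median)
    cnt <- stats::aggregate(scores, by = list(value = v), FUN = length)
    med[[col]] <- data.frame(value = agg$value, median_score = agg$x,
                             n = cnt$x)
  }
  list(correlations = do.call(rbind, unname(rows)), medians = med)
}
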