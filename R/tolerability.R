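#' Aggregate per-mouse behavioral scores into a group tolerability score
#'
#' Acute tolerability of an ICV-dosed ASO is scored per mouse over five
#' behavioral categories (hyperactivity; decreased activity and arousal;
#' motor dysfunction/ataxia; abnormal posture and breathing;
#' tremor/convulsions), each on an integer 0-4 scale.  The five category
#' scores are summed to a per-mouse total in `[0, 20]` (0 = no side
#' effects, 20 = severe signs in every category) and the totals are
#' averaged over the treatment group (typically 4-6 mice) to give the
#' ASO's representative score.
#'
#' @param mice a numeric matrix (one row per mouse, five category columns)
#'   or a list of length-5 integer vectors.
#' @return list with `group_mean`, per-mouse `totals`, and the validated
#'   `categories` matrix.
#' @examples
#' aggregateTolerability(rbind(c(1, 0, 2, 0, 0), c(0, 0, 1, 0, 0)))$group_mean
#' @export
aggregateTolerability <- function(mice) {
  if (is.list(mice) && !is.data.frame(mice)) mice <- do.call(rbind, mice)
  mice <- as.matrix(mice)
  if (ncol(mice) != 5L)
    stop("each mouse needs exactly 5 category scores; got ", ncol(mice))
  if (nrow(mice) < 1L || nrow(mice) > 10L)
    stop("expected 1-10 mice per group; got ", nrow(mice))
  if (any(mice != round(mice)) || any(mice < 0) || any(mice > 4))
    stop("category scores must be integers in [0, 4]")
  totals <- rowSums(mice)
  list(group_mean = mean(totals), totals = unname(totals),
       categories = unname(mice))
}

.SEVERITY_LEVELS <- c("mild", "moderate", "marked", "severe")

#' Bin tolerability scores into severity classes
#'
#' Group-mean acute tolerability scores are partitioned into the four
#' severity classes at thresholds 4, 7 and 18:
#' mild `[0, 4)`, moderate `[4, 7)`, marked `[7, 18]`, severe `(18, 20]`.
#' A score of exactly 4 is moderate under this binning, yet still counts as
#' *acceptable* for the binary classification task (see [binaryLabel()],
#' which follows the explicit "at or below 4" acceptability rule); the two
#' conventions are deliberately distinct and both documented here.
#'
#' @param score numeric vector of scores in `[0, 20]`.
#' @return ordered factor with levels mild < moderate < marked < severe.
#' @export
classifySeverity <- function(score) {
  score <- as.numeric(score)
  if (anyNA(score) || any(score < 0 | score > 20))
    stop("tolerability scores must lie in [0, 20]")
  cls <- ifelse(score < 4, "mild",
         ifelse(score < 7, "moderate",
         ifelse(score <= 18, "marked", "severe")))
  factor(cls, levels = .SEVERITY_LEVELS, ordered = TRUE)
}

#' Binary acceptability label
#'
#' An ASO is *acceptable* for further development when its group-mean acute
#' tolerability score is at or below 4 (no or mild signs); above 4 it is
#' labelled *toxic* (moderate-to-severe signs).
#'
#' @param score numeric vector of scores in `[0, 20]`.
#' @return factor with levels `acceptable`, `toxic`.
#' @export
binaryLabel <- function(score) {
  score <- as.numeric(score)
  if (anyNA(score) || any(score < 0 | score > 20))
    stop("tolerability scores must lie in [0, 20]")
  factor(ifelse(score <= 4, "acceptable", "toxic"),
         levels = c("acceptable", "toxic"))
}

.asToxic <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("acceptable", "toxic"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
    labels == "toxic"
  } else as.logical(labels)
}

#' ROC curve and AUC for a safety score
#'
#' Receiver operating characteristic analysis of a per-ASO predictor where
#' higher values predict *safer* ASOs.  The positive class is toxic; an ASO
#' is predicted toxic when its predictor value is at or below the moving
#' threshold.  The AUC is computed through the rank (Mann-Whitney)
#' identity and equals the probability that a randomly chosen toxic ASO
#' scores lower than a randomly chosen acceptable one, with ties counted
#' one half.
#'
#' @param predictor numeric vector (calculated sequence score or measured
#'   calcium oscillation score).
#' @param labels binary labels: a factor from [binaryLabel()], or a logical
#'   vector with `TRUE` = toxic.
#' @return list with `points` (data.frame `cutoff`, `fpr`, `tpr`; one row
#'   per distinct threshold, anchored at (0,0) and (1,1)) and `auc`.
#' @export
rocCurve <- function(predictor, labels) {
  toxic <- .asToxic(labels)
  predictor <- as.numeric(predictor)
  stopifnot(length(predictor) == length(toxic))
  if (!any(toxic) || all(toxic))
    stop("both classes must be present for a ROC analysis")
  nT <- sum(toxic); nA <- sum(!toxic)
  r <- rank(predictor)  # mid-ranks: ties counted 1/2
  auc <- (sum(r[!toxic]) - nA * (nA + 1) / 2) / (nA * nT)
  cuts <- sort(unique(predictor))
  pts <- t(vapply(cuts, function(ct) {
    predToxic <- predictor <= ct
    c(tpr = sum(predToxic & toxic) / nT,
      fpr = sum(predToxic & !toxic) / nA)
  }, c(tpr = 0, fpr = 0)))
  points <- data.frame(cutoff = c(-Inf, cuts),
                       fpr = c(0, pts[, "fpr"]),
                       tpr = c(0, pts[, "tpr"]))
  list(points = points, auc = auc)
}

#' Write ROC points as TSV
#'
#' @param roc output of [rocCurve()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeRoc <- function(roc, path) {
  utils::write.table(roc$points[, c("fpr", "tpr", "cutoff")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classification accuracy as a function of the score cutoff
#'
#' For every cutoff `c` in the grid, ASOs with predictor strictly above `c`
#' are predicted acceptable and accuracy against the true binary labels is
#' recorded.  The optimal cutoff is reported as the midpoint of the maximal
#' plateau: the longest contiguous run of grid cutoffs achieving the top
#' accuracy (ties broken toward the first such run).
#'
#' @inheritParams rocCurve
#' @param grid numeric vector of candidate cutoffs (default integers
#'   0-200, the calcium-score scale).
#' @return list with `curve` (data.frame `cutoff`, `accuracy`),
#'   `best_accuracy`, and `best_cutoff` (plateau midpoint).
#' @export
accuracyVsCutoff <- function(predictor, labels, grid = 0:200) {
  toxic <- .asToxic(labels)
  predictor <- as.numeric(predictor)
  stopifnot(length(predictor) == length(toxic))
  if (length(grid) == 0L) stop("cutoff grid must be non-empty")
  if (!any(toxic) || all(toxic))
    stop("both classes must be present")
  grid <- sort(grid)
  acc <- vapply(grid, function(ct)
    mean((predictor <= ct) == toxic), numeric(1))
  best <- max(acc)
  at <- abs(acc - best) < 1e-12
  runs <- rle(at)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  pick <- cand[which.max(runs$lengths[cand])]
  plateau <- grid[starts[pick]:ends[pick]]
  list(curve = data.frame(cutoff = grid, accuracy = acc),
       best_accuracy = best,
       best_cutoff = mean(range(plateau)))
}

#' Confusion-matrix report at a fixed cutoff
#'
#' Predicted-toxic means predictor at or below the cutoff (higher score =
#' safer).  Positive class is toxic, so sensitivity is the fraction of
#' truly toxic ASOs flagged, and NPV — the fraction of predicted-safe ASOs
#' that are truly safe — measures how clean a score-filtered pipeline would
#' be.  Metrics with a zero denominator are reported as `NaN` with a
#' warning.
#'
#' @inheritParams rocCurve
#' @param cutoff numeric score cutoff.
#' @return a [ClassificationReport-class].
#' @export
classificationReport <- function(predictor, labels, cutoff) {
  toxic <- .asToxic(labels)
  predictor <- as.numeric(predictor)
  stopifnot(length(predictor) == length(toxic), length(cutoff) == 1L)
  if (!any(toxic) || all(toxic))
    stop("both classes must be present")
  predToxic <- predictor <= cutoff
  tp <- sum(predToxic & toxic); fp <- sum(predToxic & !toxic)
  tn <- sum(!predToxic & !toxic); fn <- sum(!predToxic & toxic)
  frac <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      NaN
    } else num / den
  }
  new("ClassificationReport",
      tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      accuracy = (tp + tn) / (tp + fp + tn + fn),
      sensitivity = frac(tp, tp + fn, "sensitivity"),
      specificity = frac(tn, tn + fp, "specificity"),
      ppv = frac(tp, tp + fp, "PPV"),
      npv = frac(tn, tn + fn, "NPV"),
      cutoff = as.numeric(cutoff))
}

#' Convert a report to a list / JSON
#'
#' @param report a [ClassificationReport-class].
#' @param path optional JSON output file.
#' @return `reportAsList` returns a named list; `writeReport` writes JSON
#'   and returns `path` invisibly.
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "ClassificationReport"))
  list(cutoff = report@cutoff,
       tp = report@tp, fp = report@fp, tn = report@tn, fn = report@fn,
       accuracy = report@accuracy, sensitivity = report@sensitivity,
       specificity = report@specificity, ppv = report@ppv,
       npv = report@npv)
}

#' @rdname reportAsList
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(reportAsList(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport (positive class = toxic, cutoff = %g)\n",
              object@cutoff))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              object@tp, object@fp, object@tn, object@fn))
  cat(sprintf(
    "  accuracy %.3f  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
    object@accuracy, object@sensitivity, object@specificity, object@ppv,
    object@npv))
})

#' Kruskal-Wallis rank-sum test across score groups
#'
#' Tie-corrected H statistic with a chi-squared approximation on `k - 1`
#' degrees of freedom, as implemented in [stats::kruskal.test()].  Used to
#' compare calcium-oscillation or calculated-score distributions across the
#' four tolerability classes (one group-mean value per ASO).
#'
#' @param groups a list of at least two non-empty numeric vectors.
#' @return list with `H`, `p_value`, `df`.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group must be non-empty")
  if (sum(lengths(groups)) < 3L) stop("need at least 3 observations in total")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}
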