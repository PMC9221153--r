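#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.GAPMER_ALPHABET <- c("A", "C", "G", "T")

#' AsoPanel: an ordered collection of annotated LNA/DNA gapmers
#'
#' An `AsoPanel` holds a set of antisense oligonucleotide (ASO) gapmer
#' sequences together with per-position chemistry flags and optional per-ASO
#' annotations.  Each ASO is stored 5'->3' as an uppercase base string over
#' `{A,C,G,T}` plus a parallel modification string over `{L,D}` (`L` = locked
#' nucleic acid, `D` = DNA).  All ASOs carry a full phosphorothioate (PS)
#' backbone; backbone chemistry is a constant tag, not a per-position flag.
#'
#' @slot ids character vector of unique ASO identifiers.
#' @slot bases character vector of uppercase base strings (5'->3').
#' @slot mods character vector of modification strings, same lengths as
#'   `bases`, alphabet `{L,D}`.
#' @slot annot a [S4Vectors::DataFrame] of per-ASO annotations with one row
#'   per ASO; the columns `calcium_score` and `tolerability_score` are used by
#'   downstream modeling when present.
#'
#' @seealso [AsoPanel()], [parseGapmer()], [readPanel()], [featureTable()]
#' @exportClass AsoPanel
setClass("AsoPanel",
  representation(
    ids = "character",
    bases = "character",
    mods = "character",
    annot = "DataFrame"
  )
)

setValidity("AsoPanel", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@bases) != n || length(object@mods) != n)
    msg <- c(msg, "ids, bases and mods must have equal length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, sprintf(
      "duplicate ASO ids: %s",
      paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
  if (nrow(object@annot) != n)
    msg <- c(msg, "annot must have one row per ASO")
  if (n > 0) {
    if (any(nchar(object@bases) != nchar(object@mods)))
      msg <- c(msg, "bases and mods must have matching per-ASO lengths")
    len <- nchar(object@bases)
    if (any(len < 10L | len > 25L))
      msg <- c(msg, "ASO length must be between 10 and 25 nt")
    if (any(grepl("[^ACGT]", object@bases)))
      msg <- c(msg, "bases must be uppercase strings over {A,C,G,T}")
    if (any(grepl("[^LD]", object@mods)))
      msg <- c(msg, "mods must be strings over {L,D}")
  }
  if (length(msg)) msg else TRUE
})

#' ScoreModel: fitted weighted linear sequence-score model
#'
#' The model expresses a predicted calcium-oscillation score (percent of
#' untreated control; higher = safer) as a weighted linear combination of
#' five sequence features plus an intercept:
#'
#' score = p_A*n_A + p_T*n_T + p_C*n_C + p_G*n_G + p_3*g_3 + I
#'
#' where `n_A`, `n_T`, `n_C`, `n_G` count each nucleobase, `g_3` is the
#' length of the G-free stretch from the 3' end, and the weights plus
#' intercept `I` are estimated by ordinary least squares against measured
#' calcium oscillation scores.
#'
#' @slot coefficients named numeric of length 6: `p_A, p_T, p_C, p_G, p_3, I`.
#' @slot se,tval,pval per-coefficient standard errors, t statistics and
#'   two-sided p values (residual degrees of freedom `nObs - 6`).
#' @slot nObs number of training observations.
#' @slot sigma2 residual variance of the fit.
#'
#' @seealso [fitScoreModel()], [calculateScore()], [writeScoreModel()]
#' @exportClass ScoreModel
setClass("ScoreModel",
  representation(
    coefficients = "numeric",
    se = "numeric",
    tval = "numeric",
    pval = "numeric",
    nObs = "integer",
    sigma2 = "numeric"
  )
)

.MODEL_TERMS <- c("p_A", "p_T", "p_C", "p_G", "p_3", "I")

setValidity("ScoreModel", function(object) {
  msg <- character()
  if (!identical(names(object@coefficients), .MODEL_TERMS))
    msg <- c(msg, "coefficients must be named p_A, p_T, p_C, p_G, p_3, I")
  for (s in c("se", "tval", "pval"))
    if (length(slot(object, s)) != 6L)
      msg <- c(msg, sprintf("%s must have length 6", s))
  if (any(object@se < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be non-negative")
  if (any(object@pval < 0 | object@pval > 1, na.rm = TRUE))
    msg <- c(msg, "p values must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' FliprTrace: a 1 Hz FLIPR calcium fluorescence trace
#'
#' Fluorescence readings sampled at exactly 1 reading per second, segmented
#' according to the plate-read protocol: a 100 s `baseline` read before
#' compound addition, a 200 s `post_addition` read, and (after a pause that
#' is not sampled) a 300 s `second_read`.  Segment lengths are configurable;
#' the defaults match that protocol.
#'
#' @slot samples numeric vector of non-negative fluorescence values.
#' @slot segment character vector, same length as `samples`, labelling each
#'   1 s read with its protocol segment.
#' @slot well well identifier.
#' @slot treatment treatment label (e.g. `"control"`, an ASO id, `"vehicle"`).
#'
#' @seealso [FliprTrace()], [oscillationScore()], [countPeaks()]
#' @exportClass FliprTrace
setClass("FliprTrace",
  representation(
    samples = "numeric",
    segment = "character",
    well = "character",
    treatment = "character"
  )
)

setValidity("FliprTrace", function(object) {
  msg <- character()
  if (length(object@samples) != length(object@segment))
    msg <- c(msg, "samples and segment must have equal length")
  if (any(object@samples < 0))
    msg <- c(msg, "fluorescence values must be non-negative")
  if (length(object@well) != 1L || length(object@treatment) != 1L)
    msg <- c(msg, "well and treatment must be single strings")
  if (length(msg)) msg else TRUE
})

#' ClassificationReport: confusion counts and derived metrics
#'
#' Binary tolerability classification of ASOs from a safety score.  The
#' positive class is *toxic* (group-mean acute tolerability score > 4);
#' an ASO is predicted toxic when its score is at or below the cutoff
#' (higher score = safer).  NPV, the negative predictive value, is the
#' fraction of predicted-safe ASOs that are truly safe.
#'
#' @slot tp,fp,tn,fn confusion counts (positive class = toxic).
#' @slot accuracy,sensitivity,specificity,ppv,npv derived fractions in
#'   `[0,1]`; `NaN` (with a warning at construction) when a denominator
#'   is zero.
#' @slot cutoff the score cutoff used.
#'
#' @seealso [classificationReport()], [rocCurve()], [accuracyVsCutoff()]
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  representation(
    tp = "integer", fp = "integer", tn = "integer", fn = "integer",
    accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
    ppv = "numeric", npv = "numeric", cutoff = "numeric"
  )
)

setValidity("ClassificationReport", function(object) {
  counts <- c(object@tp, object@fp, object@tn, object@fn)
  msg <- character()
  if (any(counts < 0)) msg <- c(msg, "confusion counts must be non-negative")
  ok <- function(x) all(is.nan(x) | (x >= 0 & x <= 1))
  if (!ok(c(object@accuracy, object@sensitivity, object@specificity,
            object@ppv, object@npv)))
    msg <- c(msg, "metrics must be in [0,1] or NaN")
  if (length(msg)) msg else TRUE
})
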