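.DEFAULT_PROTOCOL <- c(baseline = 100L, post_addition = 200L,
                       second_read = 300L)

#' Construct a FLIPR trace
#'
#' @param samples numeric fluorescence readings at 1 reading/s.
#' @param protocol named integer vector of segment lengths in seconds, in
#'   trace order; defaults to the plate protocol
#'   `c(baseline = 100, post_addition = 200, second_read = 300)`.  The sum
#'   must equal `length(samples)`.
#' @param well,treatment labels.
#' @return a [FliprTrace-class].
#' @export
FliprTrace <- function(samples, protocol = .DEFAULT_PROTOCOL,
                       well = "w01", treatment = "control") {
  samples <- as.numeric(samples)
  if (sum(protocol) != length(samples))
    stop("protocol segment lengths (", sum(protocol),
         " s) must sum to the number of 1 s samples (", length(samples), ")")
  segment <- rep(names(protocol), times = protocol)
  new("FliprTrace", samples = samples, segment = segment,
      well = as.character(well), treatment = as.character(treatment))
}

setMethod("show", "FliprTrace", function(object) {
  segs <- rle(object@segment)
  cat(sprintf("FliprTrace well %s (%s): %d s at 1 reading/s [%s]\n",
              object@well, object@treatment, length(object@samples),
              paste(sprintf("%s %ds", segs$values, segs$lengths),
                    collapse = ", ")))
})

#' @describeIn FliprTrace number of 1 s readings.
#' @param x a `FliprTrace`.
#' @export
setMethod("length", "FliprTrace", function(x) length(x@samples))

.traceSegment <- function(trace, segment) {
  idx <- which(trace@segment == segment)
  if (length(idx) == 0L)
    stop("trace has no '", segment, "' segment")
  trace@samples[idx]
}

#' Per-trace resting baseline
#'
#' The resting fluorescence level of a trace, estimated as the median of
#' its 100 s pre-addition baseline segment.  "Signal increase" throughout
#' this module means fluorescence minus this level.  An alternative
#' estimator (`"rolling_min"`: running minimum over the scored window,
#' smoothing slow drift) is available.
#'
#' @param trace a [FliprTrace-class].
#' @param method `"baseline_median"` (default) or `"rolling_min"`.
#' @param window rolling window width in seconds for `"rolling_min"`.
#' @return scalar baseline (or a vector along the trace for
#'   `"rolling_min"`).
#' @export
traceBaseline <- function(trace, method = c("baseline_median",
                                            "rolling_min"), window = 30L) {
  method <- match.arg(method)
  if (method == "baseline_median") {
    stats::median(.traceSegment(trace, "baseline"))
  } else {
    x <- trace@samples
    n <- length(x)
    vapply(seq_len(n), function(i)
      min(x[max(1L, i - window):i]), numeric(1))
  }
}

# strict local maxima with a minimum separation and a minimum height above
# the reference level; returns integer positions within x
.findSpikes <- function(x, minHeight, minSep = 2L) {
  n <- length(x)
  if (n < 3L) return(integer())
  isMax <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
               x[2:(n - 1)] >= x[3:n], FALSE)
  cand <- which(isMax & x > minHeight)
  if (length(cand) <= 1L) return(cand)
  cand <- cand[order(-x[cand])]
  keep <- logical(0)
  sel <- integer()
  for (p in cand) {
    if (all(abs(sel - p) >= minSep)) sel <- c(sel, p)
  }
  sort(sel)
}

#' Average control spike amplitude
#'
#' Establishes the assay's reference amplitude: for each untreated
#' (control) well, spikes are detected in the 300 s second read and their
#' amplitudes (signal increase above the trace baseline) averaged; the
#' reference is the mean over control wells.
#'
#' @param controls a list of control [FliprTrace-class] objects (or one).
#' @param segment scored window (default `"second_read"`).
#' @param minFrac spikes must rise above `minFrac` of the largest
#'   baseline-subtracted value in the trace (default 0.1); guards against
#'   counting noise ripples as spikes.
#' @return mean control spike amplitude, in fluorescence units.
#' @export
controlAmplitude <- function(controls, segment = "second_read",
                             minFrac = 0.1) {
  if (is(controls, "FliprTrace")) controls <- list(controls)
  stopifnot(length(controls) >= 1L)
  amps <- vapply(controls, function(tr) {
    y <- .traceSegment(tr, segment) - traceBaseline(tr)
    top <- max(y)
    if (top <= 0) return(NA_real_)
    pk <- .findSpikes(y, minHeight = minFrac * top)
    if (length(pk) == 0L) return(NA_real_)
    mean(y[pk])
  }, numeric(1))
  if (all(is.na(amps)))
    stop("no spikes detected in any control trace")
  mean(amps, na.rm = TRUE)
}

#' Raw supra-threshold read count for a trace
#'
#' The amplitude-threshold scoring primitive: each 1 s read in the scored
#' window earns 1 when its signal increase above the trace baseline
#' exceeds 50% of the average control spike amplitude, else 0; the score
#' is the sum.
#'
#' @param trace a [FliprTrace-class].
#' @param controlAmp average control spike amplitude ([controlAmplitude()]).
#' @param segment scored window (default `"second_read"`, matching the
#'   control-amplitude window).
#' @return integer count of supra-threshold reads.
#' @export
rawOscillationSum <- function(trace, controlAmp, segment = "second_read") {
  stopifnot(controlAmp > 0)
  y <- .traceSegment(trace, segment) - traceBaseline(trace)
  sum(y > 0.5 * controlAmp)
}

#' Calcium oscillation score for a treated trace
#'
#' Converts the raw supra-threshold read count to percent of control:
#' `100 * raw_sum / control_raw_sum`, where `control_raw_sum` is the mean
#' raw count of the untreated control wells, so the controls themselves
#' average 100.  Higher scores mean preserved (or enhanced) spontaneous
#' oscillations; toxic ASOs reduce the score.
#'
#' @inheritParams rawOscillationSum
#' @param controlRawSum mean raw oscillation sum of the control wells.
#' @return list with `raw_sum` and `percent_of_control`.
#' @export
oscillationScore <- function(trace, controlAmp, controlRawSum,
                             segment = "second_read") {
  stopifnot(controlAmp > 0, controlRawSum > 0)
  raw <- rawOscillationSum(trace, controlAmp, segment)
  list(raw_sum = raw, percent_of_control = 100 * raw / controlRawSum)
}

#' Score a plate of traces against its controls
#'
#' Convenience wrapper: derives the control amplitude and mean control raw
#' sum from the control traces, then scores every treated trace.
#'
#' @param treated list of treated [FliprTrace-class] objects.
#' @param controls list of untreated control traces.
#' @param segment scored window.
#' @return data.frame with `well`, `treatment`, `raw_sum`,
#'   `percent_of_control`.
#' @export
scoreTraces <- function(treated, controls, segment = "second_read") {
  amp <- controlAmplitude(controls, segment = segment)
  ctlSums <- vapply(controls, rawOscillationSum, numeric(1),
                    controlAmp = amp, segment = segment)
  ctlMean <- mean(ctlSums)
  if (ctlMean <= 0) stop("control traces have no supra-threshold reads")
  rows <- lapply(treated, function(tr) {
    sc <- oscillationScore(tr, amp, ctlMean, segment)
    data.frame(well = tr@well, treatment = tr@treatment,
               raw_sum = sc$raw_sum,
               percent_of_control = sc$percent_of_control,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count oscillation peaks in a time window
#'
#' Peak counting for the receptor-pharmacology arm of the assay: local
#' maxima within the first `window` seconds of the scored segment, with a
#' prominence of at least `prominenceFrac` of the reference amplitude and
#' a minimum 2 s separation.
#'
#' @param trace a [FliprTrace-class].
#' @param window window length in seconds (default 180, a 3 min read).
#' @param referenceAmp reference amplitude; defaults to the trace's own
#'   maximal signal increase.
#' @param prominenceFrac prominence threshold as a fraction of
#'   `referenceAmp` (default 0.2).
#' @param segment segment to read from (default `"second_read"`).
#' @return integer peak count.
#' @export
countPeaks <- function(trace, window = 180L, referenceAmp = NULL,
                       prominenceFrac = 0.2, segment = "second_read") {
  y <- .traceSegment(trace, segment) - traceBaseline(trace)
  if (window > length(y))
    stop("window (", window, " s) exceeds the ", length(y), " s segment")
  y <- y[seq_len(window)]
  if (is.null(referenceAmp)) referenceAmp <- max(y)
  if (referenceAmp <= 0) return(0L)
  length(.findSpikes(y, minHeight = prominenceFrac * referenceAmp))
}

#' Peak counts as percent of vehicle
#'
#' @param treatedCounts integer peak counts for treated wells.
#' @param vehicleCounts integer peak counts for vehicle wells.
#' @return `100 * mean(treatedCounts) / mean(vehicleCounts)`.
#' @export
percentOfVehicle <- function(treatedCounts, vehicleCounts) {
  mv <- mean(vehicleCounts)
  if (mv <= 0) stop("vehicle wells have no peaks")
  100 * mean(treatedCounts) / mv
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of the sigmoidal (variable-slope) model
#' `response(c) = bottom + (top - bottom) / (1 + (ec50 / c)^hill)`
#' to percent-of-vehicle responses, via Levenberg-Marquardt
#' ([minpack.lm::nlsLM]).  Initialization is deterministic: `top` and
#' `bottom` from the response extremes, `ec50` from the geometric mean of
#' the concentration range, `hill = +1` or `-1` by the orientation of the
#' response trend (decreasing curves plateau at `bottom` with a negative
#' slope).
#'
#' @param concentrations positive concentrations (at least 5, spanning the
#'   transition).
#' @param responses responses in percent of vehicle, same length.
#' @return list with `top`, `bottom`, `ec50`, `hill_slope`, `fitted`,
#'   `residual_norm`, `degenerate` (TRUE when the responses are constant,
#'   in which case `ec50`/`hill_slope` are `NA` with a warning).
#' @export
fitDoseResponse <- function(concentrations, responses) {
  conc <- as.numeric(concentrations); resp <- as.numeric(responses)
  stopifnot(length(conc) == length(resp))
  if (length(conc) < 5L)
    stop("need at least 5 concentration points")
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (stats::var(resp) == 0) {
    warning("constant responses: top == bottom, EC50 unidentifiable")
    return(list(top = resp[1], bottom = resp[1], ec50 = NA_real_,
                hill_slope = NA_real_, fitted = resp, residual_norm = 0,
                degenerate = TRUE))
  }
  # slope sign from the data orientation: increasing curves have hill > 0
  # (response runs bottom -> top with dose), decreasing curves hill < 0
  # (the saturating plateau is then `bottom`)
  slopeSign <- if (stats::cor(log(conc), resp) < 0) -1 else 1
  start <- list(top = max(resp), bottom = min(resp),
                ec50 = exp(mean(log(range(conc)))), hill = slopeSign)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) / (1 + (ec50 / conc)^hill),
      start = start, data = data.frame(conc = conc, resp = resp),
      lower = c(top = -Inf, bottom = -Inf, ec50 = 1e-12, hill = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("dose-response fit did not converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
       ec50 = unname(cf["ec50"]), hill_slope = unname(cf["hill"]),
       fitted = stats::fitted(fit),
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       degenerate = FALSE)
}

#' Read / write FLIPR traces in long CSV format
#'
#' Long format: columns `well`, `time_s`, `fluorescence`, `segment`,
#' `treatment`; one row per 1 s reading, rows ordered by time within well.
#'
#' @param path CSV file.
#' @return `readTraces` returns a list of [FliprTrace-class]; `writeTraces`
#'   returns `path` invisibly.
#' @export
readTraces <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_s", "fluorescence", "segment", "treatment")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("trace CSV is missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(tab, tab$well), function(d) {
    d <- d[order(d$time_s), ]
    segs <- rle(d$segment)
    FliprTrace(d$fluorescence,
               protocol = stats::setNames(segs$lengths, segs$values),
               well = d$well[[1]], treatment = d$treatment[[1]])
  })
}

#' @rdname readTraces
#' @param traces a list of [FliprTrace-class] objects.
#' @export
writeTraces <- function(traces, path) {
  if (is(traces, "FliprTrace")) traces <- list(traces)
  rows <- lapply(traces, function(tr)
    data.frame(well = tr@well, time_s = seq_along(tr@samples) - 1L,
               fluorescence = tr@samples, segment = tr@segment,
               treatment = tr@treatment, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
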