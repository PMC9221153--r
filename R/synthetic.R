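#' Configuration for the synthetic study generator
#'
#' Bundles the generator conventions used to emulate the statistical
#' structure of a gapmer neurotoxicity screen: panel sizes (1,645 training
#' ASOs, 148 test ASOs and 19 validation ASOs, all tiled against a target
#' pre-mRNA), ASO architecture (14-20 nt, 3-9 LNA nucleotides split over
#' two flanks, full PS backbone), a ground-truth linear model generating
#' calcium oscillation scores with additive Gaussian noise, and a monotone
#' decreasing link from calcium score to the 0-20 acute tolerability scale
#' observed over 4-6 mice per group.
#'
#' The default true coefficients `(p_A=8, p_T=3, p_C=4, p_G=-6, p_3=2,
#' I=50)` reproduce the qualitative pattern of the fitted model (strongly
#' negative G weight, A contributing more than T or C, a positive 3'
#' G-free-stretch weight) and place a typical tiled 14-20 nt ASO near 98
#' on the 0-200 percent-of-control scale, so that roughly a third to two
#' fifths of simulated ASOs fall in the moderate-to-severe tolerability
#' range;
#' calcium noise sd 25 and the link `20 * logistic(-(ca - 70) / 15)` are
#' generator conventions, not measured values.
#'
#' @param trainSize,testSize,validationSize panel sizes.
#' @param lengthRange ASO length range in nt.
#' @param flankTotalRange total LNA nucleotides across both flanks.
#' @param nRegions number of disjoint target regions the training panel
#'   tiles (313 regions covering ~7,063 nt by default).
#' @param targetLength target pre-mRNA length in nt.
#' @param gcFraction target GC fraction.
#' @param trueCoefficients named vector `p_A, p_T, p_C, p_G, p_3, I`.
#' @param calciumNoiseSd Gaussian noise sd on calcium scores.
#' @param linkMidpoint,linkScale parameters of the tolerability link
#'   `20 * plogis(-(ca - linkMidpoint) / linkScale)`.
#' @param tolNoiseSd per-mouse Gaussian noise sd on the latent severity.
#' @param micePerGroup range of mice per treatment group.
#' @return list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(trainSize = 1645L, testSize = 148L,
                            validationSize = 19L,
                            lengthRange = c(14L, 20L),
                            flankTotalRange = c(3L, 9L),
                            nRegions = 313L, targetLength = 7063L,
                            gcFraction = 0.45,
                            trueCoefficients = c(p_A = 8, p_T = 3, p_C = 4,
                                                 p_G = -6, p_3 = 2, I = 50),
                            calciumNoiseSd = 25,
                            linkMidpoint = 70, linkScale = 15,
                            tolNoiseSd = 2, micePerGroup = c(4L, 6L)) {
  stopifnot(trainSize > 0, testSize > 0, validationSize > 0,
            calciumNoiseSd >= 0, tolNoiseSd >= 0,
            all(.MODEL_TERMS %in% names(trueCoefficients)))
  structure(as.list(environment()), class = "GeneratorConfig")
}

#' Simulate a target pre-mRNA sequence
#'
#' Seeded i.i.d. random sequence with the requested expected GC fraction,
#' standing in for the pre-mRNA an ASO panel tiles.
#'
#' @param length sequence length in nt (must cover the longest ASO).
#' @param gcFraction expected fraction of G+C (default 0.45).
#' @param seed RNG seed.
#' @return a [Biostrings::DNAString].
#' @export
simulateTargetPremrna <- function(length, gcFraction = 0.45, seed = 1L) {
  stopifnot(length >= 1, gcFraction >= 0, gcFraction <= 1)
  p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
         G = gcFraction / 2, T = (1 - gcFraction) / 2)
  withSeed(seed, Biostrings::DNAString(paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = "")))
}

.splitFlanks <- function(total) {
  # split a total LNA budget over the two flanks, each at least 1
  f5 <- sample(seq.int(1L, total - 1L), 1L)
  c(f5, total - f5)
}

#' Tile an ASO panel across a target sequence
#'
#' Emulates a knockdown screen design: the target is divided into
#' `nRegions` disjoint regions, ASOs are assigned to regions round-robin,
#' and each ASO is the reverse complement of a random window inside its
#' region, with a random admissible LNA flank pattern applied.
#'
#' @param target a [Biostrings::DNAString] (or character) target sequence.
#' @param n number of ASOs.
#' @param config a [generatorConfig()].
#' @param seed RNG seed.
#' @param prefix id prefix.
#' @return an [AsoPanel-class] with annotation columns `region`,
#'   `target_start`, `target_end` (1-based window on the target).
#' @export
tileAsos <- function(target, n, config = generatorConfig(), seed = 1L,
                     prefix = "aso") {
  target <- as.character(target)
  tlen <- nchar(target)
  maxLen <- config$lengthRange[[2]]
  nReg <- min(config$nRegions, tlen %/% maxLen)
  stopifnot(nReg >= 1)
  bnd <- floor(seq(0, tlen, length.out = nReg + 1L))
  withSeed(seed, {
    region <- rep(seq_len(nReg), length.out = n)
    len <- sample(seq.int(config$lengthRange[[1]], config$lengthRange[[2]]),
                  n, replace = TRUE)
    start <- integer(n); bases <- character(n); mods <- character(n)
    for (i in seq_len(n)) {
      lo <- bnd[region[[i]]] + 1L; hi <- bnd[region[[i]] + 1L]
      if (hi - lo + 1L < len[[i]]) len[[i]] <- hi - lo + 1L
      start[[i]] <- lo + sample.int(hi - lo + 2L - len[[i]], 1L) - 1L
      win <- substr(target, start[[i]], start[[i]] + len[[i]] - 1L)
      bases[[i]] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(win)))
      total <- sample(
        seq.int(config$flankTotalRange[[1]], config$flankTotalRange[[2]]),
        1L)
      total <- min(total, len[[i]] - 2L)  # keep a DNA gap
      fl <- .splitFlanks(max(2L, total))
      mods[[i]] <- .composeMods(len[[i]], fl)
    }
    AsoPanel(ids = paste0(prefix, "_", seq_len(n)), bases = bases,
             mods = mods,
             annot = S4Vectors::DataFrame(
               region = region, target_start = start,
               target_end = start + len - 1L))
  })
}

#' Simulate calcium oscillation scores for a panel
#'
#' Generative use of the linear sequence model: each ASO's score is its
#' exact weighted feature sum plus Gaussian noise, truncated below at 0
#' (percent-of-control scores cannot be negative); extreme scores can
#' optionally be capped.
#'
#' @param panel an [AsoPanel-class].
#' @param trueModel named coefficient vector or [ScoreModel-class].
#' @param noiseSd Gaussian noise sd (0 gives the exact linear values).
#' @param seed RNG seed.
#' @param cap optional upper cap (e.g. 200); default `NULL`.
#' @return named numeric vector of scores.
#' @export
simulateCalciumScores <- function(panel, trueModel = generatorConfig()$trueCoefficients,
                                  noiseSd = 25, seed = 1L, cap = NULL) {
  mu <- calculateScore(trueModel, panel)
  out <- withSeed(seed, pmax(0, mu + stats::rnorm(length(mu), 0, noiseSd)))
  if (!is.null(cap)) out <- pmin(out, cap)
  out
}

#' Simulate mouse tolerability scores from calcium scores
#'
#' A monotone decreasing link maps each ASO's calcium score to a latent
#' severity `20 * plogis(-(ca - midpoint) / scale)`; per-mouse totals are
#' the latent severity plus Gaussian noise, clamped to `[0, 20]` and
#' rounded; each total is decomposed into five behavioral category scores
#' (each 0-4) by random composition; group means are averaged over 4-6
#' mice.
#'
#' @param calciumScores numeric vector (pass noiseless linear values to
#'   model tolerability driven by the underlying sequence effect, or
#'   measured scores to model assay-linked tolerability).
#' @param config a [generatorConfig()] providing the link parameters.
#' @param seed RNG seed.
#' @return list with `group_mean` (named numeric, one per ASO) and `mice`
#'   (data.frame: `id`, `mouse`, `cat1 ... cat5`, `total`).
#' @export
simulateTolerability <- function(calciumScores, config = generatorConfig(),
                                 seed = 1L) {
  ids <- names(calciumScores)
  if (is.null(ids)) ids <- paste0("aso_", seq_along(calciumScores))
  withSeed(seed, {
    rows <- list(); gm <- numeric(length(calciumScores))
    for (i in seq_along(calciumScores)) {
      latent <- 20 * stats::plogis(
        -(calciumScores[[i]] - config$linkMidpoint) / config$linkScale)
      nMice <- sample(seq.int(config$micePerGroup[[1]],
                              config$micePerGroup[[2]]), 1L)
      totals <- round(pmin(20, pmax(0,
        latent + stats::rnorm(nMice, 0, config$tolNoiseSd))))
      cats <- t(vapply(totals, function(tt) {
        parts <- integer(5)
        for (k in seq_len(tt)) {
          open <- which(parts < 4L)
          j <- open[[sample.int(length(open), 1L)]]
          parts[[j]] <- parts[[j]] + 1L
        }
        parts
      }, integer(5)))
      gm[[i]] <- mean(totals)
      rows[[i]] <- data.frame(id = ids[[i]], mouse = seq_len(nMice),
                              cat1 = cats[, 1], cat2 = cats[, 2],
                              cat3 = cats[, 3], cat4 = cats[, 4],
                              cat5 = cats[, 5], total = totals,
                              stringsAsFactors = FALSE)
    }
    list(group_mean = stats::setNames(gm, ids),
         mice = do.call(rbind, rows))
  })
}

#' Simulate a FLIPR fluorescence trace
#'
#' Protocol-segmented synthetic trace: a constant resting baseline,
#' Poisson-timed calcium spikes with instantaneous rise and exponential
#' decay, and additive Gaussian instrument noise (floored at zero
#' fluorescence).
#'
#' @param spikeRate spikes per second (Poisson process intensity).
#' @param amplitude spike amplitude in fluorescence units.
#' @param noiseSd Gaussian noise sd.
#' @param protocol named vector of segment lengths in seconds.
#' @param baselineLevel resting fluorescence level.
#' @param decayTau exponential decay time constant in seconds.
#' @param seed RNG seed.
#' @param well,treatment labels.
#' @return a [FliprTrace-class].
#' @export
simulateFliprTrace <- function(spikeRate = 0.03, amplitude = 100,
                               noiseSd = 0, protocol = .DEFAULT_PROTOCOL,
                               baselineLevel = 1000, decayTau = 3,
                               seed = 1L, well = "w01",
                               treatment = "control") {
  stopifnot(spikeRate >= 0, noiseSd >= 0)
  n <- sum(protocol)
  withSeed(seed, {
    y <- rep(baselineLevel, n)
    nSpikes <- stats::rpois(1L, spikeRate * n)
    if (nSpikes > 0) {
      at <- sort(sample.int(n, min(nSpikes, n)))
      for (t0 in at) {
        idx <- t0:min(n, t0 + ceiling(8 * decayTau))
        y[idx] <- y[idx] + amplitude * exp(-(idx - t0) / decayTau)
      }
    }
    if (noiseSd > 0) y <- y + stats::rnorm(n, 0, noiseSd)
    FliprTrace(pmax(0, y), protocol = protocol, well = well,
               treatment = treatment)
  })
}

#' Simulate a transcriptome
#'
#' Seeded random transcript records with unique ids, for desk-scale
#' off-target screening.
#'
#' @param nTranscripts number of records.
#' @param lengthRange transcript length range in nt.
#' @param gcFraction expected GC fraction.
#' @param seed RNG seed.
#' @return a named [Biostrings::DNAStringSet].
#' @export
simulateTranscriptome <- function(nTranscripts, lengthRange = c(500L, 3000L),
                                  gcFraction = 0.5, seed = 1L) {
  stopifnot(nTranscripts >= 1)
  p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
         G = gcFraction / 2, T = (1 - gcFraction) / 2)
  withSeed(seed, {
    lens <- sample(seq.int(lengthRange[[1]], lengthRange[[2]]),
                   nTranscripts, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("tx%04d", seq_len(nTranscripts))
    out
  })
}

#' Materialize a complete synthetic study directory
#'
#' Generates a target pre-mRNA, tiled training/test/validation panels with
#' simulated calcium and tolerability scores, a transcriptome, and a small
#' plate of FLIPR traces, writing everything in the formats the rest of
#' the package consumes (FASTA, TSV, CSV).  Tolerability is driven by the
#' noiseless linear value of each ASO, so the sequence signal — not the
#' assay noise — determines the in-vivo labels.
#'
#' @param dir output directory (created if needed).
#' @param config a [generatorConfig()].
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return invisibly, a list of the generated file paths.
#' @export
simulateStudy <- function(dir, config = generatorConfig(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  target <- simulateTargetPremrna(config$targetLength, config$gcFraction,
                                  seed = seed)
  paths <- list(target = file.path(dir, "target_premrna.fasta"))
  ts <- Biostrings::DNAStringSet(as.character(target))
  names(ts) <- "target_premrna"
  Biostrings::writeXStringSet(ts, paths$target)
  sets <- list(train = config$trainSize, test = config$testSize,
               validation = config$validationSize)
  for (k in seq_along(sets)) {
    nm <- names(sets)[[k]]
    panel <- tileAsos(target, sets[[k]], config, seed = seed + k,
                      prefix = nm)
    mu <- calculateScore(config$trueCoefficients, panel)
    ca <- simulateCalciumScores(panel, config$trueCoefficients,
                                config$calciumNoiseSd, seed = seed + 10L + k)
    panel <- setPanelAnnot(panel, "calcium_score", unname(ca))
    if (nm != "train") {
      tol <- simulateTolerability(mu, config, seed = seed + 20L + k)
      panel <- setPanelAnnot(panel, "tolerability_score",
                             unname(tol$group_mean))
      micePath <- file.path(dir, paste0(nm, "_mice.tsv"))
      utils::write.table(tol$mice, micePath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0(nm, "_mice")]] <- micePath
    }
    p <- file.path(dir, paste0(nm, "_panel.tsv"))
    writePanel(panel, p, format = "tsv")
    paths[[nm]] <- p
  }
  paths$transcriptome <- file.path(dir, "transcriptome.fasta")
  txome <- simulateTranscriptome(50L, seed = seed + 31L)
  Biostrings::writeXStringSet(txome, paths$transcriptome)
  traces <- c(
    lapply(1:4, function(i)
      simulateFliprTrace(seed = seed + 40L + i,
                         well = sprintf("ctl%02d", i),
                         treatment = "control")),
    lapply(1:4, function(i)
      simulateFliprTrace(spikeRate = 0.01, seed = seed + 50L + i,
                         well = sprintf("trt%02d", i),
                         treatment = "treated")))
  paths$traces <- file.path(dir, "flipr_traces.csv")
  writeTraces(traces, paths$traces)
  invisible(paths)
}
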