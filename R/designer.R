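#' Design constraints for negative-control gapmers
#'
#' Encodes the filters a low-neurotoxicity negative-control design must
#' pass: no guanine anywhere in the sequence, an adenine count roughly
#' balancing the summed thymine and cytosine counts, no perfectly
#' complementary site in the transcriptome, rare partially complementary
#' sites, and a calculated sequence score above the safety cutoff.
#'
#' @param lengths admissible ASO lengths in nt (default `c(18, 20)`).
#' @param flanks list of `c(five_prime, three_prime)` LNA flank lengths
#'   sampled uniformly per candidate (default `list(c(3,3), c(4,4))`).
#' @param delta balance tolerance: require `|n_A - (n_T + n_C)| <= delta`
#'   (default 4).
#' @param requireNoG require `n_G == 0` (default `TRUE`; candidates are
#'   drawn over `{A,C,T}`).
#' @param maxMismatch mismatch allowance for the partial-complementarity
#'   screen (default 2, i.e. "fewer than three mismatched base pairs").
#' @param maxPartialFraction maximum tolerated fraction of transcripts with
#'   a partially complementary site (default 0.001, i.e. < 0.1%).
#' @param minScore minimum calculated sequence score (default 70, the
#'   optimal tolerability cutoff).
#' @param attemptBudget rejection-sampling attempt budget (default 1e6).
#' @return a list of class `DesignConstraints`.
#' @export
designConstraints <- function(lengths = c(18L, 20L),
                              flanks = list(c(3L, 3L), c(4L, 4L)),
                              delta = 4L, requireNoG = TRUE,
                              maxMismatch = 2L,
                              maxPartialFraction = 0.001,
                              minScore = 70, attemptBudget = 1e6) {
  stopifnot(all(lengths >= 10L & lengths <= 25L),
            delta >= 0, maxMismatch >= 0,
            maxPartialFraction > 0, maxPartialFraction <= 1,
            attemptBudget >= 1)
  for (f in flanks) stopifnot(length(f) == 2L, all(f >= 1L))
  structure(list(lengths = as.integer(lengths), flanks = flanks,
                 delta = as.integer(delta), requireNoG = requireNoG,
                 maxMismatch = as.integer(maxMismatch),
                 maxPartialFraction = maxPartialFraction,
                 minScore = minScore, attemptBudget = attemptBudget),
            class = "DesignConstraints")
}

#' Mismatch-tolerant off-target complementarity screen
#'
#' Slides the reverse complement of the ASO base sequence along every
#' transcript (RNA stored as DNA letters, A<->T / C<->G pairing, no gaps)
#' and calls a window a potential binding region when it matches with at
#' most `maxMismatch` Hamming mismatches.  Reports whether any transcript
#' harbors a perfectly complementary site, and the fraction of transcript
#' records harboring at least one partially complementary site.
#' Transcripts shorter than the ASO contain no window and count as
#' non-binding.
#'
#' @param panel an [AsoPanel-class] (screened per ASO).
#' @param txome a [Biostrings::DNAStringSet] of transcript sequences
#'   (5'->3', U written as T), or a named character vector.
#' @param maxMismatch mismatch allowance for the partial screen
#'   (default 2).
#' @return data.frame with one row per ASO: `id`, `perfect_match`
#'   (logical), `partial_fraction` (in `[0,1]`).
#' @export
offtargetScreen <- function(panel, txome, maxMismatch = 2L) {
  stopifnot(is(panel, "AsoPanel"), maxMismatch >= 0)
  if (!is(txome, "DNAStringSet")) txome <- Biostrings::DNAStringSet(txome)
  if (length(txome) == 0L) stop("empty transcriptome")
  rows <- lapply(seq_along(panel), function(i) {
    probe <- Biostrings::reverseComplement(
      Biostrings::DNAString(panel@bases[[i]]))
    hitsPartial <- Biostrings::vcountPattern(
      probe, txome, max.mismatch = maxMismatch, fixed = TRUE) > 0L
    hitsPerfect <- if (maxMismatch == 0L) hitsPartial else
      Biostrings::vcountPattern(probe, txome, max.mismatch = 0L,
                                fixed = TRUE) > 0L
    data.frame(id = panel@ids[[i]],
               perfect_match = any(hitsPerfect),
               partial_fraction = mean(hitsPartial),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.composeMods <- function(len, flank) {
  paste0(strrep("L", flank[[1]]),
         strrep("D", len - flank[[1]] - flank[[2]]),
         strrep("L", flank[[2]]))
}

#' Generate random candidate gapmers under composition constraints
#'
#' Seeded rejection sampling: random base sequences over `{A,C,T}` (or
#' `{A,C,G,T}` when `requireNoG` is off) of the admissible lengths, kept
#' when the A versus T+C balance holds, with LNA flank patterns applied
#' from the constraint list.
#'
#' @param constraints a [designConstraints()] object.
#' @param n number of candidates to generate.
#' @param seed RNG seed (same seed, same candidates).
#' @return an [AsoPanel-class] of `n` candidates (ids `cand_1 ...`).
#' @export
generateCandidates <- function(constraints, n, seed = 1L) {
  stopifnot(inherits(constraints, "DesignConstraints"), n >= 1L)
  alphabet <- if (constraints$requireNoG) c("A", "C", "T")
              else c("A", "C", "G", "T")
  withSeed(seed, {
    bases <- character(0); mods <- character(0)
    attempts <- 0L
    while (length(bases) < n) {
      if (attempts >= constraints$attemptBudget)
        stop("rejection-sampling budget (", constraints$attemptBudget,
             " attempts) exhausted after ", length(bases),
             " candidates; consider loosening the constraints")
      attempts <- attempts + 1L
      len <- constraints$lengths[[sample.int(length(constraints$lengths), 1L)]]
      flank <- constraints$flanks[[sample.int(length(constraints$flanks), 1L)]]
      if (sum(flank) >= len) next
      b <- sample(alphabet, len, replace = TRUE)
      nA <- sum(b == "A"); nTC <- sum(b == "T") + sum(b == "C")
      if (abs(nA - nTC) > constraints$delta) next
      bases <- c(bases, paste(b, collapse = ""))
      mods <- c(mods, .composeMods(len, flank))
    }
    AsoPanel(ids = paste0("cand_", seq_len(n)), bases = bases, mods = mods)
  })
}

#' Design negative-control gapmers with low acute neurotoxic potential
#'
#' End-to-end design procedure: draw random candidates satisfying the
#' composition constraints (G-free, A roughly balancing T+C), reject any
#' with a perfectly complementary transcriptome site or with partially
#' complementary sites in too many transcripts, reject any whose
#' calculated sequence score does not exceed the safety minimum, and rank
#' the survivors by descending calculated score.
#'
#' @param model a fitted [ScoreModel-class] (or named coefficient vector).
#' @param txome transcriptome as a [Biostrings::DNAStringSet].
#' @param constraints a [designConstraints()] object.
#' @param n number of designs wanted (e.g. 13 for a negative-control
#'   panel).
#' @param seed RNG seed; the whole procedure is reproducible given the
#'   seed.
#' @param batchSize candidates drawn per screening round.
#' @return an [AsoPanel-class] of up to `n` designs (ids `nc_1 ...`,
#'   ranked by score) with annotation columns `calculated_score`,
#'   `perfect_match`, `partial_fraction`; a warning is raised when fewer
#'   than `n` designs pass within the attempt budget.
#' @export
designNegativeControls <- function(model, txome, constraints = designConstraints(),
                                   n = 13L, seed = 1L, batchSize = 50L) {
  stopifnot(n >= 1L)
  found <- list()
  rounds <- 0L
  maxRounds <- max(1L, ceiling(constraints$attemptBudget / batchSize))
  while (length(found) < n && rounds < maxRounds) {
    rounds <- rounds + 1L
    cand <- tryCatch(
      generateCandidates(constraints, batchSize,
                         seed = seed + rounds * 1000L),
      error = function(e) NULL)
    if (is.null(cand)) break
    screen <- offtargetScreen(cand, txome, constraints$maxMismatch)
    score <- calculateScore(model, cand)
    ok <- !screen$perfect_match &
      screen$partial_fraction < constraints$maxPartialFraction &
      score > constraints$minScore
    for (i in which(ok)) {
      if (length(found) >= n) break
      found[[length(found) + 1L]] <- list(
        bases = cand@bases[[i]], mods = cand@mods[[i]],
        score = unname(score[[i]]),
        partial = screen$partial_fraction[[i]])
    }
  }
  if (length(found) < n)
    warning("only ", length(found), " of ", n,
            " requested designs passed the filters within the budget")
  if (length(found) == 0L) return(AsoPanel())
  ord <- order(-vapply(found, `[[`, numeric(1), "score"))
  found <- found[ord]
  panel <- AsoPanel(
    ids = paste0("nc_", seq_along(found)),
    bases = vapply(found, `[[`, character(1), "bases"),
    mods = vapply(found, `[[`, character(1), "mods"),
    annot = S4Vectors::DataFrame(
      calculated_score = vapply(found, `[[`, numeric(1), "score"),
      perfect_match = FALSE,
      partial_fraction = vapply(found, `[[`, numeric(1), "partial")))
  panel
}

#' Write a design panel with screen results as TSV
#'
#' @param designs panel from [designNegativeControls()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeDesigns <- function(designs, path) {
  counts <- countNucleotides(designs)
  tab <- data.frame(id = asoIds(designs),
                    sequence = unname(serializeGapmer(designs)),
                    n_a = unname(counts[, "n_a"]), n_t = unname(counts[, "n_t"]),
                    n_c = unname(counts[, "n_c"]), n_g = unname(counts[, "n_g"]),
                    stringsAsFactors = FALSE)
  for (col in c("calculated_score", "perfect_match", "partial_fraction"))
    if (col %in% colnames(designs@annot)) tab[[col]] <- designs@annot[[col]]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
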