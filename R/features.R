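#' Count nucleobases in each ASO
#'
#' @param panel an [AsoPanel-class].
#' @return integer matrix with one row per ASO and columns `n_a`, `n_t`,
#'   `n_c`, `n_g`; rows sum to the ASO length.
#' @examples
#' countNucleotides(parseGapmer("TCCactaaccaatatAAC"))
#' @export
countNucleotides <- function(panel) {
  stopifnot(is(panel, "AsoPanel"))
  if (length(panel) == 0L) {
    m <- matrix(integer(), 0L, 4L)
  } else {
    af <- Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(panel@bases))
    m <- af[, c("A", "T", "C", "G"), drop = FALSE]
  }
  dimnames(m) <- list(panel@ids, c("n_a", "n_t", "n_c", "n_g"))
  m
}

#' Length of the G-free stretch from an ASO end
#'
#' The number of consecutive non-guanine nucleobases counted inward from the
#' named terminus: 0 when the terminal base is G, and the full ASO length
#' when the sequence contains no G at all.  The count is at the nucleobase
#' level and ignores LNA/DNA chemistry.
#'
#' @param panel an [AsoPanel-class].
#' @param end `"three_prime"` (the default; the model's `g_3` feature) or
#'   `"five_prime"`.
#' @return named integer vector, one value per ASO.
#' @export
gFreeStretch <- function(panel, end = c("three_prime", "five_prime")) {
  stopifnot(is(panel, "AsoPanel"))
  end <- match.arg(end)
  out <- if (end == "three_prime")
    nchar(sub(".*G", "", panel@bases))   # run after the last G
  else
    nchar(sub("G.*", "", panel@bases))   # run before the first G
  stats::setNames(as.integer(out), panel@ids)
}

#' Per-ASO gap length
#'
#' Number of DNA (unmodified) positions lying strictly between the first and
#' last LNA positions — for a classical gapmer with two terminal LNA flanks
#' this is the central DNA gap supporting RNase H recruitment, and equals
#' `length - n_lna`.  All-DNA ASOs return their full length.
#'
#' @param panel an [AsoPanel-class].
#' @return named integer vector.
#' @export
gapLength <- function(panel) {
  stopifnot(is(panel, "AsoPanel"))
  core <- sub("D*$", "", sub("^D*", "", panel@mods))
  out <- nchar(gsub("L", "", core))
  noLna <- !grepl("L", panel@mods)
  out[noLna] <- nchar(panel@mods)[noLna]
  stats::setNames(as.integer(out), panel@ids)
}

#' Sequence feature table for an ASO panel
#'
#' Materializes, one row per ASO in panel order, the sequence features used
#' throughout the analysis: total length, LNA count, gap length, the four
#' nucleobase counts and the G-free stretches from both ends.
#'
#' @param panel an [AsoPanel-class].
#' @return a `data.frame` with columns `id`, `length`, `n_lna`, `gap_length`,
#'   `n_a`, `n_t`, `n_c`, `n_g`, `g3`, `g5`.
#' @seealso [writeFeatureTable()]
#' @export
featureTable <- function(panel) {
  stopifnot(is(panel, "AsoPanel"))
  counts <- countNucleotides(panel)
  data.frame(
    id = asoIds(panel),
    length = nchar(panel@bases),
    n_lna = nchar(panel@mods) - nchar(gsub("L", "", panel@mods)),
    gap_length = unname(gapLength(panel)),
    n_a = unname(counts[, "n_a"]),
    n_t = unname(counts[, "n_t"]),
    n_c = unname(counts[, "n_c"]),
    n_g = unname(counts[, "n_g"]),
    g3 = unname(gFreeStretch(panel, "three_prime")),
    g5 = unname(gFreeStretch(panel, "five_prime")),
    stringsAsFactors = FALSE
  )
}

#' Write a feature table as TSV
#'
#' @param features output of [featureTable()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Levenshtein edit distance between base strings
#'
#' Minimal number of single-character substitutions, insertions and
#' deletions (unit costs) transforming one base string into another.
#'
#' @param a,b character vectors of base strings over `{A,C,G,T}`; distances
#'   are computed for all pairs.
#' @return integer matrix of edit distances (`length(a)` x `length(b)`).
#' @export
levenshteinDist <- function(a, b = a) {
  stopifnot(is.character(a), is.character(b))
  if (any(grepl("[^ACGT]", c(a, b))))
    stop("base strings must be over {A,C,G,T}")
  d <- utils::adist(a, b)
  storage.mode(d) <- "integer"
  d
}

#' Association between sequence similarity and score similarity
#'
#' Tests whether similar sequences tend to have similar scores: for sampled
#' (or exhaustive) ASO pairs, computes the Levenshtein edit distance between
#' base strings and the absolute difference of their scores, and the
#' Spearman rank correlation between the two.  A positive correlation means
#' more-dissimilar sequences have more-dissimilar scores.
#'
#' @param panel an [AsoPanel-class] with at least two scored ASOs.
#' @param scores numeric score per ASO; defaults to the panel's
#'   `calcium_score` annotation.
#' @param maxPairs pairs are subsampled without replacement above this cap
#'   (default 100000; a 1,645-ASO panel has ~1.35M pairs).
#' @param seed RNG seed for the subsample.
#' @return a list with `pairs` (data.frame: `id1`, `id2`, `edit_distance`,
#'   `score_difference`), `rho` and `p_value`.
#' @export
similarityScoreAssociation <- function(panel, scores = calciumScores(panel),
                                       maxPairs = 1e5, seed = 1L) {
  stopifnot(is(panel, "AsoPanel"))
  if (is.null(scores)) stop("panel has no scores")
  keep <- which(!is.na(scores))
  if (length(keep) < 2L)
    stop("need at least 2 scored ASOs for a pairwise analysis")
  ids <- asoIds(panel)[keep]
  bases <- unname(asoBases(panel))[keep]
  scores <- scores[keep]
  n <- length(keep)
  npair <- n * (n - 1) / 2
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (npair > maxPairs) {
    sel <- withSeed(seed, sample.int(nrow(ij), maxPairs))
    ij <- ij[sel, , drop = FALSE]
  }
  ed <- vapply(seq_len(nrow(ij)), function(k)
    utils::adist(bases[ij[k, 1L]], bases[ij[k, 2L]])[1L, 1L], numeric(1))
  sd_ <- abs(scores[ij[, 1L]] - scores[ij[, 2L]])
  pairs <- data.frame(id1 = ids[ij[, 1L]], id2 = ids[ij[, 2L]],
                      edit_distance = as.integer(ed),
                      score_difference = sd_, stringsAsFactors = FALSE)
  if (nrow(ij) >= 3L && stats::var(ed) > 0 && stats::var(sd_) > 0) {
    st <- spearmanTest(ed, sd_)
    rho <- st$rho; p <- st$p_value
  } else {
    rho <- NA_real_; p <- NA_real_  # too few / degenerate pairs
  }
  list(pairs = pairs, rho = rho, p_value = p)
}
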