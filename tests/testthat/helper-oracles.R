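# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately share no code with R/.

# full dynamic-programming Levenshtein distance (unit costs)
oracleLevenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n; d[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- min(
      d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
      d[i, j] + (x[i] != y[j]))
  }
  d[n + 1L, m + 1L]
}

# exhaustive Mann-Whitney AUC: pairwise comparison, ties count 1/2;
# returns P(acceptable predictor > toxic predictor)
oracleAuc <- function(predictor, toxic) {
  acc <- predictor[!toxic]; tox <- predictor[toxic]
  tot <- 0
  for (a in acc) for (t in tox)
    tot <- tot + if (a > t) 1 else if (a == t) 0.5 else 0
  tot / (length(acc) * length(tox))
}

# tie-corrected Kruskal-Wallis H from the rank-sum formula
oracleKruskalH <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Spearman rho as Pearson correlation of mid-ranks, coded independently
oracleSpearman <- function(x, y) {
  rk <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1L]] == v[o[i]]) j <- j + 1L
      r[o[i:j]] <- mean(i:j)
      i <- j + 1L
    }
    r
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force sliding-window off-target screen: for each transcript,
# enumerate every window and count Hamming mismatches against the reverse
# complement of the ASO
oracleOfftarget <- function(bases, transcripts, maxMismatch) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(bases, "")[[1]]]), collapse = "")
  probe <- strsplit(rc, "")[[1]]
  k <- length(probe)
  perfect <- FALSE
  partial <- logical(length(transcripts))
  for (ti in seq_along(transcripts)) {
    tx <- strsplit(transcripts[[ti]], "")[[1]]
    if (length(tx) < k) next
    for (s in seq_len(length(tx) - k + 1L)) {
      mm <- sum(tx[s:(s + k - 1L)] != probe)
      if (mm == 0L) perfect <- TRUE
      if (mm <= maxMismatch) partial[ti] <- TRUE
    }
  }
  list(perfect_match = perfect, partial_fraction = mean(partial))
}

# random valid gapmer strings in the annotated dialect
randomGapmers <- function(n, seed, lenRange = c(10L, 25L)) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    len <- sample(seq.int(lenRange[1], lenRange[2]), 1L)
    b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    lna <- sample(c(TRUE, FALSE), len, replace = TRUE)
    b[!lna] <- tolower(b[!lna])
    paste(b, collapse = "")
  }, character(1)))
}

# small tiled study used by several tests
makeStudyPanels <- function(nTrain, nTest, seed = 11L,
                            config = generatorConfig()) {
  target <- simulateTargetPremrna(config$targetLength, config$gcFraction,
                                  seed = seed)
  list(
    train = tileAsos(target, nTrain, config, seed = seed + 1L,
                     prefix = "tr"),
    test = tileAsos(target, nTest, config, seed = seed + 2L,
                    prefix = "te"),
    config = config, target = target)
}
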