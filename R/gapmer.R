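#' Parse an annotated gapmer string
#'
#' The textual gapmer dialect encodes per-position chemistry by letter case:
#' uppercase letters are LNA-modified nucleotides, lowercase letters are DNA
#' nucleotides.  Sequences are written 5'->3' over the alphabet
#' `{A,C,G,T,a,c,g,t}` and must be 10-25 nt long.  Arbitrary per-position
#' patterns are accepted (flanks need not be contiguous), e.g.
#' `"CcAAAtcttataataACtAC"`.
#'
#' @param text annotated gapmer string(s), e.g. `"TCCactaaccaatatAAC"`.
#' @param id optional identifier(s); defaults to `aso_1 ...`.
#' @return an [AsoPanel-class] with one entry per input string.
#' @examples
#' p <- parseGapmer("TCCactaaccaatatAAC", id = "nc1")
#' asoBases(p)   # "TCCACTAACCAATATAAC"
#' asoMods(p)    # "LLLDDDDDDDDDDDDLLL"
#' @export
parseGapmer <- function(text, id = NULL) {
  stopifnot(is.character(text), length(text) >= 1L)
  if (is.null(id)) id <- paste0("aso_", seq_along(text))
  if (length(id) != length(text))
    stop("'id' must match 'text' in length")
  for (i in seq_along(text)) {
    s <- text[[i]]
    if (!nzchar(s)) stop("empty gapmer string (id '", id[[i]], "')")
    bad <- regexpr("[^ACGTacgt]", s)
    if (bad > 0L)
      stop(sprintf(
        "invalid character '%s' at position %d in gapmer '%s'",
        substr(s, bad, bad), bad, id[[i]]))
    if (nchar(s) < 10L || nchar(s) > 25L)
      stop(sprintf("gapmer '%s' has length %d; must be within [10, 25]",
                   id[[i]], nchar(s)))
  }
  mods <- chartr("ACGTacgt", "LLLLDDDD", text)
  AsoPanel(ids = id, bases = toupper(text), mods = mods)
}

#' Serialize gapmers back to the annotated dialect
#'
#' Inverse of [parseGapmer()]: LNA positions are rendered uppercase, DNA
#' positions lowercase, so that `parseGapmer(serializeGapmer(x))` restores
#' the panel exactly.
#'
#' @param panel an [AsoPanel-class].
#' @return character vector of annotated gapmer strings, named by ASO id.
#' @export
serializeGapmer <- function(panel) {
  stopifnot(is(panel, "AsoPanel"))
  out <- vapply(seq_along(panel), function(i) {
    b <- strsplit(panel@bases[[i]], "")[[1]]
    m <- strsplit(panel@mods[[i]], "")[[1]]
    b[m == "D"] <- tolower(b[m == "D"])
    paste(b, collapse = "")
  }, character(1))
  names(out) <- panel@ids
  out
}

#' Construct an AsoPanel
#'
#' @param ids character vector of unique identifiers.
#' @param bases uppercase base strings (5'->3', `{A,C,G,T}`, 10-25 nt).
#' @param mods per-position modification strings over `{L,D}`; default all-DNA.
#' @param annot optional per-ASO annotation `data.frame`/`DataFrame`
#'   (e.g. columns `calcium_score`, `tolerability_score`).
#' @return an [AsoPanel-class] object.
#' @export
AsoPanel <- function(ids = character(), bases = character(), mods = NULL,
                     annot = NULL) {
  ids <- as.character(ids)
  bases <- toupper(as.character(bases))
  if (is.null(mods)) mods <- strrep("D", nchar(bases))
  if (is.null(annot)) {
    annot <- S4Vectors::DataFrame(matrix(nrow = length(ids), ncol = 0))
  } else {
    annot <- S4Vectors::DataFrame(annot)
  }
  new("AsoPanel", ids = ids, bases = bases, mods = as.character(mods),
      annot = annot)
}

#' @describeIn AsoPanel number of ASOs in the panel.
#' @param x,object an `AsoPanel`.
#' @export
setMethod("length", "AsoPanel", function(x) length(x@ids))

#' Panel accessors
#'
#' `asoIds`, `asoBases` and `asoMods` return the identifier, uppercase base
#' string and `{L,D}` modification string of each ASO; `panelAnnot` returns
#' the per-ASO annotation table; `calciumScores` and `tolerabilityScores`
#' return the corresponding annotation columns (`NULL` when absent).
#'
#' @param panel an [AsoPanel-class].
#' @return character vectors (named by id for `asoBases`/`asoMods`), a
#'   `DataFrame`, or numeric score vectors.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
asoIds <- function(panel) panel@ids

#' @rdname panel-accessors
#' @export
asoBases <- function(panel) stats::setNames(panel@bases, panel@ids)

#' @rdname panel-accessors
#' @export
asoMods <- function(panel) stats::setNames(panel@mods, panel@ids)

#' @rdname panel-accessors
#' @export
panelAnnot <- function(panel) panel@annot

#' @rdname panel-accessors
#' @export
calciumScores <- function(panel) {
  if ("calcium_score" %in% colnames(panel@annot))
    stats::setNames(panel@annot$calcium_score, panel@ids)
  else NULL
}

#' @rdname panel-accessors
#' @export
tolerabilityScores <- function(panel) {
  if ("tolerability_score" %in% colnames(panel@annot))
    stats::setNames(panel@annot$tolerability_score, panel@ids)
  else NULL
}

#' Attach or replace an annotation column
#'
#' @param panel an [AsoPanel-class].
#' @param name column name (e.g. `"calcium_score"`).
#' @param value numeric vector, one value per ASO.
#' @return the panel with the column set.
#' @export
setPanelAnnot <- function(panel, name, value) {
  stopifnot(length(value) == length(panel))
  panel@annot[[name]] <- value
  validObject(panel)
  panel
}

#' @describeIn AsoPanel subset a panel by index, id or logical mask.
#' @param i index vector.
#' @param j,drop,... ignored (matrix-style calls are not supported).
#' @export
setMethod("[", "AsoPanel", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("AsoPanel", ids = x@ids[i], bases = x@bases[i], mods = x@mods[i],
      annot = x@annot[i, , drop = FALSE])
})

setMethod("show", "AsoPanel", function(object) {
  cat(sprintf("AsoPanel with %d ASO%s (full PS backbone)\n",
              length(object), if (length(object) == 1L) "" else "s"))
  n <- min(length(object), 6L)
  if (n > 0L) {
    s <- serializeGapmer(object[seq_len(n)])
    cat(sprintf("  %-12s %s\n", names(s), s), sep = "")
    if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                        length(object) - n))
  }
  if (ncol(object@annot) > 0L)
    cat("annotations:", paste(colnames(object@annot), collapse = ", "), "\n")
})

#' Read an ASO panel from FASTA or TSV
#'
#' FASTA records hold annotated gapmer strings (case = chemistry) as their
#' sequence lines, one record per ASO.  Tabular files are tab- (`.tsv`) or
#' comma-separated (`.csv`) with a header and columns `id`, `sequence`,
#' plus optional `calcium_score` and `tolerability_score` which are attached
#' as panel annotations.
#'
#' @param path input file.
#' @param format `"fasta"` or `"tsv"` (`"tsv"` also covers CSV); guessed from
#'   the file extension by default.
#' @return an [AsoPanel-class]; an empty file yields an empty panel with a
#'   warning.
#' @export
readPanel <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    recs <- Biostrings::readBStringSet(path)
    if (length(recs) == 0L) {
      warning("empty FASTA file: ", path)
      return(AsoPanel())
    }
    ids <- sub("\\s.*$", "", names(recs))
    if (anyDuplicated(ids))
      stop("duplicate ids in FASTA panel: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    parseGapmer(as.character(recs), id = ids)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(tab) == 0L) {
      warning("empty panel table: ", path)
      return(AsoPanel())
    }
    need <- c("id", "sequence")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
      stop("panel table is missing required column(s): ",
           paste(miss, collapse = ", "))
    if (anyDuplicated(tab$id))
      stop("duplicate ids in panel table: ",
           paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
    panel <- parseGapmer(tab$sequence, id = as.character(tab$id))
    for (col in intersect(c("calcium_score", "tolerability_score"),
                          colnames(tab)))
      panel <- setPanelAnnot(panel, col, as.numeric(tab[[col]]))
    panel
  }
}

#' Write an ASO panel to FASTA or TSV
#'
#' @param panel an [AsoPanel-class].
#' @param path output file.
#' @inheritParams readPanel
#' @return invisibly, `path`.
#' @export
writePanel <- function(panel, path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  ann <- serializeGapmer(panel)
  if (format == "fasta") {
    recs <- Biostrings::BStringSet(ann)
    Biostrings::writeXStringSet(recs, path)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- data.frame(id = asoIds(panel), sequence = unname(ann),
                      stringsAsFactors = FALSE)
    for (col in intersect(c("calcium_score", "tolerability_score"),
                          colnames(panel@annot)))
      tab[[col]] <- panel@annot[[col]]
    utils::write.table(tab, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
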