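#' Published G-free negative-control gapmer panel
#'
#' A published panel of 13 LNA gapmers designed as general negative
#' controls with very low acute neurotoxic potential: no guanine anywhere
#' in the sequence, adenine roughly balancing thymine plus cytosine, no
#' perfectly matching (and only rare partially mismatched) sites in the
#' mouse transcriptome, and calculated sequence scores all above 70.  All
#' were well tolerated in vivo (group-mean acute tolerability scores
#' below 1).
#'
#' @param withReference if `TRUE`, return a list with the panel and the
#'   printed reference table (`n_a`, `n_t`, `n_c`, `n_g`,
#'   `calculated_score`, `tolerance_score` per design).
#' @return an [AsoPanel-class] (or a list, see `withReference`).
#' @examples
#' nc <- negativeControlPanel()
#' all(countNucleotides(nc)[, "n_g"] == 0)
#' @export
negativeControlPanel <- function(withReference = FALSE) {
  fa <- system.file("extdata", "negative_controls.fasta",
                    package = "gapmerTox", mustWork = TRUE)
  panel <- readPanel(fa, format = "fasta")
  if (!withReference) return(panel)
  tsv <- system.file("extdata", "negative_controls.tsv",
                     package = "gapmerTox", mustWork = TRUE)
  ref <- utils::read.table(tsv, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  list(panel = panel, reference = ref)
}
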