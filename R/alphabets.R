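AA_STATES <- c("A","R","N","D","C","Q","E","G","H","I",
               "L","K","M","F","P","S","T","W","Y","V")
NT_STATES <- c("A","C","G","T")
NT_IUPAC_PARTIAL <- c("R","Y","S","W","K","M","B","D","H","V")

#' Alphabet definition used by alignments
#'
#' Returns the observable state set and the default ambiguity/missing set for
#' an alphabet. Ambiguous symbols are treated as missing data throughout:
#' they are excluded from symmetry tests, composition scores and
#' completeness counts, and enter likelihoods as uninformative tips.
#' For nucleotide data the IUPAC partial-ambiguity codes are treated as
#' missing by default (configurable via `iupac_missing`).
#'
#' @param alphabet `"AA"` or `"NT"`.
#' @param iupac_missing for NT, treat IUPAC partial codes as missing
#'   (default `TRUE`).
#' @return list with `states`, `missing`, `name`.
#' @export
alphabet_def <- function(alphabet = c("AA", "NT"), iupac_missing = TRUE) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "AA") {
    list(name = "AA", states = AA_STATES, missing = c("X", "-", "?", "*"))
  } else {
    miss <- c("N", "-", "?")
    if (iupac_missing) miss <- c(miss, NT_IUPAC_PARTIAL)
    list(name = "NT", states = NT_STATES, missing = miss)
  }
}
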