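#' The standard genetic code
#'
#' Returns the standard genetic code (NCBI translation table 1) as a named
#' character vector mapping DNA codons to one-letter amino-acid codes, with
#' `"*"` for the three stop codons. Backed by [Biostrings::GENETIC_CODE].
#'
#' @return named character vector of length 64.
#' @examples
#' genetic_code()[["ATG"]]  # "M"
#' @export
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Sense codons of the standard code
#'
#' @return character vector of the 61 non-stop DNA codons, sorted.
#' @export
sense_codons <- function() {
  gc <- genetic_code()
  sort(names(gc)[gc != "*"])
}

#' Stop codons of the standard code
#'
#' @return character vector: TAA, TAG, TGA.
#' @export
stop_codons <- function() {
  gc <- genetic_code()
  sort(names(gc)[gc == "*"])
}

#' Synonymous codons of an amino acid
#'
#' @param amino_acid one-letter amino-acid code.
#' @return character vector of codons translating to `amino_acid`, sorted.
#' @export
synonymous_codons <- function(amino_acid) {
  gc <- genetic_code()
  sort(names(gc)[gc == amino_acid])
}

#' Translate a frame-0 coding sequence
#'
#' Translates a CDS under the standard genetic code. A trailing stop codon is
#' dropped from the returned protein; internal stop codons are kept as `"*"`
#' and reported with a warning (their 1-based codon positions).
#'
#' @param cds nucleotide string (DNA or RNA), length divisible by 3.
#' @return amino-acid string (one-letter codes).
#' @examples
#' translate_cds("ATGTAA")      # "M"
#' translate_cds("TCCAGCTCG")   # "SSS": three synonymous serine codons
#' @export
translate_cds <- function(cds) {
  codons <- split_codons(cds)
  if (length(codons) == 0L) return("")
  gc <- genetic_code()
  aa <- unname(gc[codons])
  stopifnot(!anyNA(aa))
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  internal <- which(aa == "*")
  if (length(internal) > 0L) {
    warning(sprintf("internal stop codon(s) at codon position(s): %s",
                    paste(internal, collapse = ", ")), call. = FALSE)
  }
  paste(aa, collapse = "")
}
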