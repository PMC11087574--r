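#' Codon usage profile of a coding sequence
#'
#' Counts every in-frame codon of a frame-0 CDS. Following the usual
#' codon-usage convention, the terminal stop codon is excluded and
#' frequencies are counts over total sense codons. Internal stop codons
#' trigger a warning naming their codon positions and are excluded from the
#' denominator.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @param id optional CDS label stored as an attribute.
#' @return data.frame of class `codon_usage_table` with `codon`,
#'   `amino_acid`, `count`, `frequency`, sorted by decreasing frequency then
#'   codon; attribute `total` holds the sense-codon count.
#' @examples
#' codon_frequency("ATGTCCTCCTAA")
#' @export
codon_frequency <- function(cds, id = NULL) {
  codons <- split_codons(cds)
  gc <- genetic_code()
  n <- length(codons)
  if (n > 0L && gc[[codons[n]]] == "*") codons <- codons[-n]
  internal <- which(gc[codons] == "*")
  if (length(internal) > 0L) {
    warning(sprintf("internal stop codon(s) at codon position(s): %s",
                    paste(internal, collapse = ", ")), call. = FALSE)
    codons <- codons[gc[codons] != "*"]
  }
  if (length(codons) == 0L) {
    out <- data.frame(codon = character(0), amino_acid = character(0),
                      count = integer(0), frequency = numeric(0))
  } else {
    tab <- table(codons)
    out <- data.frame(codon = names(tab), amino_acid = unname(gc[names(tab)]),
                      count = as.integer(tab),
                      frequency = as.integer(tab) / length(codons),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$frequency, out$codon), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "total") <- length(codons)
  attr(out, "cds_id") <- id
  class(out) <- c("codon_usage_table", "data.frame")
  out
}

#' Cross-reference codon usage with tRNA m1A58 sensitivity
#'
#' Identifies translationally vulnerable codons: those that are both decoded
#' by one of the `k_top` tRNAs most affected by methyltransferase loss and
#' among the `m` most frequently used codons of the CDS.
#'
#' @param usage a [codon_frequency] table.
#' @param delta a [delta_m1a] table.
#' @param map a [build_decoding_map] result.
#' @param k_top size of the most-affected tRNA set (default 4).
#' @param m frequency-rank cutoff (default 10).
#' @return data.frame of class `vulnerability_report` with per-codon
#'   `frequency`, `freq_rank`, decoding `trna_ids` (semicolon-joined,
#'   `"unmapped"` when no tRNA decodes the codon), the maximum `delta` over
#'   decoding tRNAs, and logical `vulnerable`; sorted by decreasing
#'   frequency with ties broken by codon.
#' @export
vulnerability_report <- function(usage, delta, map, k_top = 4L, m = 10L) {
  if (nrow(delta) == 0L) stop("empty delta table", call. = FALSE)
  stopifnot(inherits(map, "decoding_map"), m >= 0)
  affected <- rank_trnas(delta, k_top = min(k_top, nrow(delta)))$most_affected
  out <- usage[order(-usage$frequency, usage$codon), , drop = FALSE]
  out$freq_rank <- seq_len(nrow(out))
  deco <- lapply(out$codon, function(cd) map[[cd]])
  out$trna_ids <- vapply(deco, function(x)
    if (is.null(x)) "unmapped" else paste(sort(x), collapse = ";"),
    character(1))
  out$delta <- vapply(deco, function(x) {
    if (is.null(x)) return(NA_real_)
    d <- delta$delta[match(x, delta$tRNA_id)]
    if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
  }, numeric(1))
  out$vulnerable <- vapply(deco, function(x)
    !is.null(x) && any(x %in% affected), logical(1)) & out$freq_rank <= m
  rownames(out) <- NULL
  class(out) <- c("vulnerability_report", "data.frame")
  attr(out, "most_affected") <- affected
  out
}
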