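# Shared fixture builders. Everything is generated in code; no stored data.

# The four focal decoders plus the two escape decoders of the worked example.
focal_codons <- c("TCC", "AGC", "CTG", "TTG")
escape_codons <- c("TCG", "CTT")

make_reference <- function(codons, seed = 11L) {
  generate_trna_reference(length(codons), seed = seed, codons = codons)
}

# Hand-built delta table with chosen delta per tRNA id (bypasses simulation).
make_delta <- function(ids, deltas, codons = NA_character_) {
  out <- data.frame(tRNA_id = ids, decoded_codons = codons,
                    level_WT = pmin(1, deltas + 0.05), level_KO = 0.05,
                    delta = deltas, stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$tRNA_id), , drop = FALSE]
  out$rank <- cumsum(!duplicated(out$delta))
  rownames(out) <- NULL
  class(out) <- c("delta_table", "data.frame")
  out
}

# Independent translation oracle: Biostrings' translator, not the package's
# codon-lookup loop.
oracle_translate <- function(cds) {
  # no.init.codon: plain translation, no special-casing of CTG/TTG starts
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

# Independent codon counting oracle: stride-3 substring loop.
oracle_codon_counts <- function(cds) {
  n <- nchar(cds)
  counts <- list()
  for (i in seq(1, n, by = 3)) {
    cd <- substr(cds, i, i + 2)
    counts[[cd]] <- (counts[[cd]] %||% 0L) + 1L
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_cds <- function(n_codons, seed) {
  with_seed(seed, {
    paste0(paste(sample(sense_codons(), n_codons, replace = TRUE),
                 collapse = ""), "TAA")
  })
}

# Full 61-codon reference: one strict decoder per sense codon.
full_reference <- function(seed = 5L) {
  make_reference(sense_codons(), seed = seed)
}
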