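#' Locate the m1A58 site via the T-loop consensus
#'
#' Cytosolic tRNA m1A sites sit inside a conserved T-loop 9-mer with
#' consensus GUUCNANNC, in which the single fixed adenosine (the 6th base of
#' the 9-mer) is the methylated position — position 58 by canonical tRNA
#' numbering. This function scans 5'->3' for the first consensus match and
#' returns the 0-based index of that adenosine. Synthetic tRNAs need not be
#' 76 nt, so "position 58" is located operationally by the motif rather than
#' by absolute coordinate.
#'
#' @param sequence tRNA sequence (DNA or RNA alphabet; U and T equivalent).
#' @return 0-based index of the m1A adenosine, or `NA_integer_` if the
#'   consensus is absent.
#' @examples
#' locate_position58("GUUCGAAUC")  # 5
#' @export
locate_position58 <- function(sequence) {
  seq_dna <- normalize_dna(sequence, "tRNA sequence")
  m <- regexpr("GTTC[ACGT]A[ACGT][ACGT]C", seq_dna)
  if (m == -1L) return(NA_integer_)
  # regexpr start is 1-based; the fixed A is the 6th base of the 9-mer.
  as.integer(m - 1L + 5L)
}

#' Construct a tRNA species record
#'
#' One tRNA family, named by the codon it decodes (the field convention used
#' when relating tRNA modification changes to mRNA codon content). The
#' anticodon is stored but the public identifier is built from the decoded
#' codon.
#'
#' @param id unique text label, e.g. `"tRNA-Ser-TCC"`.
#' @param anticodon 3-mer, written 5'->3' (RNA or DNA; `I` allowed at the
#'   wobble position 34 for inosine).
#' @param amino_acid one-letter amino-acid code.
#' @param sequence full tRNA sequence (DNA or RNA).
#' @param decoded_codons DNA codons this tRNA decodes; defaults to the
#'   Watson-Crick reverse complement of the anticodon.
#' @param pos58 0-based index of the m1A58 adenosine; located from the T-loop
#'   consensus when `NULL`.
#' @return object of class `trna_species`.
#' @export
trna_species <- function(id, anticodon, amino_acid, sequence,
                         decoded_codons = NULL, pos58 = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  anticodon <- toupper(chartr("u", "U", anticodon))
  anticodon <- chartr("U", "T", anticodon)
  if (!grepl("^[ACGTI][ACGT][ACGT]$", anticodon)) {
    stop("anticodon must be a 3-mer over ACGTU (I allowed at position 34)",
         call. = FALSE)
  }
  sequence <- normalize_dna(sequence, "tRNA sequence")
  # Inosine at 34 arises by deamination of A34; its WC-coded codon uses C3.
  wc_anticodon <- chartr("I", "A", anticodon)
  primary <- revcomp(wc_anticodon)
  if (substr(anticodon, 1, 1) == "I") {
    substr(primary, 3, 3) <- "C"
  }
  if (is.null(decoded_codons)) decoded_codons <- primary
  decoded_codons <- toupper(decoded_codons)
  gc <- genetic_code()
  bad <- decoded_codons[gc[decoded_codons] != amino_acid]
  if (length(bad) > 0L || anyNA(gc[decoded_codons])) {
    stop(sprintf("decoded codon(s) inconsistent with amino acid %s: %s",
                 amino_acid, paste(bad, collapse = ", ")), call. = FALSE)
  }
  # Wobble is confined to codon position 3: positions 1-2 must be WC.
  if (any(substr(decoded_codons, 1, 2) != substr(primary, 1, 2))) {
    stop("decoded codons must match the anticodon at codon positions 1-2",
         call. = FALSE)
  }
  if (is.null(pos58)) pos58 <- locate_position58(sequence)
  if (!is.na(pos58)) {
    pos58 <- as.integer(pos58)
    if (substr(sequence, pos58 + 1L, pos58 + 1L) != "A") {
      stop("pos58 must index an adenosine", call. = FALSE)
    }
    window_start <- pos58 - 5L
    if (window_start < 0L ||
        !grepl("^GTTC[ACGT]A[ACGT][ACGT]C",
               substr(sequence, window_start + 1L, window_start + 9L))) {
      stop("pos58 must be the fixed A of a GUUCNANNC T-loop window",
           call. = FALSE)
    }
  }
  structure(
    list(id = id, anticodon = anticodon, amino_acid = amino_acid,
         sequence = sequence, decoded_codons = sort(unique(decoded_codons)),
         primary_codon = primary, pos58 = pos58),
    class = "trna_species"
  )
}

#' @export
print.trna_species <- function(x, ...) {
  cat(sprintf("<trna_species> %s  aa=%s anticodon=%s codons={%s} pos58=%s\n",
              x$id, x$amino_acid, x$anticodon,
              paste(x$decoded_codons, collapse = ","),
              ifelse(is.na(x$pos58), "NA", x$pos58)))
  invisible(x)
}

# Codons reachable from an anticodon under a wobble policy. The anticodon is
# 5'->3'; its first base (position 34) pairs codon position 3.
wobble_codons <- function(anticodon, policy = c("strict", "crick")) {
  policy <- match.arg(policy)
  n34 <- substr(anticodon, 1, 1)
  stem <- revcomp(chartr("I", "A", substr(anticodon, 2, 3)))  # codon pos 1-2
  third <- if (policy == "strict") {
    switch(n34, A = "T", C = "G", G = "C", T = "A", I = "C")
  } else {
    # Crick wobble rules at anticodon position 34.
    switch(n34,
           A = "T",
           C = "G",
           G = c("C", "T"),
           T = c("A", "G"),
           I = c("T", "C", "A"))
  }
  paste0(stem, third)
}

#' Build the codon -> tRNA decoding map
#'
#' Maps each codon to the tRNA species able to decode it under a wobble
#' policy. `strict` admits only the exact Watson-Crick reverse complement of
#' the anticodon; `crick` additionally allows the classical wobble pairings
#' at anticodon position 34 (G34:U/C, U34:A/G, I34:U/C/A). Wobble expansions
#' that would change the encoded amino acid (e.g. a U34 Ile anticodon
#' reaching the Met codon) are excluded, so every mapped tRNA's amino acid
#' equals the codon's translation.
#'
#' @param trnas list of [trna_species] objects.
#' @param wobble_policy `"strict"` (default) or `"crick"`.
#' @return object of class `decoding_map`: a named list codon -> character
#'   vector of tRNA ids, with the policy stored as an attribute.
#' @export
build_decoding_map <- function(trnas, wobble_policy = c("strict", "crick")) {
  wobble_policy <- match.arg(wobble_policy)
  stopifnot(is.list(trnas), length(trnas) > 0L)
  ids <- vapply(trnas, function(t) t$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate tRNA ids in reference set", call. = FALSE)
  }
  gc <- genetic_code()
  map <- list()
  for (t in trnas) {
    if (!inherits(t, "trna_species")) stop("trnas must be trna_species objects")
    codons <- wobble_codons(t$anticodon, wobble_policy)
    codons <- codons[gc[codons] == t$amino_acid]
    for (cd in codons) map[[cd]] <- c(map[[cd]], t$id)
  }
  map <- map[order(names(map))]
  structure(map, class = "decoding_map", wobble_policy = wobble_policy)
}

#' @export
print.decoding_map <- function(x, ...) {
  cat(sprintf("<decoding_map> %d codons, policy=%s\n",
              length(x), attr(x, "wobble_policy")))
  invisible(x)
}

#' Tabulate a tRNA reference set
#'
#' @param trnas list of [trna_species] objects.
#' @return data.frame with one row per tRNA (id, amino_acid, anticodon,
#'   decoded_codons semicolon-joined, pos58, sequence).
#' @export
trna_reference_table <- function(trnas) {
  data.frame(
    id = vapply(trnas, `[[`, character(1), "id"),
    amino_acid = vapply(trnas, `[[`, character(1), "amino_acid"),
    anticodon = vapply(trnas, `[[`, character(1), "anticodon"),
    decoded_codons = vapply(trnas, function(t)
      paste(t$decoded_codons, collapse = ";"), character(1)),
    pos58 = vapply(trnas, function(t)
      if (is.na(t$pos58)) NA_integer_ else t$pos58, integer(1)),
    sequence = vapply(trnas, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE
  )
}

#' Write a tRNA reference set to FASTA + TSV
#'
#' @param trnas list of [trna_species] objects.
#' @param fasta,tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_trna_reference <- function(trnas, fasta, tsv) {
  tab <- trna_reference_table(trnas)
  seqs <- Biostrings::DNAStringSet(stats::setNames(tab$sequence, tab$id))
  Biostrings::writeXStringSet(seqs, fasta)
  write_tsv(tab[, c("id", "amino_acid", "anticodon", "decoded_codons",
                    "pos58")], tsv)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Read a tRNA reference set from FASTA + TSV
#'
#' @param fasta FASTA of tRNA sequences, names matching the TSV `id` column.
#' @param tsv metadata with columns id, amino_acid, anticodon,
#'   decoded_codons (semicolon-separated) and optionally pos58.
#' @return list of [trna_species] objects.
#' @export
read_trna_reference <- function(fasta, tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tab <- read_tsv(tsv)
  stopifnot(all(c("id", "amino_acid", "anticodon", "decoded_codons")
                %in% names(tab)))
  missing <- setdiff(tab$id, names(seqs))
  if (length(missing) > 0L) {
    stop(sprintf("tRNA id(s) absent from FASTA: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    pos58 <- if ("pos58" %in% names(tab) && !is.na(tab$pos58[i])) {
      as.integer(tab$pos58[i])
    } else NULL
    trna_species(
      id = tab$id[i], anticodon = tab$anticodon[i],
      amino_acid = tab$amino_acid[i],
      sequence = as.character(seqs[[tab$id[i]]]),
      decoded_codons = strsplit(tab$decoded_codons[i], ";", fixed = TRUE)[[1]],
      pos58 = pos58
    )
  })
}
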