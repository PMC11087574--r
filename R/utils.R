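#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state so package functions never clobber a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage/per-row child seed from one master seed. Kept strictly
# below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Normalise a nucleotide string to upper-case DNA
#'
#' RNA input is accepted and mapped U->T; any other character is an error.
#'
#' @param x character scalar.
#' @param what label used in error messages.
#' @return upper-case DNA string over ACGT.
#' @keywords internal
normalize_dna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  if (grepl("[^ACGT]", x)) {
    stop(sprintf("invalid character in %s: alphabet must be A/C/G/T/U", what),
         call. = FALSE)
  }
  x
}

revcomp <- function(x) {
  x <- normalize_dna(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Split a frame-0 CDS into its codons (character vector of 3-mers).
split_codons <- function(cds) {
  cds <- normalize_dna(cds, "CDS")
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length must be divisible by 3 (frame-0)", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
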