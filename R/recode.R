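#' Design a synonymous codon-switch recoding plan
#'
#' Implements the codon-switch design rule: for every amino acid with codons
#' decoded by one of the `k_top` most modification-sensitive tRNAs, replace
#' those codons with the synonymous codon whose decoding tRNA shows the
#' smallest m1A58 decrease (the least-affected escape codon). One
#' replacement codon per amino acid; ties are broken by codon lexicographic
#' order. Amino acids with no affected codon get no rule; amino acids whose
#' every synonymous codon is decoded by an affected tRNA (or is unmapped)
#' are skipped with a warning — a protein-changing substitution is never
#' emitted.
#'
#' @param delta a [delta_m1a] table.
#' @param map a [build_decoding_map] result.
#' @param k_top size of the most-affected tRNA set (default 4).
#' @return data.frame of class `recoding_plan` with one rule per row:
#'   `amino_acid`, `source_codons` (semicolon-joined), `replacement_codon`,
#'   `note` (provenance: which Delta ranking produced the rule).
#' @export
build_recoding_plan <- function(delta, map, k_top = 4L) {
  stopifnot(inherits(map, "decoding_map"))
  if (k_top == 0L || nrow(delta) == 0L) {
    return(empty_plan())
  }
  affected <- rank_trnas(delta, k_top = min(k_top, nrow(delta)))$most_affected
  gc <- genetic_code()
  # Minimum delta over the tRNAs decoding each mapped codon.
  codon_delta <- vapply(names(map), function(cd) {
    d <- delta$delta[match(map[[cd]], delta$tRNA_id)]
    if (all(is.na(d))) NA_real_ else min(d, na.rm = TRUE)
  }, numeric(1))
  source_codons <- names(map)[vapply(map, function(ids)
    any(ids %in% affected), logical(1))]
  aas <- sort(unique(unname(gc[source_codons])))
  rules <- lapply(aas, function(aa) {
    src <- sort(source_codons[gc[source_codons] == aa])
    cand <- setdiff(synonymous_codons(aa), src)
    cand <- cand[cand %in% names(map)]
    cand <- cand[!vapply(cand, function(cd)
      any(map[[cd]] %in% affected), logical(1))]
    cand <- cand[!is.na(codon_delta[cand])]
    if (length(cand) == 0L) {
      warning(sprintf(
        "no synonymous escape codon for %s (sources %s): rule skipped",
        aa, paste(src, collapse = ",")), call. = FALSE)
      return(NULL)
    }
    cand <- cand[order(codon_delta[cand], cand)]
    data.frame(
      amino_acid = aa,
      source_codons = paste(src, collapse = ";"),
      replacement_codon = cand[[1]],
      note = sprintf("replacement decoded by %s (delta=%.4g); top-%d affected: %s",
                     paste(map[[cand[[1]]]], collapse = ","),
                     codon_delta[[cand[[1]]]], length(affected),
                     paste(affected, collapse = ",")),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, Filter(Negate(is.null), rules))
  if (is.null(out)) return(empty_plan())
  rownames(out) <- NULL
  class(out) <- c("recoding_plan", "data.frame")
  validate_plan(out)
  out
}

empty_plan <- function() {
  out <- data.frame(amino_acid = character(0), source_codons = character(0),
                    replacement_codon = character(0), note = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("recoding_plan", "data.frame")
  out
}

#' Construct a recoding plan by hand
#'
#' @param amino_acid one-letter codes, one per rule.
#' @param source_codons list (or semicolon-joined character) of source
#'   codons per rule.
#' @param replacement_codon replacement per rule.
#' @param note optional provenance notes.
#' @return `recoding_plan` data.frame, validated.
#' @export
recoding_plan <- function(amino_acid, source_codons, replacement_codon,
                          note = "") {
  if (is.list(source_codons)) {
    source_codons <- vapply(source_codons, paste, character(1),
                            collapse = ";")
  }
  out <- data.frame(amino_acid = amino_acid, source_codons = source_codons,
                    replacement_codon = replacement_codon,
                    note = rep_len(note, length(amino_acid)),
                    stringsAsFactors = FALSE)
  class(out) <- c("recoding_plan", "data.frame")
  validate_plan(out)
  out
}

validate_plan <- function(plan) {
  gc <- genetic_code()
  if (anyDuplicated(plan$amino_acid)) {
    stop("recoding plan must have at most one rule per amino acid",
         call. = FALSE)
  }
  for (i in seq_len(nrow(plan))) {
    src <- strsplit(plan$source_codons[i], ";", fixed = TRUE)[[1]]
    rep_cd <- plan$replacement_codon[i]
    aa <- plan$amino_acid[i]
    if (any(gc[src] != aa) || gc[[rep_cd]] != aa) {
      stop(sprintf("rule %d: codons do not all encode %s", i, aa),
           call. = FALSE)
    }
    if (rep_cd %in% src) {
      stop(sprintf("rule %d: replacement codon is a source codon", i),
           call. = FALSE)
    }
  }
  invisible(plan)
}

# source codon -> replacement lookup for a plan
plan_lookup <- function(plan) {
  if (nrow(plan) == 0L) return(stats::setNames(character(0), character(0)))
  src <- strsplit(plan$source_codons, ";", fixed = TRUE)
  stats::setNames(rep(plan$replacement_codon, lengths(src)), unlist(src))
}

#' Recode a CDS under a codon-switch plan
#'
#' Replaces every in-frame occurrence of a source codon by its rule's
#' replacement codon; all other codons (including stops) are untouched, so
#' the encoded protein is preserved exactly. An internal stop in the input
#' is reported with a warning and left alone.
#'
#' @param cds frame-0 nucleotide string.
#' @param plan a [recoding_plan].
#' @param id optional CDS label.
#' @return object of class `recoded_cds`: list with `id`, `sequence`,
#'   `log` (data.frame: 0-based nt `position` of the codon start, `from`,
#'   `to`), and `counts` (substitutions per rule source codon).
#' @export
recode_cds <- function(cds, plan, id = NULL) {
  validate_plan(plan)
  codons <- split_codons(cds)
  gc <- genetic_code()
  internal <- which(gc[codons] == "*" & seq_along(codons) < length(codons))
  if (length(internal) > 0L) {
    warning(sprintf("internal stop codon(s) at codon position(s): %s; left unmodified",
                    paste(internal, collapse = ", ")), call. = FALSE)
  }
  lookup <- plan_lookup(plan)
  hit <- codons %in% names(lookup)
  log <- data.frame(
    position = (which(hit) - 1L) * 3L,
    from = codons[hit],
    to = unname(lookup[codons[hit]]),
    stringsAsFactors = FALSE
  )
  codons[hit] <- lookup[codons[hit]]
  structure(
    list(id = id, sequence = paste(codons, collapse = ""), log = log,
         counts = if (nrow(log)) table(log$from) else table(character(0))),
    class = "recoded_cds"
  )
}

#' @export
print.recoded_cds <- function(x, ...) {
  cat(sprintf("<recoded_cds> %s: %d nt, %d substitution(s)\n",
              if (is.null(x$id)) "(unnamed)" else x$id,
              nchar(x$sequence), nrow(x$log)))
  invisible(x)
}

#' Verify a codon-switch recoding
#'
#' In-silico functional check of a recoded CDS: (a) exact protein identity
#' with the original, (b) zero remaining source codons, (c) consistency of
#' the substitution log with the actual sequence diff and the plan rules.
#' Failures are report findings, not errors; the first offending codon
#' position (0-based nt of the codon start) is named.
#'
#' @param original the original CDS string.
#' @param recoded a [recode_cds] result (or a plain recoded string).
#' @param plan the [recoding_plan] used.
#' @return list with logicals `protein_identical`, `no_residual_source`,
#'   `log_consistent`, overall `ok`, and `first_offending_position`
#'   (`NA` when all checks pass).
#' @export
verify_recoding <- function(original, recoded, plan) {
  validate_plan(plan)
  if (inherits(recoded, "recoded_cds")) {
    rec_seq <- recoded$sequence
    log <- recoded$log
  } else {
    rec_seq <- recoded
    log <- NULL
  }
  orig_codons <- split_codons(original)
  rec_codons <- split_codons(rec_seq)
  lookup <- plan_lookup(plan)
  offending <- integer(0)

  prot_ok <- length(orig_codons) == length(rec_codons) &&
    identical(suppressWarnings(translate_cds(original)),
              suppressWarnings(translate_cds(rec_seq)))
  if (!prot_ok && length(orig_codons) == length(rec_codons)) {
    gc <- genetic_code()
    bad <- which(gc[orig_codons] != gc[rec_codons])
    offending <- c(offending, (bad - 1L) * 3L)
  }

  residual <- which(rec_codons %in% names(lookup))
  res_ok <- length(residual) == 0L
  offending <- c(offending, (residual - 1L) * 3L)

  log_ok <- TRUE
  if (length(orig_codons) == length(rec_codons)) {
    diff_idx <- which(orig_codons != rec_codons)
    expected <- data.frame(
      position = (diff_idx - 1L) * 3L,
      from = orig_codons[diff_idx],
      to = rec_codons[diff_idx],
      stringsAsFactors = FALSE
    )
    rule_ok <- expected$from %in% names(lookup) &
      expected$to == unname(lookup[expected$from])
    if (any(!rule_ok)) {
      log_ok <- FALSE
      offending <- c(offending, expected$position[!rule_ok])
    }
    if (!is.null(log)) {
      same <- nrow(log) == nrow(expected) &&
        all(log$position == expected$position) &&
        all(log$from == expected$from) && all(log$to == expected$to)
      if (!same) {
        log_ok <- FALSE
        mism <- setdiff(union(log$position, expected$position),
                        intersect(log$position, expected$position))
        offending <- c(offending, mism)
      }
    }
  } else {
    log_ok <- FALSE
    offending <- c(offending, 0L)
  }

  list(
    protein_identical = prot_ok,
    no_residual_source = res_ok,
    log_consistent = log_ok,
    ok = prot_ok && res_ok && log_ok,
    first_offending_position = if (length(offending) == 0L) NA_integer_
                               else min(offending)
  )
}

#' Read / write a recoding plan as TSV
#'
#' @param plan a [recoding_plan].
#' @param path TSV path.
#' @return the path (write) or the plan (read).
#' @export
write_recoding_plan <- function(plan, path) write_tsv(plan, path)

#' @rdname write_recoding_plan
#' @export
read_recoding_plan <- function(path) {
  df <- read_tsv(path)
  df$amino_acid <- as.character(df$amino_acid)
  recoding_plan(df$amino_acid, df$source_codons, df$replacement_codon,
                if ("note" %in% names(df)) df$note else "")
}
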