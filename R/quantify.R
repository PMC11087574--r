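#' Read / write pileup tables
#'
#' The pileup dialect is a TSV with columns `tRNA_id`, `position` (0-based),
#' `count_A`, `count_C`, `count_G`, `count_T`, `count_stop`, and optionally
#' `ref_base` and `condition`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_pileup <- function(path) {
  df <- read_tsv(path)
  need <- c("tRNA_id", "position", "count_A", "count_C", "count_G",
            "count_T", "count_stop")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("pileup missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname read_pileup
#' @param pileup pileup data.frame.
#' @export
write_pileup <- function(pileup, path) write_tsv(pileup, path)

#' Misincorporation and stop rates at one pileup position
#'
#' The standard m1A readout: `mismatch_rate` is the fraction of base-called
#' reads carrying a non-reference base; `stop_rate` is the fraction of reads
#' entering the position at which RT terminated. Reads entering = base calls
#' + stops, which at the m1A58 column of a full-length-from-3' library
#' equals the read depth.
#'
#' @param pileup pileup data.frame (one or more tRNAs).
#' @param trna_id tRNA to interrogate.
#' @param position 0-based position.
#' @param ref_base reference base at the position; taken from the pileup's
#'   `ref_base` column when present.
#' @return list with `mismatch_rate`, `stop_rate`, `coverage` (reads
#'   entering the position).
#' @export
misincorporation_rate <- function(pileup, trna_id, position,
                                  ref_base = NULL) {
  row <- pileup[pileup$tRNA_id == trna_id & pileup$position == position, ,
                drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("expected exactly one pileup row for %s position %d, got %d",
                 trna_id, position, nrow(row)), call. = FALSE)
  }
  if (is.null(ref_base)) {
    if (!"ref_base" %in% names(row)) {
      stop("ref_base column absent; supply ref_base explicitly", call. = FALSE)
    }
    ref_base <- row$ref_base
  }
  stopifnot(ref_base %in% c("A", "C", "G", "T"))
  counts <- c(A = row$count_A, C = row$count_C, G = row$count_G,
              T = row$count_T)
  base_total <- sum(counts)
  entering <- base_total + row$count_stop
  mism <- base_total - counts[[ref_base]]
  list(
    mismatch_rate = if (base_total > 0) mism / base_total else NA_real_,
    stop_rate = if (entering > 0) row$count_stop / entering else NA_real_,
    coverage = entering
  )
}

#' Estimate m1A58 stoichiometry from the RT signature
#'
#' Method-of-moments inversion of the generative model using both signals.
#' With stoichiometry s, misincorporation probability `p_mis`, stop
#' probability `p_stop` and background error `e_bg`, the expected fraction
#' of reads showing *any* signature (wrong base or stop) among reads
#' entering the site is
#'
#'   r = s (p_mis + p_stop) + (1 - s) e_bg
#'
#' so  s-hat = (r - e_bg) / (p_mis + p_stop - e_bg),  clipped to `[0, 1]`.
#' The observed r is reconstructed from the two rates as
#' `mismatch_rate * (1 - stop_rate) + stop_rate` (mismatch_rate is
#' conditioned on a base call; stops occupy the complementary fraction).
#'
#' @param mismatch_rate,stop_rate observed rates at the m1A58 site.
#' @param model an [error_model] with known (or assumed) parameters.
#' @return estimated stoichiometry in `[0, 1]`, or `NA` (with a warning)
#'   when `p_mis + p_stop = 0` leaves s unidentifiable despite signal.
#' @export
estimate_stoichiometry <- function(mismatch_rate, stop_rate,
                                   model = error_model()) {
  stopifnot(inherits(model, "error_model"))
  r <- mismatch_rate * (1 - stop_rate) + stop_rate
  denom <- model$p_mis + model$p_stop - model$e_bg
  if (model$p_mis + model$p_stop == 0) {
    if (isTRUE(r > model$e_bg + 1e-9)) {
      warning("nonzero RT signature with p_mis + p_stop = 0: ",
              "stoichiometry unidentifiable", call. = FALSE)
      return(NA_real_)
    }
    return(0)
  }
  clip01((r - model$e_bg) / denom)
}

#' Per-tRNA m1A58 level table
#'
#' Applies [misincorporation_rate] and [estimate_stoichiometry] at each
#' tRNA's m1A58 site. Positions with coverage below `min_coverage` are
#' excluded from the table (flagged via message), never imputed.
#'
#' @param pileup pileup data.frame (may carry a `condition` column).
#' @param trnas list of [trna_species], or a named integer vector mapping
#'   tRNA id to 0-based m1A58 index.
#' @param model an [error_model].
#' @param condition condition label stored in the output; defaulted from the
#'   pileup's `condition` column when unique.
#' @param min_coverage minimum reads entering the site (default 100).
#' @return data.frame of class `m1a_level_table`: one row per quantified
#'   tRNA with `tRNA_id`, `condition`, `mismatch_rate`, `stop_rate`,
#'   `stoichiometry`, `coverage`.
#' @export
m1a_levels <- function(pileup, trnas, model = error_model(),
                       condition = NULL, min_coverage = 100L) {
  if (is.list(trnas) && all(vapply(trnas, inherits, logical(1),
                                   "trna_species"))) {
    pos58 <- stats::setNames(
      vapply(trnas, function(t) as.integer(t$pos58), integer(1)),
      vapply(trnas, `[[`, character(1), "id"))
  } else {
    pos58 <- trnas
    stopifnot(!is.null(names(pos58)))
  }
  if (is.null(condition)) {
    condition <- if ("condition" %in% names(pileup) &&
                     length(unique(pileup$condition)) == 1L) {
      unique(pileup$condition)
    } else NA_character_
  }
  ids <- intersect(unique(pileup$tRNA_id), names(pos58))
  rows <- lapply(sort(ids), function(id) {
    p <- pos58[[id]]
    if (is.na(p)) return(NULL)
    r <- misincorporation_rate(pileup, id, p, ref_base = "A")
    if (r$coverage < min_coverage) {
      message(sprintf("m1a_levels: %s excluded (coverage %d < %d)",
                      id, r$coverage, min_coverage))
      return(NULL)
    }
    data.frame(tRNA_id = id, condition = condition,
               mismatch_rate = r$mismatch_rate, stop_rate = r$stop_rate,
               stoichiometry = estimate_stoichiometry(
                 r$mismatch_rate, r$stop_rate, model),
               coverage = r$coverage, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(tRNA_id = character(0), condition = character(0),
                      mismatch_rate = numeric(0), stop_rate = numeric(0),
                      stoichiometry = numeric(0), coverage = integer(0))
  }
  class(out) <- c("m1a_level_table", "data.frame")
  out
}

#' Wild-type minus knockout m1A58 decrease per tRNA
#'
#' The per-tRNA decrease in m1A58 level after methyltransferase loss
#' (Delta = level_WT - level_KO), with a dense rank by decreasing Delta and
#' deterministic tie-breaking by tRNA id.
#'
#' @param wt,ko [m1a_levels] tables for the two conditions.
#' @param metric `"stoichiometry"` (default) or `"mismatch_rate"` — the
#'   model-free fallback.
#' @param trnas optional reference (list of [trna_species]) used to annotate
#'   decoded codons.
#' @return data.frame of class `delta_table` with `tRNA_id`,
#'   `decoded_codons`, `level_WT`, `level_KO`, `delta`, `rank`. tRNAs
#'   present in only one condition are dropped with a message.
#' @export
delta_m1a <- function(wt, ko, metric = c("stoichiometry", "mismatch_rate"),
                      trnas = NULL) {
  metric <- match.arg(metric)
  shared <- intersect(wt$tRNA_id, ko$tRNA_id)
  if (length(shared) == 0L) {
    stop("no tRNA shared between the two level tables", call. = FALSE)
  }
  only <- c(setdiff(wt$tRNA_id, shared), setdiff(ko$tRNA_id, shared))
  if (length(only) > 0L) {
    message("delta_m1a: dropped (single condition): ",
            paste(only, collapse = ", "))
  }
  lw <- wt[[metric]][match(shared, wt$tRNA_id)]
  lk <- ko[[metric]][match(shared, ko$tRNA_id)]
  codons <- rep(NA_character_, length(shared))
  if (!is.null(trnas)) {
    tab <- trna_reference_table(trnas)
    codons <- tab$decoded_codons[match(shared, tab$id)]
  }
  out <- data.frame(tRNA_id = shared, decoded_codons = codons,
                    level_WT = lw, level_KO = lk, delta = lw - lk,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$tRNA_id), , drop = FALSE]
  out$rank <- cumsum(!duplicated(out$delta))  # dense rank, decreasing delta
  rownames(out) <- NULL
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Most- and least-affected tRNAs
#'
#' @param delta a [delta_m1a] table.
#' @param k_top number of most-affected tRNAs (largest Delta).
#' @param k_bottom number of least-affected tRNAs (smallest Delta).
#' @return list with `most_affected` and `least_affected` character vectors
#'   of tRNA ids; disjoint, ties broken by tRNA id.
#' @export
rank_trnas <- function(delta, k_top, k_bottom = 0L) {
  stopifnot(k_top >= 0, k_bottom >= 0)
  if (k_top + k_bottom > nrow(delta)) {
    stop("k_top + k_bottom exceeds the number of ranked tRNAs",
         call. = FALSE)
  }
  ord_top <- order(-delta$delta, delta$tRNA_id)
  ord_bot <- order(delta$delta, delta$tRNA_id)
  list(
    most_affected = delta$tRNA_id[ord_top][seq_len(k_top)],
    least_affected = delta$tRNA_id[ord_bot][seq_len(k_bottom)]
  )
}
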