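#' Reverse-transcription error model for m1A sites
#'
#' m1A blocks Watson-Crick pairing, so a reverse transcriptase reading
#' through a methylated adenosine either terminates or writes a wrong base —
#' the sequencing-detectable signature used to quantify m1A58. The model is
#' deliberately minimal (mismatch + stop only, independent per-base
#' background error): enough to exercise the estimator without pretending to
#' reproduce any particular library protocol.
#'
#' @param p_mis probability that RT reading through an m1A writes a non-A
#'   base (split uniformly over the 3 alternatives). Default 0.5.
#' @param p_stop probability that RT terminates at an m1A. Default 0.2.
#' @param e_bg background per-base error rate applied at unmodified
#'   positions. Default 0.001.
#' @return object of class `error_model`.
#' @export
error_model <- function(p_mis = 0.5, p_stop = 0.2, e_bg = 0.001) {
  stopifnot(p_mis >= 0, p_mis <= 1, p_stop >= 0, p_stop <= 1,
            e_bg >= 0, e_bg <= 1)
  if (p_mis + p_stop > 1) {
    stop("p_mis + p_stop must be <= 1", call. = FALSE)
  }
  structure(list(p_mis = p_mis, p_stop = p_stop, e_bg = e_bg),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> p_mis=%g p_stop=%g e_bg=%g\n",
              x$p_mis, x$p_stop, x$e_bg))
  invisible(x)
}

# Three-letter amino-acid names, used to build human-readable tRNA ids.
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' Generate a synthetic tRNA reference set
#'
#' Builds one synthetic tRNA family per requested decoded codon. Each 76-nt
#' sequence carries its anticodon at the canonical anticodon positions and a
#' valid GUUCNANNC T-loop window whose fixed adenosine falls at 0-based index
#' 57 (canonical position 58); sequences are rejection-sampled so the first
#' motif match is that window. These are synthetic stand-ins, not genomic
#' tRNA genes: acceptor stems and other structural elements are not modelled.
#'
#' @param n_families number of tRNA families (1..61).
#' @param seed integer seed; output is reproducible for a fixed seed.
#' @param codons optional character vector of decoded DNA codons (length
#'   `n_families`, distinct sense codons). When `NULL`, codons are sampled
#'   from the 61 sense codons.
#' @param dir optional directory; when given, writes `reference.fasta` and
#'   `reference.tsv` there.
#' @return list of [trna_species] objects.
#' @examples
#' trnas <- generate_trna_reference(4, seed = 1,
#'                                  codons = c("TCC", "AGC", "CTG", "TTG"))
#' @export
generate_trna_reference <- function(n_families, seed, codons = NULL,
                                    dir = NULL) {
  stopifnot(n_families >= 1)
  if (n_families > 61) stop("n_families must be <= 61", call. = FALSE)
  gc <- genetic_code()
  with_seed(seed, {
    if (is.null(codons)) {
      codons <- sample(sense_codons(), n_families)
    }
    codons <- toupper(codons)
    stopifnot(length(codons) == n_families, !anyDuplicated(codons),
              all(codons %in% sense_codons()))
    trnas <- lapply(codons, function(cd) {
      aa <- unname(gc[[cd]])
      anticodon <- revcomp(cd)
      repeat {
        s <- sample(c("A", "C", "G", "T"), 76, replace = TRUE)
        s[34:36] <- strsplit(anticodon, "")[[1]]  # 1-based 34-36
        # T-loop window occupies 1-based 53..61; fixed A at 58.
        s[53:61] <- c("G", "T", "T", "C",
                      sample(c("A", "C", "G", "T"), 1), "A",
                      sample(c("A", "C", "G", "T"), 1),
                      sample(c("A", "C", "G", "T"), 1), "C")
        seq_str <- paste(s, collapse = "")
        if (identical(locate_position58(seq_str), 57L)) break
      }
      trna_species(id = paste0("tRNA-", AA3[[aa]], "-", cd),
                   anticodon = anticodon, amino_acid = aa,
                   sequence = seq_str, decoded_codons = cd, pos58 = 57L)
    })
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_trna_reference(trnas, file.path(dir, "reference.fasta"),
                           file.path(dir, "reference.tsv"))
    }
    trnas
  })
}

#' Simulate a tRNA-seq pileup for one tRNA
#'
#' Per-read generative process at the m1A58 site: with probability `s` the
#' site is modified, in which case RT terminates with `p_stop` or writes a
#' wrong base with `p_mis` (uniform over the 3 alternatives); with
#' probability `1 - s`, and at every other position, each base errs with
#' `e_bg`. Reads are full-length from the tRNA 3' end (RT directionality),
#' so every read enters the m1A58 column and a stop there removes coverage
#' from all positions 5' of it.
#'
#' @param trna a [trna_species] with a located `pos58`.
#' @param s m1A58 stoichiometry in `[0, 1]`.
#' @param n_reads number of reads (>= 1).
#' @param model an [error_model].
#' @param seed integer seed.
#' @return data.frame with columns `tRNA_id`, `position` (0-based),
#'   `ref_base`, `count_A`, `count_C`, `count_G`, `count_T`, `count_stop`.
#'   At the m1A58 row, base counts + stop count equal `n_reads`.
#' @export
simulate_pileup <- function(trna, s, n_reads, model = error_model(),
                            seed = 1L) {
  stopifnot(inherits(trna, "trna_species"), !is.na(trna$pos58),
            s >= 0, s <= 1, n_reads >= 1)
  bases <- c("A", "C", "G", "T")
  seq_chars <- strsplit(trna$sequence, "")[[1]]
  L <- length(seq_chars)
  pos58 <- trna$pos58  # 0-based
  with_seed(seed, {
    counts <- matrix(0L, nrow = L, ncol = 5L,
                     dimnames = list(NULL, c(bases, "stop")))
    for (i in seq_len(L)) {
      ref <- seq_chars[i]
      alt <- setdiff(bases, ref)
      if (i - 1L == pos58) {
        p_stop_eff <- s * model$p_stop
        p_mis_eff <- s * model$p_mis + (1 - s) * model$e_bg
        p <- stats::setNames(numeric(5), c(bases, "stop"))
        p[alt] <- p_mis_eff / 3
        p["stop"] <- p_stop_eff
        p[ref] <- 1 - p_stop_eff - p_mis_eff
        counts[i, ] <- as.integer(stats::rmultinom(1, n_reads, p))
      } else {
        # Coverage: reads run 3'->5'; a stop at pos58 truncates everything
        # 5' of it (indices < pos58). Stop counts are filled after pos58 is
        # drawn, so process positions 3'->5' like the RT does.
        counts[i, ] <- NA_integer_
      }
    }
    stops58 <- counts[pos58 + 1L, "stop"]
    for (i in seq_len(L)) {
      if (i - 1L == pos58) next
      cov <- if (i - 1L < pos58) n_reads - stops58 else n_reads
      ref <- seq_chars[i]
      alt <- setdiff(bases, ref)
      p <- stats::setNames(numeric(5), c(bases, "stop"))
      p[alt] <- model$e_bg / 3
      p[ref] <- 1 - model$e_bg
      counts[i, ] <- as.integer(stats::rmultinom(1, cov, p))
    }
    data.frame(
      tRNA_id = trna$id,
      position = 0:(L - 1L),
      ref_base = seq_chars,
      count_A = counts[, "A"], count_C = counts[, "C"],
      count_G = counts[, "G"], count_T = counts[, "T"],
      count_stop = counts[, "stop"],
      stringsAsFactors = FALSE
    )
  })
}

#' Define a simulation ground truth
#'
#' @param tRNA_id character vector of tRNA ids.
#' @param s_wt,s_ko per-tRNA m1A58 stoichiometries for the wild-type and
#'   knockout conditions. The knockout only removes methylation, so
#'   `s_ko <= s_wt` is enforced.
#' @param n_reads read depth per (tRNA, condition); recycled.
#' @return data.frame of class `simulation_truth` in long format with
#'   columns `tRNA_id`, `condition` (WT/KO), `s`, `n_reads`.
#' @export
simulation_truth <- function(tRNA_id, s_wt, s_ko, n_reads = 10000L) {
  stopifnot(length(tRNA_id) == length(s_wt), length(s_wt) == length(s_ko),
            all(s_wt >= 0 & s_wt <= 1), all(s_ko >= 0 & s_ko <= 1))
  if (any(s_ko > s_wt)) {
    stop("knockout stoichiometry must not exceed wild-type", call. = FALSE)
  }
  n_reads <- rep_len(as.integer(n_reads), length(tRNA_id))
  out <- rbind(
    data.frame(tRNA_id = tRNA_id, condition = "WT", s = s_wt,
               n_reads = n_reads, stringsAsFactors = FALSE),
    data.frame(tRNA_id = tRNA_id, condition = "KO", s = s_ko,
               n_reads = n_reads, stringsAsFactors = FALSE)
  )
  class(out) <- c("simulation_truth", "data.frame")
  out
}

#' Simulate a paired wild-type/knockout tRNA-seq experiment
#'
#' Generates one pileup per (tRNA, condition) from a stated ground truth and
#' optionally writes per-condition pileup TSVs plus a machine-readable truth
#' table. Fully reproducible from `seed`.
#'
#' @param trnas list of [trna_species]; must cover every id in `truth`.
#' @param truth a [simulation_truth] with both conditions for every tRNA.
#' @param model an [error_model].
#' @param seed integer master seed; per-(tRNA, condition) seeds are derived
#'   from it deterministically.
#' @param dir optional output directory for `pileup_WT.tsv`,
#'   `pileup_KO.tsv`, `truth.tsv`.
#' @return named list of pileup data.frames (`WT`, `KO`, rows stacked over
#'   tRNAs) plus the `truth` table.
#' @export
simulate_experiment <- function(trnas, truth, model = error_model(),
                                seed = 1L, dir = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  ids <- unique(truth$tRNA_id)
  for (cond in c("WT", "KO")) {
    missing <- setdiff(ids, truth$tRNA_id[truth$condition == cond])
    if (length(missing) > 0L) {
      stop(sprintf("missing %s condition for: %s", cond,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  by_id <- stats::setNames(trnas, vapply(trnas, `[[`, character(1), "id"))
  absent <- setdiff(ids, names(by_id))
  if (length(absent) > 0L) {
    stop(sprintf("truth references unknown tRNA id(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  piles <- list()
  for (cond in c("WT", "KO")) {
    rows <- truth[truth$condition == cond, , drop = FALSE]
    rows <- rows[order(rows$tRNA_id), , drop = FALSE]
    chunks <- lapply(seq_len(nrow(rows)), function(i) {
      child <- derive_seed(seed, match(rows$tRNA_id[i], sort(ids)) * 2L +
                             (cond == "KO"))
      simulate_pileup(by_id[[rows$tRNA_id[i]]], rows$s[i], rows$n_reads[i],
                      model, seed = child)
    })
    piles[[cond]] <- do.call(rbind, chunks)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(piles$WT, file.path(dir, "pileup_WT.tsv"))
    write_tsv(piles$KO, file.path(dir, "pileup_KO.tsv"))
    write_tsv(as.data.frame(truth), file.path(dir, "truth.tsv"))
  }
  c(piles, list(truth = truth))
}

#' Generate a random coding sequence with controlled codon usage
#'
#' Samples `n_codons` sense codons with probabilities proportional to
#' `codon_weights` and appends a TAA stop, yielding a CDS of
#' `3 * (n_codons + 1)` nt with no internal stop.
#'
#' @param codon_weights named nonnegative numeric vector over sense codons;
#'   codons absent from the vector get weight 0. At least one positive
#'   weight is required; stop-codon weights are an error.
#' @param n_codons number of sense codons (>= 1).
#' @param seed integer seed.
#' @param fasta optional path; when given the CDS is written as FASTA.
#' @param id sequence name used in the FASTA header.
#' @return the CDS as a character string.
#' @export
generate_cds <- function(codon_weights, n_codons, seed, fasta = NULL,
                         id = "synthetic_cds") {
  stopifnot(n_codons >= 1, is.numeric(codon_weights),
            !is.null(names(codon_weights)))
  if (any(codon_weights < 0)) stop("codon weights must be nonnegative")
  if (any(names(codon_weights) %in% stop_codons() & codon_weights > 0)) {
    stop("stop codons cannot carry positive weight", call. = FALSE)
  }
  keep <- names(codon_weights) %in% sense_codons() & codon_weights > 0
  w <- codon_weights[keep]
  if (length(w) == 0L || sum(w) <= 0) {
    stop("at least one positive sense-codon weight required", call. = FALSE)
  }
  cds <- with_seed(seed, {
    codons <- sample(names(w), n_codons, replace = TRUE, prob = w / sum(w))
    paste0(paste(codons, collapse = ""), "TAA")
  })
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(cds, id)), fasta)
  }
  cds
}

#' The demonstration ground truth
#'
#' The stated world used by the end-to-end demo and the acceptance tests:
#' 12 tRNA families in which the serine TCC/AGC and leucine CTG/TTG decoders
#' lose most of their m1A58 on knockout of the methyltransferase (wild-type
#' stoichiometries 0.90/0.85/0.80/0.75 dropping to 0.05), six bystander
#' families show graded intermediate decreases, and the serine TCG and
#' leucine CTT decoders are nearly untouched — the configuration under which
#' the codon-switch design must select TCG and CTT as replacements.
#'
#' @param n_reads read depth per (tRNA, condition).
#' @return list with `codons` (12 decoded codons) and a constructor
#'   `truth(trnas)` mapping a matching reference to a [simulation_truth].
#' @export
demo_truth <- function(n_reads = 10000L) {
  spec <- data.frame(
    codon = c("TCC", "AGC", "CTG", "TTG", "GCT", "AAG",
              "GAA", "GGC", "ATC", "GTG", "TCG", "CTT"),
    s_wt = c(0.90, 0.85, 0.80, 0.75, 0.80, 0.75,
             0.70, 0.65, 0.60, 0.55, 0.50, 0.50),
    s_ko = c(0.05, 0.05, 0.05, 0.05, 0.20, 0.25,
             0.30, 0.35, 0.40, 0.45, 0.46, 0.48),
    stringsAsFactors = FALSE
  )
  list(
    codons = spec$codon,
    spec = spec,
    truth = function(trnas) {
      tab <- trna_reference_table(trnas)
      idx <- match(spec$codon, tab$decoded_codons)
      stopifnot(!anyNA(idx))
      simulation_truth(tab$id[idx], spec$s_wt, spec$s_ko, n_reads)
    }
  )
}
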