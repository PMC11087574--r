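#' Pipeline configuration
#'
#' One flat configuration object drives the whole simulate -> quantify ->
#' rank -> profile -> switch -> verify pipeline. A single `seed` fans out to
#' per-stage seeds by a fixed derivation, so one knob reproduces everything.
#'
#' @param seed master integer seed.
#' @param n_reads read depth per (tRNA, condition).
#' @param p_mis,p_stop,e_bg RT error-model parameters (see [error_model]).
#' @param k_top,k_bottom sizes of the most-/least-affected tRNA sets.
#' @param m frequency-rank cutoff for the vulnerability report.
#' @param wobble_policy `"strict"` or `"crick"`.
#' @param n_codons length (in sense codons) of the generated demo CDS.
#' @param cds_weight_focal weight multiplier for the four focal codons
#'   (TCC, AGC, CTG, TTG) in the demo CDS; other reference codons get
#'   weight 1, emulating an mRNA that leans heavily on codons read by
#'   modification-sensitive tRNAs.
#' @param cds_fasta optional path to a user-supplied CDS FASTA analysed in
#'   place of the generated demo CDS.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_reads = 10000L, p_mis = 0.5,
                            p_stop = 0.2, e_bg = 0.001, k_top = 4L,
                            k_bottom = 2L, m = 10L,
                            wobble_policy = "strict", n_codons = 300L,
                            cds_weight_focal = 8, cds_fasta = "") {
  cfg <- list(seed = as.integer(seed), n_reads = as.integer(n_reads),
              p_mis = p_mis, p_stop = p_stop, e_bg = e_bg,
              k_top = as.integer(k_top), k_bottom = as.integer(k_bottom),
              m = as.integer(m), wobble_policy = wobble_policy,
              n_codons = as.integer(n_codons),
              cds_weight_focal = cds_weight_focal,
              cds_fasta = cds_fasta)
  stopifnot(cfg$wobble_policy %in% c("strict", "crick"))
  error_model(cfg$p_mis, cfg$p_stop, cfg$e_bg)  # validates
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save / load a pipeline configuration
#'
#' Flat `key = value` text, one pair per line; round-trips exactly
#' (`load(save(c)) = c`).
#'
#' @param config a [pipeline_config].
#' @param path file path.
#' @return the path (save) or the config (load).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k,
            if (is.character(v)) v else format(v, digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  vals <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, character(1), 2L))
  defaults <- pipeline_config()
  args <- lapply(names(defaults), function(k) {
    if (!k %in% names(vals)) return(defaults[[k]])
    v <- vals[[k]]
    if (is.character(defaults[[k]])) v
    else if (is.integer(defaults[[k]])) as.integer(v)
    else as.numeric(v)
  })
  names(args) <- names(defaults)
  do.call(pipeline_config, args)
}

#' Run the full codon-switch pipeline
#'
#' Executes, in order: synthetic reference + paired WT/KO tRNA-seq
#' simulation under the demonstration ground truth ([demo_truth]); per-tRNA
#' m1A58 quantification; WT-KO delta ranking; codon usage profiling of the
#' (generated or user-supplied) CDS with the vulnerability cross-reference;
#' codon-switch plan design; CDS recoding; and verification. Every stage
#' writes its table to `dir`, and a manifest records the configuration,
#' seed, package version and MD5 checksum of every output so that a rerun
#' with the same configuration is byte-identical.
#'
#' @param config a [pipeline_config].
#' @param dir output run directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  model <- error_model(config$p_mis, config$p_stop, config$e_bg)
  stage <- "simulate"
  res <- tryCatch({
    demo <- demo_truth(config$n_reads)
    trnas <- generate_trna_reference(length(demo$codons),
                                     seed = derive_seed(config$seed, 1L),
                                     codons = demo$codons, dir = dir)
    truth <- demo$truth(trnas)
    say(stage, "simulating %d tRNAs x 2 conditions at %d reads",
        length(trnas), config$n_reads)
    sim <- simulate_experiment(trnas, truth, model,
                               seed = derive_seed(config$seed, 2L),
                               dir = dir)

    stage <- "quantify"
    wt <- m1a_levels(sim$WT, trnas, model, condition = "WT")
    ko <- m1a_levels(sim$KO, trnas, model, condition = "KO")
    write_tsv(rbind(wt, ko), file.path(dir, "levels.tsv"))
    say(stage, "quantified %d WT and %d KO tRNAs", nrow(wt), nrow(ko))

    stage <- "delta"
    delta <- delta_m1a(wt, ko, trnas = trnas)
    write_tsv(delta, file.path(dir, "delta.tsv"))
    ranks <- rank_trnas(delta, config$k_top, config$k_bottom)
    write_tsv(data.frame(
      tRNA_id = c(ranks$most_affected, ranks$least_affected),
      set = c(rep("most_affected", length(ranks$most_affected)),
              rep("least_affected", length(ranks$least_affected)))),
      file.path(dir, "ranked.tsv"))

    stage <- "usage"
    if (nzchar(config$cds_fasta)) {
      seqs <- Biostrings::readDNAStringSet(config$cds_fasta)
      cds <- as.character(seqs[[1]])
      cds_id <- names(seqs)[1]
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(stats::setNames(cds, cds_id)),
        file.path(dir, "cds.fasta"))
    } else {
      focal <- c("TCC", "AGC", "CTG", "TTG")
      w <- stats::setNames(rep(1, length(demo$codons)), demo$codons)
      w[focal] <- config$cds_weight_focal
      cds_id <- "demo_cds"
      cds <- generate_cds(w, config$n_codons,
                          seed = derive_seed(config$seed, 3L),
                          fasta = file.path(dir, "cds.fasta"), id = cds_id)
    }
    usage <- codon_frequency(cds, id = cds_id)
    write_tsv(usage, file.path(dir, "usage.tsv"))
    map <- build_decoding_map(trnas, config$wobble_policy)
    vuln <- vulnerability_report(usage, delta, map, config$k_top, config$m)
    write_tsv(vuln, file.path(dir, "vulnerability.tsv"))
    say(stage, "%d codons profiled, %d flagged vulnerable",
        nrow(usage), sum(vuln$vulnerable))

    stage <- "plan"
    plan <- build_recoding_plan(delta, map, config$k_top)
    write_recoding_plan(plan, file.path(dir, "plan.tsv"))
    say(stage, "%d recoding rule(s)", nrow(plan))

    stage <- "switch"
    recoded <- recode_cds(cds, plan, id = paste0(cds_id, "_switch"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(recoded$sequence,
                                               recoded$id)),
      file.path(dir, "recoded.fasta"))
    write_tsv(recoded$log, file.path(dir, "substitutions.tsv"))
    say(stage, "%d substitution(s)", nrow(recoded$log))

    stage <- "verify"
    verification <- verify_recoding(cds, recoded, plan)
    jsonlite::write_json(verification, file.path(dir, "verification.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!verification$ok) {
      stop("recoding verification failed", call. = FALSE)
    }
    list(trnas = trnas, truth = truth, sim = sim, wt = wt, ko = ko,
         delta = delta, ranks = ranks, cds = cds, usage = usage,
         vulnerability = vuln, plan = plan, recoded = recoded,
         verification = verification)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  stage_files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- list(
    package = "trnaswitch",
    version = as.character(utils::packageVersion("trnaswitch")),
    seed = config$seed,
    config = unclass(config),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(dir, stage_files))), stage_files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
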