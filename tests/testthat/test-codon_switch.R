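# The worked example of the assay: serine TCC/AGC and leucine CTG/TTG are
# decoded by the most modification-sensitive tRNAs; TCG and CTT by the least.
focal_world <- function() {
  codons <- c(focal_codons, escape_codons, "GAA", "GGC")
  trnas <- make_reference(codons, seed = 23)
  ids <- vapply(trnas, `[[`, character(1), "id")
  delta <- make_delta(ids, c(0.85, 0.80, 0.75, 0.70, 0.02, 0.03, 0.4, 0.3),
                      codons = codons)
  list(trnas = trnas, ids = ids, delta = delta,
       map = build_decoding_map(trnas))
}

test_that("build_recoding_plan reproduces the serine/leucine switch", {
  w <- focal_world()
  plan <- build_recoding_plan(w$delta, w$map, k_top = 4)
  expect_identical(nrow(plan), 2L)
  ser <- plan[plan$amino_acid == "S", ]
  leu <- plan[plan$amino_acid == "L", ]
  expect_identical(ser$source_codons, "AGC;TCC")
  expect_identical(ser$replacement_codon, "TCG")
  expect_identical(leu$source_codons, "CTG;TTG")
  expect_identical(leu$replacement_codon, "CTT")

  # empty most-affected set => empty plan
  expect_identical(nrow(build_recoding_plan(w$delta, w$map, k_top = 0)), 0L)

  # no synonymous escape: lone Met decoder among the affected
  trnas2 <- make_reference(c("ATG", "TCG"), seed = 29)
  ids2 <- vapply(trnas2, `[[`, character(1), "id")
  d2 <- make_delta(ids2, c(0.8, 0.01), c("ATG", "TCG"))
  expect_warning(p2 <- build_recoding_plan(d2, build_decoding_map(trnas2),
                                           k_top = 1),
                 "no synonymous escape")
  expect_identical(nrow(p2), 0L)
})

test_that("plan construction matches a brute-force argmin oracle", {
  trnas <- full_reference()
  ids <- vapply(trnas, `[[`, character(1), "id")
  codons <- vapply(trnas, `[[`, character(1), "primary_codon")
  map <- build_decoding_map(trnas)
  gc <- genetic_code()
  with_seed(31, {
    for (rep_i in 1:25) {
      deltas <- round(stats::runif(61), 2)
      d <- make_delta(ids, deltas, codons)
      k <- sample(1:8, 1)
      # Met/Trp among the affected trigger a legitimate skip warning
      plan <- suppressWarnings(build_recoding_plan(d, map, k_top = k))
      # oracle: per amino acid, sources = codons of top-k tRNAs; replacement
      # = synonymous non-source codon with minimal decoder delta, ties by
      # codon order
      affected <- rank_trnas(d, k)$most_affected
      src_codons <- codons[ids %in% affected]
      delta_of <- setNames(deltas[match(map_ids <- ids, ids)], codons)
      for (aa in unique(gc[src_codons])) {
        src <- sort(src_codons[gc[src_codons] == aa])
        cand <- setdiff(synonymous_codons(aa), src)
        if (length(cand) == 0L) {
          expect_false(aa %in% plan$amino_acid)
          next
        }
        cand <- cand[order(delta_of[cand], cand)]
        row <- plan[plan$amino_acid == aa, ]
        expect_identical(row$source_codons, paste(src, collapse = ";"))
        expect_identical(row$replacement_codon, cand[[1]])
      }
    }
  })
})

test_that("recode_cds rewrites exactly the source codons", {
  w <- focal_world()
  plan <- build_recoding_plan(w$delta, w$map, k_top = 4)
  rec <- recode_cds("ATGTCCAGCTTGCTGTAA", plan)
  expect_identical(rec$sequence, "ATGTCGTCGCTTCTTTAA")
  expect_identical(nrow(rec$log), 4L)
  expect_identical(rec$log$position, c(3L, 6L, 9L, 12L))
  expect_identical(rec$log$from, c("TCC", "AGC", "TTG", "CTG"))

  # identity on CDS without source codons
  rec0 <- recode_cds("ATGGAAGGCTAA", plan)
  expect_identical(rec0$sequence, "ATGGAAGGCTAA")
  expect_identical(nrow(rec0$log), 0L)

  # internal stops are warned about and never rewritten
  expect_warning(reci <- recode_cds("TCCTAATCCTAA", plan), "internal stop")
  expect_identical(reci$sequence, "TCGTAATCGTAA")
})

test_that("recoding preserves the protein on random CDSs", {
  w <- focal_world()
  plan <- build_recoding_plan(w$delta, w$map, k_top = 4)
  for (seed in 1:5) {
    cds <- random_cds(2000, seed)
    rec <- suppressWarnings(recode_cds(cds, plan))
    expect_identical(oracle_translate(rec$sequence), oracle_translate(cds))
    # substitution count equals brute-force source-codon occurrences
    src <- unlist(strsplit(plan$source_codons, ";"))
    expect_identical(nrow(rec$log),
                     sum(split_codons(cds) %in% src))
    # completeness and idempotence
    expect_identical(sum(split_codons(rec$sequence) %in% src), 0L)
    rec2 <- suppressWarnings(recode_cds(rec$sequence, plan))
    expect_identical(rec2$sequence, rec$sequence)
  }
})

test_that("verify_recoding detects tampering and passes honest output", {
  w <- focal_world()
  plan <- build_recoding_plan(w$delta, w$map, k_top = 4)
  cds <- "ATGTCCAGCTTGCTGGAATAA"
  rec <- recode_cds(cds, plan)
  v <- verify_recoding(cds, rec, plan)
  expect_true(v$ok)
  expect_true(is.na(v$first_offending_position))

  # tamper one codon (synonymous but off-plan): log check must fail there
  bad <- rec
  substr(bad$sequence, 16, 18) <- "GAG"  # codon 6 (0-based nt 15), GAA->GAG
  vb <- verify_recoding(cds, bad, plan)
  expect_false(vb$ok)
  expect_false(vb$log_consistent)
  expect_identical(vb$first_offending_position, 15L)

  # non-synonymous tampering breaks protein identity
  bad2 <- rec
  substr(bad2$sequence, 1, 3) <- "CCC"
  v2 <- verify_recoding(cds, bad2, plan)
  expect_false(v2$protein_identical)

  # a residual source codon is caught
  v3 <- verify_recoding(cds, cds, plan)
  expect_false(v3$no_residual_source)
})

test_that("verify agrees with an independent diff-based checker", {
  w <- focal_world()
  plan <- build_recoding_plan(w$delta, w$map, k_top = 4)
  lookup <- setNames(rep(plan$replacement_codon,
                         lengths(strsplit(plan$source_codons, ";"))),
                     unlist(strsplit(plan$source_codons, ";")))
  oracle_check <- function(orig, rec_seq) {
    oc <- split_codons(orig); rc <- split_codons(rec_seq)
    if (length(oc) != length(rc)) return(FALSE)
    ok_prot <- identical(oracle_translate(orig), oracle_translate(rec_seq))
    ok_res <- !any(rc %in% names(lookup))
    diffs <- which(oc != rc)
    ok_diff <- all(oc[diffs] %in% names(lookup)) &&
      all(rc[diffs] == lookup[oc[diffs]])
    ok_prot && ok_res && ok_diff
  }
  with_seed(53, {
    for (i in 1:100) {
      cds <- random_cds(sample(20:60, 1), 700 + i)
      rec <- suppressWarnings(recode_cds(cds, plan))
      seq_out <- rec$sequence
      if (i %% 3 == 0) {  # tamper a random codon in a third of the cases
        j <- sample(seq_len(nchar(seq_out) / 3), 1)
        substr(seq_out, j * 3 - 2, j * 3) <- sample(sense_codons(), 1)
      }
      v <- suppressWarnings(verify_recoding(cds, seq_out, plan))
      expect_identical(v$ok, oracle_check(cds, seq_out))
    }
  })
})

test_that("plan validation and TSV round-trip", {
  expect_error(recoding_plan("S", "TCC", "TCC"), "source codon")
  expect_error(recoding_plan("S", "TCC", "CTG"), "encode S")
  expect_error(recoding_plan(c("S", "S"), c("TCC", "AGC"), c("TCG", "TCG")),
               "one rule per amino acid")
  plan <- recoding_plan(c("L", "S"), list(c("CTG", "TTG"), c("AGC", "TCC")),
                        c("CTT", "TCG"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recoding_plan(plan, path)
  expect_identical(read_recoding_plan(path)$replacement_codon,
                   plan$replacement_codon)
})
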