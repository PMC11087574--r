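test_that("misincorporation_rate reads a pileup column correctly", {
  pile <- data.frame(
    tRNA_id = "t1", position = c(10L, 11L), ref_base = c("A", "A"),
    count_A = c(1000L, 0L), count_C = c(0L, 400L), count_G = c(0L, 300L),
    count_T = c(0L, 300L), count_stop = c(0L, 0L),
    stringsAsFactors = FALSE)
  r <- misincorporation_rate(pile, "t1", 10L)
  expect_identical(r$mismatch_rate, 0)
  expect_identical(r$stop_rate, 0)
  expect_identical(r$coverage, 1000L)
  r2 <- misincorporation_rate(pile, "t1", 11L)
  expect_identical(r2$mismatch_rate, 1)

  # stops count toward reads entering, not base calls
  pile$count_stop[1] <- 1000L
  r3 <- misincorporation_rate(pile, "t1", 10L)
  expect_identical(r3$stop_rate, 0.5)
  expect_identical(r3$coverage, 2000L)
})

test_that("rates on simulated pileups match generative expectations", {
  trna <- make_reference("CTG")[[1]]
  s <- 0.8; model <- error_model(0.5, 0.2, 0.001); n <- 1e5
  pile <- simulate_pileup(trna, s, n, model, seed = 13)
  r <- misincorporation_rate(pile, trna$id, trna$pos58)
  e_stop <- s * model$p_stop
  e_mis <- (s * model$p_mis + (1 - s) * model$e_bg) / (1 - e_stop)
  expect_lt(abs(r$stop_rate - e_stop), 3 * sqrt(e_stop * (1 - e_stop) / n))
  n_base <- n * (1 - e_stop)
  expect_lt(abs(r$mismatch_rate - e_mis),
            3 * sqrt(e_mis * (1 - e_mis) / n_base))
})

test_that("estimate_stoichiometry inverts the model", {
  model <- error_model(0.5, 0.2, 0.001)
  exp_rates <- function(s) {
    stop_rate <- s * model$p_stop
    list(m = (s * model$p_mis + (1 - s) * model$e_bg) / (1 - stop_rate),
         t = stop_rate)
  }
  # boundary inversions are exact
  r1 <- exp_rates(1)
  expect_equal(estimate_stoichiometry(r1$m, r1$t, model), 1)
  r0 <- exp_rates(0)
  expect_equal(estimate_stoichiometry(r0$m, r0$t, model), 0)
  # interior values recovered exactly from exact rates
  for (s in c(0.25, 0.5, 0.9)) {
    r <- exp_rates(s)
    expect_equal(estimate_stoichiometry(r$m, r$t, model), s,
                 tolerance = 1e-12)
  }
  # unidentifiable flag
  expect_warning(
    out <- estimate_stoichiometry(0.3, 0, error_model(0, 0, 0.001)),
    "unidentifiable")
  expect_true(is.na(out))
})

test_that("stoichiometry recovery is unbiased and consistent", {
  trna <- make_reference("GAA")[[1]]
  model <- error_model()
  # scaled-down replicate study here (full 500-replicate run lives in the
  # acceptance suite)
  est <- vapply(1:60, function(i) {
    pile <- simulate_pileup(trna, 0.6, 1e4, model, seed = 1000 + i)
    lev <- m1a_levels(pile, list(trna), model)
    lev$stoichiometry
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6), 0.05)

  # error shrinks with depth
  err_at <- function(n) {
    e <- vapply(1:30, function(i) {
      pile <- simulate_pileup(trna, 0.6, n, model, seed = 5000 + i)
      abs(m1a_levels(pile, list(trna), model)$stoichiometry - 0.6)
    }, numeric(1))
    mean(e)
  }
  errs <- vapply(c(1e3, 1e4, 1e5), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("m1a_levels excludes low-coverage tRNAs", {
  trnas <- make_reference(c("TCC", "AGC"))
  p1 <- simulate_pileup(trnas[[1]], 0.5, 1000, seed = 1)
  p2 <- simulate_pileup(trnas[[2]], 0.5, 50, seed = 2)
  expect_message(
    lev <- m1a_levels(rbind(p1, p2), trnas, min_coverage = 100),
    "excluded")
  expect_identical(lev$tRNA_id, trnas[[1]]$id)
  expect_true(all(lev$coverage > 0))
  expect_true(all(lev$stoichiometry >= 0 & lev$stoichiometry <= 1))
})

test_that("delta_m1a computes WT-KO decreases with dense ranking", {
  mk_level <- function(ids, s) {
    out <- data.frame(tRNA_id = ids, condition = NA, mismatch_rate = s,
                      stop_rate = 0, stoichiometry = s,
                      coverage = 1000L, stringsAsFactors = FALSE)
    class(out) <- c("m1a_level_table", "data.frame")
    out
  }
  wt <- mk_level(c("a", "b", "c"), c(0.9, 0.5, 0.5))
  ko <- mk_level(c("a", "b", "c"), c(0.05, 0.5, 0.1))
  d <- delta_m1a(wt, ko)
  expect_equal(d$delta[d$tRNA_id == "a"], 0.85)
  expect_identical(d$tRNA_id, c("a", "c", "b"))
  expect_identical(d$rank, 1:3)
  expect_true(all(d$delta >= -1 & d$delta <= 1))

  # identity => all zero
  d0 <- delta_m1a(wt, wt)
  expect_true(all(d0$delta == 0))
  expect_true(all(d0$rank == 1L))  # dense rank with a single tie group

  # single-condition tRNAs are dropped with a message
  expect_message(d1 <- delta_m1a(wt, ko[1:2, ]), "dropped")
  expect_setequal(d1$tRNA_id, c("a", "b"))
  expect_error(delta_m1a(wt, mk_level("z", 0.5)), "no tRNA shared")
})

test_that("rank_trnas matches a brute-force sort with tie-breaks", {
  with_seed(99, {
    for (rep in 1:25) {
      n <- sample(3:12, 1)
      ids <- paste0("t", sample(LETTERS, n))
      deltas <- round(stats::runif(n, -0.2, 0.9), 2)  # rounding forces ties
      d <- make_delta(ids, deltas)
      k_top <- sample(0:n, 1)
      k_bot <- sample(0:(n - k_top), 1)
      r <- rank_trnas(d, k_top, k_bot)
      ord <- order(-deltas, ids)
      expect_identical(r$most_affected, ids[ord][seq_len(k_top)])
      expect_identical(r$least_affected,
                       ids[order(deltas, ids)][seq_len(k_bot)])
      expect_length(intersect(r$most_affected, r$least_affected), 0L)
    }
  })
  d <- make_delta(c("a", "b"), c(0.5, 0.1))
  expect_identical(rank_trnas(d, 0)$most_affected, character(0))
  expect_error(rank_trnas(d, 2, 1), "exceeds")
})

test_that("ranking recovery on a graded 12-tRNA simulation", {
  demo <- demo_truth(n_reads = 10000L)
  trnas <- make_reference(demo$codons, seed = 61)
  truth <- demo$truth(trnas)
  sim <- simulate_experiment(trnas, truth, seed = 71)
  model <- error_model()
  d <- delta_m1a(m1a_levels(sim$WT, trnas, model),
                 m1a_levels(sim$KO, trnas, model), trnas = trnas)
  true_delta <- with(truth, s[condition == "WT"] - s[condition == "KO"])
  names(true_delta) <- truth$tRNA_id[truth$condition == "WT"]
  est <- d$delta[match(names(true_delta), d$tRNA_id)]
  expect_gte(stats::cor(est, true_delta, method = "spearman"), 0.9)
  top4 <- rank_trnas(d, 4)$most_affected
  expect_setequal(top4, names(sort(true_delta, decreasing = TRUE))[1:4])
})
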