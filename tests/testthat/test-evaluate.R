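test_that("sample deviations convert to ms via the 450-sample geometry", {
  expect_equal(sample_deviation_to_ms(4, "ABR"), 4 * 15 / 450)
  expect_equal(round(sample_deviation_to_ms(4, "ABR"), 2), 0.13)
  expect_equal(sample_deviation_to_ms(4, "AMLR"), 4 * 150 / 450)
  expect_equal(round(sample_deviation_to_ms(4, "AMLR"), 2), 1.33)
  expect_identical(sample_deviation_to_ms(0, "ABR"), 0)
  expect_error(sample_deviation_to_ms(-1, "AMLR"))
})

shifted_pair <- function(n, shift) {
  gold <- lapply(seq_len(n), function(i) {
    make_annotation("ABR", c(I = 40 + i, III = 100 + i, V = 160 + i))
  })
  pred <- lapply(seq_len(n), function(i) {
    make_annotation("ABR", c(I = 40 + i + shift, III = 100 + i + shift,
                             V = 160 + i + shift))
  })
  list(pred = pred, gold = gold)
}

test_that("identical annotations score 100 percent everywhere", {
  pair <- shifted_pair(10, 0)
  rep <- compute_match_rates(pair$gold, pair$gold)
  expect_true(all(rep$match_rate[rep$n_evaluable > 0] == 100))
})

test_that("the 4-sample tolerance boundary is inclusive", {
  on_edge <- compute_match_rates(shifted_pair(10, 4)$pred,
                                 shifted_pair(10, 4)$gold)
  expect_true(all(on_edge$match_rate[on_edge$wave %in%
                                       c("I", "III", "V")] == 100))
  past_edge <- compute_match_rates(shifted_pair(10, 5)$pred,
                                   shifted_pair(10, 5)$gold)
  expect_true(all(past_edge$match_rate[past_edge$wave %in%
                                         c("I", "III", "V")] == 0))
})

test_that("match rates are monotone in the tolerance", {
  set.seed(41)
  gold <- lapply(1:30, function(i) {
    make_annotation("AMLR", c(Na = 60, Pa = 90, Nb = 125,
                              Pb = 180) + sample(0:3, 4, replace = TRUE))
  })
  pred <- lapply(1:30, function(i) {
    make_annotation("AMLR", c(Na = 60, Pa = 90, Nb = 125,
                              Pb = 180) + sample(-8:8, 4, replace = TRUE))
  })
  prev <- rep(0, 4)
  for (tol in 0:10) {
    cur <- compute_match_rates(pred, gold, tolerance = tol)$match_rate
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("gold NA leaves the denominator; predicted NA is a miss", {
  gold <- list(make_annotation("ABR", c(I = 45, V = 165)),      # no III
               make_annotation("ABR", c(I = 50, III = 105, V = 170)))
  pred <- list(make_annotation("ABR", c(I = 45, III = 99, V = 165)),
               make_annotation("ABR", c(I = 50, V = 170)))      # missed III
  rep <- compute_match_rates(pred, gold)
  expect_identical(rep$n_evaluable[rep$wave == "III"], 1L)  # one gold III
  expect_identical(rep$n_matched[rep$wave == "III"], 0L)    # predicted NA
  expect_identical(rep$match_rate[rep$wave == "I"], 100)
  # counting every recording as evaluable instead
  rep_all <- compute_match_rates(pred, gold, drop_gold_na = FALSE)
  expect_identical(rep_all$n_evaluable[rep_all$wave == "III"], 2L)
})

test_that("rates agree with a brute-force double-loop scorer", {
  set.seed(43)
  n <- 40
  gold <- list(); pred <- list()
  for (i in seq_len(n)) {
    g <- c(Na = 60L, Pa = 90L, Nb = 125L, Pb = 180L) +
      sample(0:4, 4, replace = TRUE)
    g[runif(4) < 0.2] <- NA                      # some unmarked gold waves
    p <- g + sample(-7:7, 4, replace = TRUE)
    p[runif(4) < 0.2] <- NA                      # some missed predictions
    gold[[i]] <- make_annotation("AMLR", g[!is.na(g)])
    pred[[i]] <- make_annotation("AMLR", p[!is.na(p)])
  }
  rep <- compute_match_rates(pred, gold, tolerance = 4)
  for (lbl in c("Na", "Pa", "Nb", "Pb")) {
    n_eval <- 0L; n_match <- 0L
    for (i in seq_len(n)) {
      gi <- gold[[i]]$waves[[lbl]]$index
      pi <- pred[[i]]$waves[[lbl]]$index
      if (is.na(gi)) next
      n_eval <- n_eval + 1L
      if (!is.na(pi) && abs(pi - gi) <= 4) n_match <- n_match + 1L
    }
    expect_identical(rep$n_evaluable[rep$wave == lbl], n_eval)
    expect_identical(rep$n_matched[rep$wave == lbl], n_match)
  }
})

test_that("rates are invariant to joint reordering of the pairs", {
  set.seed(44)
  pair <- shifted_pair(15, 2)
  perm <- sample(15)
  a <- compute_match_rates(pair$pred, pair$gold)
  b <- compute_match_rates(pair$pred[perm], pair$gold[perm])
  expect_equal(a$match_rate, b$match_rate)
})

test_that("unaligned prediction/gold lists are refused", {
  expect_error(
    compute_match_rates(list(make_annotation("ABR", c(I = 45))),
                        list(make_annotation("AMLR", c(Pa = 90)))),
    "not aligned"
  )
})
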