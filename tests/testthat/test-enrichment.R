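test_that("pKi labeling splits at the stated thresholds with an excluded band", {
  expect_equal(classify_by_pki(4.2), "nonbinder")
  expect_equal(classify_by_pki(6.5), "binder")
  expect_equal(classify_by_pki(5.5), "excluded")
  expect_equal(classify_by_pki(c(4.9, 5.0, 6.0, 6.01)),
               c("nonbinder", "excluded", "excluded", "binder"))
  expect_error(classify_by_pki(NaN), "finite")
  expect_error(classify_by_pki(5, lower = 7, upper = 6))
})

test_that("hit rate is binders over total", {
  t41 <- random_table(41, 14, seed = 1)
  expect_equal(hit_rate(t41), 14 / 41)       # 34% library
  t32 <- random_table(32, 5, seed = 2)
  expect_equal(hit_rate(t32), 5 / 32)        # ~16% after subsampling
  all_b <- screen_table(c("a", "b"), c(1, 2), c("binder", "binder"))
  expect_equal(hit_rate(all_b), 1)
  expect_error(hit_rate(t41[0, ]), "empty")
})

test_that("EF at 100% is exactly 1 for any table", {
  for (seed in 1:20) {
    tab <- random_table(sample(10:60, 1), sample(1:5, 1), seed = seed)
    expect_identical(ef_at(tab, 100)$ef, 1)
  }
})

test_that("perfect ranking of a 5/32 screen gives EF30 = 10/3", {
  tab <- screen_table(sprintf("L%02d", 1:32), 32:1,
                      rep(c("binder", "nonbinder"), c(5, 27)))
  res <- ef_at(tab, 30)
  expect_equal(res$n_selected, 10L)          # ceil(0.3 * 32)
  expect_equal(res$hits_in_selection, 5L)
  expect_equal(res$ef, 10 / 3)               # (5 / 9.6) / (5 / 32)
  expect_error(ef_at(screen_table("a", 1, "nonbinder"), 30), "no binders")
})

test_that("pure-tie EF averages to the random expectation over id orderings", {
  # all scores equal: the deterministic id tie-break decides the selection,
  # so averaging over random binder placements must recover chance level
  set.seed(99)
  efs <- replicate(1000, {
    lab <- rep("nonbinder", 32)
    lab[sample.int(32, 5)] <- "binder"
    ef_at(screen_table(sprintf("L%02d", 1:32), rep(0, 32), lab), 30)$ef
  })
  expect_lt(abs(mean(efs) - 1.0), 0.1)
})

test_that("EF is invariant to strictly monotone score transformations", {
  tab <- random_table(40, 6, seed = 5)
  for (xx in c(10, 25, 50)) {
    base <- ef_at(tab, xx)$ef
    t2 <- tab; t2$score <- exp(tab$score)
    t3 <- tab; t3$score <- 3 * tab$score - 7
    expect_equal(ef_at(t2, xx)$ef, base)
    expect_equal(ef_at(t3, xx)$ef, base)
  }
})

test_that("BEDROC matches the independent direct-formula oracle", {
  N <- 32; n <- 5; alpha <- 20
  perfect <- screen_table(sprintf("L%02d", 1:N), N:1,
                          rep(c("binder", "nonbinder"), c(n, N - n)))
  worst <- screen_table(sprintf("L%02d", 1:N), N:1,
                        rep(c("nonbinder", "binder"), c(N - n, n)))
  expect_equal(bedroc(perfect, alpha), oracle_bedroc(1:n, N, alpha),
               tolerance = 1e-10)
  expect_equal(bedroc(worst, alpha), oracle_bedroc((N - n + 1):N, N, alpha),
               tolerance = 1e-10)
  expect_gt(bedroc(perfect, alpha), 0.95)
  expect_lt(bedroc(worst, alpha), 0.01)
  # a single active at rank 1 of 2 saturates the score
  tiny <- screen_table(c("a", "b"), c(2, 1), c("binder", "nonbinder"))
  expect_equal(bedroc(tiny, 20), 1, tolerance = 1e-3)
  expect_error(bedroc(worst[worst$label == "nonbinder", ], 20), "no binders")
})

test_that("BEDROC never increases when an active is swapped down in rank", {
  set.seed(17)
  for (case in 1:500) {
    N <- sample(10:40, 1)
    n <- sample(1:5, 1)
    lab <- rep("nonbinder", N)
    lab[sample.int(N, n)] <- "binder"
    tab <- screen_table(sprintf("L%03d", 1:N), N:1, lab)
    b0 <- bedroc(tab, 20)
    # swap a random active with the next-lower-ranked inactive
    act <- which(tab$label == "binder")
    cand <- act[vapply(act, function(i)
      i < N && tab$label[i + 1] == "nonbinder", logical(1))]
    if (length(cand) == 0) next
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    tab$label[c(i, i + 1)] <- tab$label[c(i + 1, i)]
    expect_lte(bedroc(tab, 20), b0 + 1e-12)
  }
})

test_that("random rankings average to chance for EF30 and BEDROC(20)", {
  N <- 32; n <- 5
  lab <- rep(c("binder", "nonbinder"), c(n, N - n))
  set.seed(123)
  vals <- t(replicate(2000, {
    tab <- screen_table(sprintf("L%02d", 1:N), runif(N), lab)
    c(ef_at(tab, 30)$ef, bedroc(tab, 20))
  }))
  expect_lt(abs(mean(vals[, 1]) - 1.0), 0.1)
  # E[RIE] = 1 under uniform ranking, so the BEDROC expectation is analytic
  ra <- n / N; a <- 20
  b_exp <- ra * sinh(a / 2) / (cosh(a / 2) - cosh(a / 2 - a * ra)) +
    1 / (1 - exp(a * (1 - ra)))
  expect_lt(abs(mean(vals[, 2]) - b_exp), 0.02)
})

test_that("binder subsampling keeps all non-binders and is seed-stable", {
  tab <- random_table(41, 14, seed = 3)
  r1 <- subsample_enrichment(tab, k = 5, n_repeats = 25, xx_list = c(20, 30),
                             alpha_list = 20, seed = 7)
  r2 <- subsample_enrichment(tab, k = 5, n_repeats = 25, xx_list = c(20, 30),
                             alpha_list = 20, seed = 7)
  expect_identical(r1, r2)
  r3 <- subsample_enrichment(tab, k = 5, n_repeats = 25, xx_list = c(20, 30),
                             alpha_list = 20, seed = 8)
  expect_false(identical(r1$mean, r3$mean))
  expect_equal(r1$metric, c("EF", "EF", "BEDROC"))
  expect_true(all(r1$lo <= r1$median & r1$median <= r1$hi))
})

test_that("perfectly separated scores give EF30 = 10/3 in every subsample", {
  # binders all above non-binders: whichever 5 binders are drawn, the
  # 32-row subsample is perfectly ranked, so EF30 is the analytic 10/3
  tab <- screen_table(sprintf("L%02d", 1:41),
                      c(100 + rnorm(14), rnorm(27)),
                      rep(c("binder", "nonbinder"), c(14, 27)))
  r <- subsample_enrichment(tab, k = 5, n_repeats = 50, xx_list = 30,
                            alpha_list = 20, seed = 1)
  expect_equal(r$mean[1], 10 / 3)
  expect_equal(r$lo[1], 10 / 3)
  expect_equal(r$hi[1], 10 / 3)
})

test_that("subsampling allows k above the number of distinct binders", {
  tab <- random_table(30, 3, seed = 4)
  r <- subsample_enrichment(tab, k = 5, n_repeats = 10, xx_list = 30,
                            alpha_list = 20, seed = 1)
  expect_true(all(is.finite(r$mean)))
  expect_error(subsample_enrichment(tab, k = 0, n_repeats = 5), ">= 1")
})

test_that("score tables load from label and pKi text formats", {
  lab_file <- withr::local_tempfile(lines = c(
    "ligand_id,score,label", "a,1.5,binder", "b,0.5,nonbinder"
  ))
  tab <- read_screen_table(lab_file)
  expect_equal(tab$label, c("binder", "nonbinder"))
  pki_file <- withr::local_tempfile(lines = c(
    "ligand_id,score,pki", "a,1.5,6.8", "b,0.9,5.5", "c,0.5,4.1"
  ))
  tab2 <- read_screen_table(pki_file)
  expect_equal(tab2$ligand_id, c("a", "c"))  # ambiguous band dropped
  expect_equal(tab2$label, c("binder", "nonbinder"))
})
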