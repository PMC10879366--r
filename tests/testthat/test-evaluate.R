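# Small synthetic sample tables used throughout: one row per
# (patient, timepoint, score).
make_samples <- function(t1, t2, t3 = NULL, t4 = NULL, score_name = "PE") {
  n <- length(t1)
  tp <- list(T1 = t1, T2 = t2, T3 = t3, T4 = t4)
  purrr::imap_dfr(tp[!vapply(tp, is.null, logical(1))], function(v, nm) {
    tibble::tibble(patient_id = sprintf("P%02d", seq_len(n)), timepoint = nm,
                   target_time_s = NA_real_,
                   responsive = nm %in% c("T1", "T4"),
                   score_name = score_name, score = v)
  })
}

test_that("timepoint sampling hits the nearest block and labels states", {
  scores <- tibble::tibble(time_s = 30:500, PE = (30:500) / 100,
                           STE_MEAN = (30:500) / 200)
  events <- tibble::tibble(patient_id = "A", lor_s = 100, ror_s = 400)
  s <- sample_timepoints(scores, events)
  expect_equal(nrow(s), 8)  # 4 timepoints x 2 scores
  got <- dplyr::filter(s, score_name == "PE")
  expect_equal(got$target_time_s, c(85, 130, 385, 430))
  expect_equal(got$score, c(85, 130, 385, 430) / 100)  # exact grid match
  expect_equal(got$responsive, c(TRUE, FALSE, FALSE, TRUE))
  # target outside coverage names the timepoint
  bad <- tibble::tibble(patient_id = "A", lor_s = 100, ror_s = 490)
  expect_error(sample_timepoints(scores, bad), "T4")
})

test_that("threshold selection maximizes LoR accuracy with the stated tie rule", {
  s <- make_samples(t1 = c(0.8, 0.9), t2 = c(0.1, 0.2))
  expect_equal(select_threshold(s), 0.5)
  expect_equal(accuracy(dplyr::filter(s, timepoint %in% c("T1", "T2")), 0.5), 1)
  # identical score multisets: no threshold beats chance
  s2 <- make_samples(t1 = c(0.3, 0.6), t2 = c(0.3, 0.6))
  th2 <- select_threshold(s2)
  expect_equal(accuracy(s2, th2), 0.5)
  # ties at the threshold count as negative (strict >)
  s3 <- make_samples(t1 = 0.5, t2 = 0.5)
  expect_equal(accuracy(s3, 0.5), 0.5)
  expect_error(select_threshold(make_samples(numeric(0), numeric(0))), "empty")
})

test_that("the selected threshold is optimal against an exhaustive scan", {
  set.seed(83)
  for (i in 1:20) {
    s <- make_samples(t1 = round(rnorm(20, 1), 2), t2 = round(rnorm(20, 0.4), 2))
    th <- select_threshold(s)
    expect_equal(accuracy(s, th), oracle_best_accuracy(s))
  }
})

test_that("accuracy implements the confusion-matrix formula", {
  # t_p = 3, f_n = 1 among responsive; t_n = 4, f_p = 2 among unresponsive
  s <- tibble::tibble(responsive = c(rep(TRUE, 4), rep(FALSE, 6)),
                      score = c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1))
  expect_equal(accuracy(s, 0.5), 0.7)
  expect_equal(accuracy(make_samples(t1 = c(1, 1), t2 = c(0, 0)), 0.5), 1)
  expect_equal(accuracy(make_samples(t1 = c(0, 0), t2 = c(1, 1)), 0.5), 0)
})

test_that("contrasts pool the stated timepoints under one threshold", {
  s <- make_samples(t1 = c(1, 1, 1), t2 = c(0, 0, 0),
                    t3 = c(0, 0, 1), t4 = c(1, 1, 0))
  th <- select_threshold(s)
  lor <- evaluate_contrast(s, th, "LoR")
  ror <- evaluate_contrast(s, th, "RoR")
  comb <- evaluate_contrast(s, th, "combined")
  expect_equal(lor$accuracy, 1)
  expect_equal(ror$accuracy, 4 / 6)
  # combined = pooled corrects over 4 * n samples
  expect_equal(comb$accuracy, (6 + 4) / 12)
  expect_error(evaluate_contrast(dplyr::filter(s, timepoint != "T3"), th, "RoR"),
               "missing timepoint")
})

test_that("patient bootstrap is seeded, degenerate on identical patients, and calibrated", {
  s <- make_samples(t1 = rep(1, 6), t2 = rep(0, 6), t3 = rep(0, 6), t4 = rep(1, 6))
  ci <- bootstrap_ci(s, 0.5, "combined", B = 200, seed = 4)
  expect_equal(unname(ci), c(1, 1))  # identical patients -> zero width
  set.seed(91)
  s2 <- make_samples(t1 = rnorm(12, 0.8, 0.3), t2 = rnorm(12, 0.2, 0.3))
  ci_a <- bootstrap_ci(s2, 0.5, "LoR", B = 500, seed = 7)
  ci_b <- bootstrap_ci(s2, 0.5, "LoR", B = 500, seed = 7)
  expect_identical(ci_a, ci_b)
  expect_true(ci_a[["ci_low"]] <= accuracy(s2, 0.5) &&
                accuracy(s2, 0.5) <= ci_a[["ci_high"]])
  expect_error(bootstrap_ci(s2, 0.5, "LoR", B = 0), "B must be")
})

test_that("bootstrap CI width matches the binomial approximation for Bernoulli patients", {
  # 50 patients, both LoR timepoints jointly correct with probability 0.7
  set.seed(97)
  correct <- rbinom(50, 1, 0.7)
  s <- make_samples(t1 = as.numeric(correct),          # responsive: 1 iff correct
                    t2 = as.numeric(1 - correct))      # unresponsive: 0 iff correct
  ci <- bootstrap_ci(s, 0.5, "LoR", B = 10000, seed = 13)
  p_hat <- mean(correct)
  width_binom <- 2 * 1.96 * sqrt(p_hat * (1 - p_hat) / 50)
  width_boot <- ci[["ci_high"]] - ci[["ci_low"]]
  expect_lt(abs(width_boot - width_binom), 0.2 * width_binom)
})

test_that("paired accuracy differences behave as designed", {
  s_pe <- make_samples(t1 = c(1, 1, 1, 1), t2 = c(0, 0, 0, 0), score_name = "PE")
  s_a <- make_samples(t1 = c(1, 1, 1, 1), t2 = c(0, 0, 0, 0), score_name = "A")
  both <- dplyr::bind_rows(s_pe, s_a)
  thr <- c(PE = 0.5, A = 0.5)
  d <- accuracy_difference(both, "A", "PE", thr, "LoR", B = 300, seed = 3)
  expect_equal(d$difference, 0)
  expect_equal(c(d$ci_low, d$ci_high), c(0, 0))  # identical scores -> zero width
  # A perfect, B always wrong -> difference 1
  s_bad <- make_samples(t1 = c(0, 0, 0, 0), t2 = c(1, 1, 1, 1), score_name = "B")
  d2 <- accuracy_difference(dplyr::bind_rows(s_a, s_bad), "A", "B",
                            c(A = 0.5, B = 0.5), "LoR", B = 300, seed = 3)
  expect_equal(d2$difference, 1)
  # mismatched patient sets are rejected
  s_short <- dplyr::filter(s_pe, patient_id != "P01")
  expect_error(accuracy_difference(dplyr::bind_rows(s_a, s_short), "A", "PE",
                                   thr, "LoR", B = 50, seed = 1), "patient sets")
})

test_that("pairing narrows the difference CI when scores are correlated", {
  set.seed(101)
  n <- 24
  latent <- rnorm(n, 0, 0.6)
  t1a <- 1 + latent + rnorm(n, 0, 0.2); t2a <- latent + rnorm(n, 0, 0.2)
  t1b <- 1 + latent + rnorm(n, 0, 0.2); t2b <- latent + rnorm(n, 0, 0.2)
  both <- dplyr::bind_rows(make_samples(t1a, t2a, score_name = "A"),
                           make_samples(t1b, t2b, score_name = "B"))
  thr <- c(A = 0.5, B = 0.5)
  d <- accuracy_difference(both, "A", "B", thr, "LoR", B = 4000, seed = 5)
  paired_width <- d$ci_high - d$ci_low
  ci_a <- bootstrap_ci(dplyr::filter(both, score_name == "A"), 0.5, "LoR",
                       B = 4000, seed = 6)
  ci_b <- bootstrap_ci(dplyr::filter(both, score_name == "B"), 0.5, "LoR",
                       B = 4000, seed = 7)
  unpaired_width <- sqrt((ci_a[["ci_high"]] - ci_a[["ci_low"]])^2 +
                           (ci_b[["ci_high"]] - ci_b[["ci_low"]])^2)
  expect_lt(paired_width, unpaired_width)
})

test_that("label permutation drives expected accuracy to chance", {
  set.seed(103)
  accs <- replicate(200, {
    s <- make_samples(t1 = rnorm(10, 1), t2 = rnorm(10, 0))
    s$responsive <- sample(s$responsive)
    accuracy(s, 0.5)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("the full evaluation object is tidy-able and plottable", {
  set.seed(107)
  both <- dplyr::bind_rows(
    make_samples(rnorm(10, 3), rnorm(10, 1), rnorm(10, 1), rnorm(10, 3),
                 score_name = "PE"),
    make_samples(rnorm(10, 2), rnorm(10, 1), rnorm(10, 1), rnorm(10, 2),
                 score_name = "STE_MEAN"))
  fit <- evaluate_responsiveness(both, B = 400, seed = 9)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)  # 2 scores x 3 contrasts
  expect_true(all(td$ci_low <= td$accuracy & td$accuracy <= td$ci_high))
  expect_true(all(td$accuracy >= 0 & td$accuracy <= 1))
  gl <- glance(fit)
  expect_equal(gl$n_patients, 10)
  expect_equal(nrow(fit$differences), 3)  # STE_MEAN vs PE per contrast
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
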