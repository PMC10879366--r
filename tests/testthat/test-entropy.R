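test_that("shannon_entropy matches hand-computed values", {
  expect_equal(shannon_entropy(10), 0)
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2)
  expect_equal(shannon_entropy(c(3, 1)),
               -0.75 * log2(0.75) - 0.25 * log2(0.25), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(3, 1)), 0.8113, tolerance = 1e-4)
  expect_error(shannon_entropy(c(0, 0)), "all-zero")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("permutation entropy attains its analytic limits", {
  expect_equal(permutation_entropy(rep(7L, 100)), 0)
  expect_equal(permutation_entropy(rep(0:119, 50)), log2(120), tolerance = 1e-12)
  expect_equal(permutation_entropy(encode_patterns(1:300)), 0)  # monotone signal
  expect_error(permutation_entropy(integer(0)), "empty")
  expect_error(permutation_entropy(c(0L, 120L)), "codes must lie")
})

test_that("uniform-code windows show the expected plug-in bias", {
  # Miller-Madow: E[H] ~ log2(K) - (K-1)/(2 N ln 2) for iid uniform symbols
  K <- 120; N <- 5996
  bias <- (K - 1) / (2 * N * log(2))
  set.seed(31)
  deficit <- replicate(120, log2(K) - permutation_entropy(sample(0:119, N, TRUE)))
  expect_lt(abs(mean(deficit) - bias), 0.25 * bias)
})

test_that("transfer entropy matches the brute-force tabulation oracle", {
  x <- c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  y <- c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L)
  expect_equal(transfer_entropy(x, y, 1), oracle_te(x, y, 1), tolerance = 1e-12)
  set.seed(41)
  for (delta in c(1, 3)) {
    a <- sample(0:3, 120, TRUE)
    b <- sample(0:3, 120, TRUE)
    expect_equal(transfer_entropy(a, b, delta), oracle_te(a, b, delta),
                 tolerance = 1e-12)
  }
  expect_error(transfer_entropy(1:5, 1:4, 1), "aligned")
  expect_error(transfer_entropy(1:5, 1:5, 5), "smaller than")
})

test_that("transfer entropy attains its analytic limits", {
  expect_equal(transfer_entropy(rep(2L, 50), rep(5L, 50), 3), 0)
  # perfect copy on a cyclic sequence covering every symbol pair once:
  # H(Y'|Y) = log2 K exactly, H(Y'|X,Y) = 0, so TE = log2 K
  db <- debruijn4()
  pairs <- paste(db, c(db[-1], db[1]))
  expect_equal(sort(pairs), sort(paste(rep(0:3, each = 4), rep(0:3, 4))))
  x <- c(db, db[1])
  y <- c(db[length(db)], db)
  expect_equal(transfer_entropy(x, y, 1), 2, tolerance = 1e-12)
})

test_that("plug-in transfer entropy is non-negative on random blocks", {
  set.seed(53)
  for (i in 1:1000) {
    n <- sample(60:200, 1)
    K <- sample(c(2, 6, 120), 1)
    te <- transfer_entropy(sample(seq_len(K) - 1L, n, TRUE),
                           sample(seq_len(K) - 1L, n, TRUE),
                           sample(1:5, 1))
    expect_gte(te, 0)
  }
})

test_that("independent sequences give a symmetric TE null and shuffling destroys coupling", {
  set.seed(67)
  fwd <- bwd <- numeric(60)
  for (i in seq_len(60)) {
    a <- sample(0:5, 400, TRUE)
    b <- sample(0:5, 400, TRUE)
    fwd[i] <- transfer_entropy(a, b, 2)
    bwd[i] <- transfer_entropy(b, a, 2)
  }
  # exchanging the roles of X and Y leaves the null distribution unchanged
  expect_lt(abs(mean(fwd) - mean(bwd)), 3 * sd(fwd - bwd) / sqrt(60))
  # coupled pair: y copies x with delay 2; shuffling the target removes it
  x <- sample(0:5, 2000, TRUE)
  y <- c(sample(0:5, 2), x[seq_len(1998)])
  te_coupled <- transfer_entropy(x, y, 2)
  set.seed(68)
  te_shuffled <- transfer_entropy(x, sample(y), 2)
  expect_gt(te_coupled, 2)  # near log2(6)
  expect_lt(te_shuffled, te_coupled / 5)
  # the shuffled estimate sits at the independent-case plug-in bias level,
  # which scales as 1/N (null estimates used N = 398 tuples, this one 1998)
  expect_lt(te_shuffled, 3 * mean(fwd) * 398 / 1998 + 0.02)
})

test_that("block scores aggregate exactly 48 STE estimates as defined", {
  set.seed(71)
  cm <- matrix(sample(0:119, 4000 * 4, TRUE), ncol = 4,
               dimnames = list(NULL, c("Fp1", "Fp2", "P3", "P4")))
  storage.mode(cm) <- "integer"
  bs <- block_scores(cm)
  expect_equal(dim(bs$ste), c(8, 6))
  expect_equal(length(bs$ste), 48)
  expect_equal(bs$scores[["STE_FP"]], mean(bs$ste[1:4, ]), tolerance = 1e-12)
  expect_equal(bs$scores[["STE_PF"]], mean(bs$ste[5:8, ]), tolerance = 1e-12)
  expect_equal(bs$scores[["STE_UND"]],
               bs$scores[["STE_FP"]] + bs$scores[["STE_PF"]], tolerance = 1e-12)
  expect_equal(bs$scores[["STE_MEAN"]], bs$scores[["STE_UND"]] / 2,
               tolerance = 1e-12)
  # kernel agrees with the reference R implementation pair by pair
  expect_equal(bs$ste["Fp2->P4", "d9"],
               transfer_entropy(cm[, "Fp2"], cm[, "P4"], 9), tolerance = 1e-12)
  expect_equal(bs$ste["P3->Fp1", "d12"],
               transfer_entropy(cm[, "P3"], cm[, "Fp1"], 12), tolerance = 1e-12)
  # degenerate block: identical constant channels
  const <- matrix(3L, 500, 4, dimnames = list(NULL, c("Fp1", "Fp2", "P3", "P4")))
  bc <- block_scores(const)
  expect_true(all(bc$scores == 0))
  # missing channel is named
  expect_error(block_scores(cm[, 1:3]), "P4")
})

test_that("score_recording produces the 1 s grid and recovers the designed contrasts", {
  res <- small_recording(seed = 11)
  scores <- score_recording(preprocess_recording(res$recording))
  # 220 s recording, first window excluded by startup settling
  expect_equal(scores$time_s, seq(31, 220, by = 1))
  expect_true(all(scores$PE >= 0 & scores$PE <= log2(120)))
  expect_true(all(scores$STE_FP >= 0 & scores$STE_PF >= 0))
  expect_equal(scores$STE_UND, scores$STE_FP + scores$STE_PF, tolerance = 1e-12)
  ev <- res$events
  awake <- scores[scores$time_s <= ev$lor_s - 15, ]
  anesth <- scores[scores$time_s >= ev$lor_s + 30 & scores$time_s <= ev$ror_s - 30, ]
  expect_gt(median(awake$PE), median(anesth$PE))
  expect_gt(median(awake$STE_MEAN), median(anesth$STE_MEAN))
  expect_gt(median(awake$STE_FP), median(awake$STE_PF))
  # wrong rate is rejected
  expect_error(score_recording(res$recording), "200 Hz")
})
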