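#' Sample entropy scores at the four responsiveness time points
#'
#' Extracts each score at T1 = LoR - 15 s, T2 = LoR + 30 s, T3 = RoR - 15 s
#' and T4 = RoR + 30 s. T1 is the latest block containing no anesthetized
#' EEG (the 30 s window ending at LoR - 15 s lies entirely before LoR), and
#' T2 the earliest containing no awake EEG; T3/T4 mirror this around RoR.
#' T1 and T4 are labelled responsive, T2 and T3 unresponsive. The block
#' whose timestamp is nearest each target time is used and must lie within
#' 0.5 s of it.
#'
#' @param scores Score tibble (`time_s` plus score columns) for one patient,
#'   or a cohort-level tibble with a `patient_id` column.
#' @param events Tibble with `patient_id`, `lor_s`, `ror_s`.
#' @return Long tibble: `patient_id`, `timepoint` (T1..T4), `target_time_s`,
#'   `responsive`, `score_name`, `score`.
#' @export
sample_timepoints <- function(scores, events) {
  if (!"patient_id" %in% names(scores)) {
    if (nrow(events) != 1) {
      stop("scores lack a patient_id column but events has multiple rows",
           call. = FALSE)
    }
    scores <- dplyr::bind_cols(patient_id = events$patient_id[1], scores)
  }
  score_names <- setdiff(names(scores), c("patient_id", "time_s"))
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    s <- dplyr::filter(scores, .data$patient_id == ev$patient_id)
    if (nrow(s) == 0) {
      stop(sprintf("no scores found for patient %s", ev$patient_id), call. = FALSE)
    }
    targets <- c(T1 = ev$lor_s - 15, T2 = ev$lor_s + 30,
                 T3 = ev$ror_s - 15, T4 = ev$ror_s + 30)
    purrr::map_dfr(names(targets), function(tp) {
      tt <- targets[[tp]]
      j <- which.min(abs(s$time_s - tt))
      if (abs(s$time_s[j] - tt) > 0.5) {
        stop(sprintf("patient %s: no block within 0.5 s of %s (%.1f s)",
                     ev$patient_id, tp, tt), call. = FALSE)
      }
      tibble::tibble(patient_id = ev$patient_id,
                     timepoint = tp,
                     target_time_s = tt,
                     responsive = tp %in% c("T1", "T4"),
                     score_name = score_names,
                     score = unname(unlist(s[j, score_names])))
    })
  })
}

contrast_timepoints <- function(contrast) {
  switch(contrast,
         LoR = c("T1", "T2"),
         RoR = c("T3", "T4"),
         combined = c("T1", "T2", "T3", "T4"),
         stop(sprintf("unknown contrast '%s'", contrast), call. = FALSE))
}

one_score <- function(samples) {
  sn <- unique(samples$score_name)
  if (length(sn) != 1) {
    stop("expected samples for exactly one score; filter by score_name first",
         call. = FALSE)
  }
  sn
}

#' Classification accuracy at a threshold
#'
#' A sample is called "positive for wakefulness" when its score strictly
#' exceeds the threshold; accuracy is
#' `(t_p + t_n) / (t_p + f_p + t_n + f_n)`, the fraction of samples whose
#' responsiveness state is classified correctly.
#'
#' @param samples Time-point sample tibble (see [sample_timepoints()]) for
#'   one score.
#' @param threshold Decision threshold in score units (bits).
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(samples, threshold) {
  if (nrow(samples) == 0) stop("empty sample set", call. = FALSE)
  mean((samples$score > threshold) == samples$responsive)
}

#' Accuracy-maximizing threshold from the LoR contrast
#'
#' Scans candidate thresholds — midpoints between consecutive distinct
#' pooled T1/T2 scores, plus one candidate below the minimum and one above
#' the maximum — and returns the one maximizing LoR accuracy; ties go to the
#' smallest candidate. This threshold is then reused for all contrasts.
#'
#' @param samples Time-point samples for one score; only T1 and T2 rows are
#'   used.
#' @return The selected threshold (bits).
#' @export
select_threshold <- function(samples) {
  if (nrow(samples) == 0) stop("empty sample set", call. = FALSE)
  one_score(samples)
  s <- dplyr::filter(samples, .data$timepoint %in% c("T1", "T2"))
  if (nrow(s) == 0) stop("empty sample set: need T1/T2 samples", call. = FALSE)
  v <- sort(unique(s$score))
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2,
            v[length(v)] + 1)
  acc <- vapply(cand, function(th) accuracy(s, th), numeric(1))
  cand[which.max(acc)]  # which.max returns the first, i.e. smallest, maximizer
}

#' Thresholds for every score in a sample tibble
#'
#' @param samples Time-point samples (all scores).
#' @return Tibble: `score_name`, `threshold`, `accuracy_lor`.
#' @export
select_thresholds <- function(samples) {
  samples |>
    dplyr::group_by(.data$score_name) |>
    dplyr::group_modify(function(d, g) {
      th <- select_threshold(dplyr::bind_cols(d, score_name = g$score_name))
      tibble::tibble(
        threshold = th,
        accuracy_lor = accuracy(dplyr::filter(d, .data$timepoint %in% c("T1", "T2")), th))
    }) |>
    dplyr::ungroup()
}

#' Accuracy of one contrast at a fixed threshold
#'
#' @param samples Time-point samples for one score.
#' @param threshold Fixed decision threshold (normally the LoR-derived one).
#' @param contrast `"LoR"` (T1 vs T2), `"RoR"` (T3 vs T4) or `"combined"`
#'   (all four time points pooled).
#' @return One-row tibble: `contrast`, `score_name`, `threshold`,
#'   `accuracy`, `n_patients`.
#' @export
evaluate_contrast <- function(samples, threshold, contrast) {
  sn <- one_score(samples)
  tps <- contrast_timepoints(contrast)
  s <- dplyr::filter(samples, .data$timepoint %in% tps)
  if (!setequal(unique(s$timepoint), tps)) {
    stop(sprintf("missing timepoint(s) for contrast %s", contrast), call. = FALSE)
  }
  tibble::tibble(contrast = contrast, score_name = sn, threshold = threshold,
                 accuracy = accuracy(s, threshold),
                 n_patients = dplyr::n_distinct(s$patient_id))
}

# Per-patient number of correctly classified timepoints for a contrast;
# the resampling unit of every bootstrap here is the patient.
patient_correct_counts <- function(samples, threshold, contrast) {
  tps <- contrast_timepoints(contrast)
  s <- dplyr::filter(samples, .data$timepoint %in% tps)
  s$correct <- (s$score > threshold) == s$responsive
  agg <- s |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_correct = sum(.data$correct), n = dplyr::n(),
                     .groups = "drop")
  if (length(unique(agg$n)) != 1) {
    stop("patients contribute unequal numbers of timepoints", call. = FALSE)
  }
  agg
}

#' Patient-level bootstrap confidence interval for an accuracy
#'
#' Resamples patients (with all their time points) with replacement `B`
#' times, recomputes the accuracy of the contrast with the *fixed* threshold
#' on each replicate, and returns the percentile interval. The threshold is
#' not re-selected inside replicates.
#'
#' @param samples Time-point samples for one score.
#' @param threshold Fixed decision threshold.
#' @param contrast See [evaluate_contrast()].
#' @param B Number of bootstrap replicates. Default 10000.
#' @param level Confidence level. Default 0.95.
#' @param seed Integer seed making the interval reproducible.
#' @return Named numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(samples, threshold, contrast, B = 10000L,
                         level = 0.95, seed = 1L) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  one_score(samples)
  agg <- patient_correct_counts(samples, threshold, contrast)
  n_pat <- nrow(agg)
  if (n_pat < 2) stop("need at least two patients to bootstrap", call. = FALSE)
  k <- agg$n[1]
  acc_rep <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(n_pat, n_pat * B, replace = TRUE), nrow = B)
    rowSums(matrix(agg$n_correct[idx], nrow = B)) / (n_pat * k)
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(acc_rep, c(alpha, 1 - alpha), names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Paired bootstrap comparison of two scores' accuracies
#'
#' Point difference `accuracy(A) - accuracy(B)` for a contrast, with a
#' paired percentile bootstrap: each replicate resamples patients once and
#' recomputes both accuracies on the same resample, so between-patient
#' variability common to the two scores cancels.
#'
#' @param samples Time-point samples containing both scores.
#' @param score_a,score_b Score names to compare (A minus B).
#' @param thresholds Named numeric of fixed thresholds, one per score.
#' @param contrast See [evaluate_contrast()].
#' @param B,level,seed As in [bootstrap_ci()].
#' @return One-row tibble: `contrast`, `comparison`, `difference`, `ci_low`,
#'   `ci_high`.
#' @export
accuracy_difference <- function(samples, score_a, score_b, thresholds,
                                contrast, B = 10000L, level = 0.95,
                                seed = 1L) {
  sa <- dplyr::filter(samples, .data$score_name == score_a)
  sb <- dplyr::filter(samples, .data$score_name == score_b)
  agg_a <- patient_correct_counts(sa, thresholds[[score_a]], contrast)
  agg_b <- patient_correct_counts(sb, thresholds[[score_b]], contrast)
  if (!identical(sort(agg_a$patient_id), sort(agg_b$patient_id))) {
    stop("patient sets differ between the two scores", call. = FALSE)
  }
  agg_b <- agg_b[match(agg_a$patient_id, agg_b$patient_id), ]
  n_pat <- nrow(agg_a)
  k <- agg_a$n[1]
  point <- (sum(agg_a$n_correct) - sum(agg_b$n_correct)) / (n_pat * k)
  diff_rep <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(n_pat, n_pat * B, replace = TRUE), nrow = B)
    (rowSums(matrix(agg_a$n_correct[idx], nrow = B)) -
       rowSums(matrix(agg_b$n_correct[idx], nrow = B))) / (n_pat * k)
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(diff_rep, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(contrast = contrast,
                 comparison = paste(score_a, "-", score_b),
                 difference = point, ci_low = q[1], ci_high = q[2])
}

#' Full responsiveness-classification analysis
#'
#' Runs the complete statistical pipeline on time-point samples: selects the
#' LoR-accuracy-maximizing threshold per score, evaluates the LoR, RoR and
#' combined contrasts with that single threshold, attaches patient-level
#' percentile bootstrap confidence intervals, and computes paired accuracy
#' differences of every other score against the reference score.
#'
#' @param samples Time-point samples from [sample_timepoints()].
#' @param B Bootstrap replicates. Default 10000.
#' @param level Confidence level. Default 0.95.
#' @param seed Integer seed for all resampling.
#' @param reference Score the differences are taken against. Default `"PE"`.
#' @return A `responsiveness_eval` object; see [tidy.responsiveness_eval()],
#'   [glance.responsiveness_eval()] and [autoplot.responsiveness_eval()].
#' @export
evaluate_responsiveness <- function(samples, B = 10000L, level = 0.95,
                                    seed = 1L, reference = "PE") {
  thr_tbl <- select_thresholds(samples)
  thresholds <- purrr::set_names(thr_tbl$threshold, thr_tbl$score_name)
  score_names <- names(thresholds)
  contrasts <- c("LoR", "RoR", "combined")
  results <- purrr::map_dfr(score_names, function(sn) {
    s <- dplyr::filter(samples, .data$score_name == sn)
    purrr::map_dfr(contrasts, function(ct) {
      res <- evaluate_contrast(s, thresholds[[sn]], ct)
      ci <- bootstrap_ci(s, thresholds[[sn]], ct, B = B, level = level, seed = seed)
      dplyr::bind_cols(res, tibble::tibble(ci_low = ci[["ci_low"]],
                                           ci_high = ci[["ci_high"]]))
    })
  })
  differences <- NULL
  if (reference %in% score_names && length(score_names) > 1) {
    differences <- purrr::map_dfr(setdiff(score_names, reference), function(sn) {
      purrr::map_dfr(contrasts, function(ct) {
        accuracy_difference(samples, sn, reference, thresholds, ct,
                            B = B, level = level, seed = seed)
      })
    })
  }
  structure(
    list(samples = samples, thresholds = thresholds, results = results,
         differences = differences, B = as.integer(B), level = level,
         seed = as.integer(seed), reference = reference,
         n_patients = dplyr::n_distinct(samples$patient_id)),
    class = "responsiveness_eval"
  )
}

#' @export
print.responsiveness_eval <- function(x, ...) {
  cat(sprintf("<responsiveness_eval> %d patients, %d-fold bootstrap, %.0f%% CI\n",
              x$n_patients, x$B, 100 * x$level))
  print(x$results, n = nrow(x$results))
  if (!is.null(x$differences)) {
    cat(sprintf("Paired accuracy differences vs %s:\n", x$reference))
    print(x$differences, n = nrow(x$differences))
  }
  invisible(x)
}

#' Tidy the per-contrast accuracy table of a responsiveness analysis
#'
#' @param x A `responsiveness_eval` object.
#' @param ... Unused.
#' @return Tibble: `contrast`, `score_name`, `threshold`, `accuracy`,
#'   `n_patients`, `ci_low`, `ci_high`.
#' @export
tidy.responsiveness_eval <- function(x, ...) {
  x$results
}

#' One-row summary of a responsiveness analysis
#'
#' @param x A `responsiveness_eval` object.
#' @param ... Unused.
#' @return One-row tibble with the cohort size, bootstrap settings, and the
#'   best score/accuracy for the LoR contrast.
#' @export
glance.responsiveness_eval <- function(x, ...) {
  lor <- dplyr::filter(x$results, .data$contrast == "LoR")
  best <- lor[which.max(lor$accuracy), ]
  tibble::tibble(n_patients = x$n_patients, n_scores = length(x$thresholds),
                 B = x$B, level = x$level,
                 best_lor_score = best$score_name,
                 best_lor_accuracy = best$accuracy)
}
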