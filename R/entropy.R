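#' Entropy scoring configuration
#'
#' Defaults follow the monitoring setup this package implements: transfer
#' delays 7..12 pattern steps on the 200 Hz grid (35..60 ms), the four
#' fronto-parietal source-target pairs plus their four reverses (48 transfer
#' entropy estimates per data block), frontal permutation entropy averaged
#' over Fp1 and Fp2, and all scores in bits (base-2 logarithms).
#'
#' @param delays Integer transfer delays in pattern steps. Default `7:12`.
#' @param fp_pairs List of `c(source, target)` fronto-parietal pairs.
#' @param pe_channels Channels averaged for the permutation-entropy score.
#' @return An `entropy_config` list; `pf_pairs` are the reversed `fp_pairs`.
#' @export
entropy_config <- function(delays = 7:12,
                           fp_pairs = list(c("Fp1", "P3"), c("Fp1", "P4"),
                                           c("Fp2", "P3"), c("Fp2", "P4")),
                           pe_channels = c("Fp1", "Fp2")) {
  delays <- as.integer(delays)
  if (any(delays < 1L)) stop("transfer delays must be positive", call. = FALSE)
  structure(
    list(delays = delays,
         fp_pairs = fp_pairs,
         pf_pairs = lapply(fp_pairs, rev),
         pe_channels = pe_channels),
    class = "entropy_config"
  )
}

#' Shannon entropy of a count vector
#'
#' @param counts Non-negative counts; at least one must be positive.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("all-zero counts: entropy undefined", call. = FALSE)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Entropy (bits) of the empirical distribution of a key vector.
ent_keys <- function(k) {
  cnt <- tabulate(match(k, k), nbins = length(k))
  cnt <- cnt[cnt > 0L]
  n <- length(k)
  p <- cnt / n
  -sum(p * log2(p))
}

#' Permutation entropy of a code window
#'
#' Plug-in Shannon entropy of the empirical ordinal-pattern distribution
#' within one window; 0 bits when a single pattern dominates entirely, up to
#' `log2(factorial(m))` bits (about 6.91 for m = 5) for a uniform pattern
#' distribution.
#'
#' @param codes Integer pattern codes in `[0, factorial(m) - 1]`.
#' @param m Embedding dimension the codes were produced with. Default 5.
#' @return Entropy in bits.
#' @export
permutation_entropy <- function(codes, m = 5L) {
  if (length(codes) == 0) stop("empty code window", call. = FALSE)
  K <- factorial(m)
  if (any(codes < 0 | codes >= K)) {
    stop(sprintf("codes must lie in [0, %d] for m = %d", K - 1, m), call. = FALSE)
  }
  shannon_entropy(tabulate(codes + 1L, nbins = K))
}

#' Plug-in transfer entropy between two symbol sequences
#'
#' Estimates `T(X -> Y) = H(Y_t, Y_{t+delta}) - H(Y_t) -
#' H(X_t, Y_t, Y_{t+delta}) + H(X_t, Y_t)` by counting relative frequencies.
#' All four entropies are marginals of the single empirical distribution of
#' triples `(X_t, Y_t, Y_{t+delta})` over the common index range
#' `t = 1 .. n - delta`, which makes the estimate a conditional mutual
#' information of one distribution and therefore non-negative by
#' construction.
#'
#' @param x,y Aligned integer sequences (source, target) of equal length.
#' @param delta Transfer delay in sequence steps; must be `< length(y)`.
#' @return Transfer entropy in bits.
#' @export
transfer_entropy <- function(x, y, delta) {
  n <- length(x)
  if (length(y) != n) stop("x and y must be aligned (equal length)", call. = FALSE)
  delta <- as.integer(delta)
  if (delta >= n) stop("delta must be smaller than the sequence length", call. = FALSE)
  if (delta < 1L) stop("delta must be >= 1", call. = FALSE)
  rng <- seq_len(n - delta)
  B <- max(x, y) + 1
  xk <- as.double(x[rng]); yk <- as.double(y[rng]); yf <- as.double(y[rng + delta])
  h_y <- ent_keys(yk)
  h_yy <- ent_keys(yk * B + yf)
  h_xy <- ent_keys(xk * B + yk)
  h_xyy <- ent_keys((xk * B + yk) * B + yf)
  max(h_yy - h_y - h_xyy + h_xy, 0)
}

# All pairwise symbolic transfer entropies of one block: 8 ordered pairs x
# length(delays) transfer delays. Delegates to the compiled kernel, which
# shares the per-target marginal entropies within each delay; falls back to
# transfer_entropy() for alphabets too large for the counting buffer.
block_ste_matrix <- function(code_mat, cfg) {
  pairs <- c(cfg$fp_pairs, cfg$pf_pairs)
  pair_names <- vapply(pairs, function(p) paste0(p[1], "->", p[2]), character(1))
  chans <- colnames(code_mat)
  alphabet <- max(code_mat) + 1L
  src <- match(vapply(pairs, `[`, character(1), 1), chans) - 1L
  tgt <- match(vapply(pairs, `[`, character(1), 2), chans) - 1L
  if (alphabet <= 256L) {
    ste <- ste_matrix_cpp(code_mat, as.integer(cfg$delays), src, tgt, alphabet)
  } else {
    ste <- matrix(NA_real_, length(pairs), length(cfg$delays))
    for (pi in seq_along(pairs)) {
      for (di in seq_along(cfg$delays)) {
        ste[pi, di] <- transfer_entropy(code_mat[, src[pi] + 1L],
                                        code_mat[, tgt[pi] + 1L],
                                        cfg$delays[di])
      }
    }
  }
  dimnames(ste) <- list(pair_names, paste0("d", cfg$delays))
  ste
}

#' Entropy scores of one data block
#'
#' Computes the full set of 48 symbolic transfer entropy estimates (8
#' directed channel pairs x 6 transfer delays) and the frontal permutation
#' entropy, then aggregates: `STE_FP` is the mean of the 24 fronto-parietal
#' estimates, `STE_PF` the mean of the 24 parieto-frontal ones, `STE_UND`
#' their sum (undirected total information transfer), `STE_MEAN` the mean of
#' all 48 (so `STE_MEAN = STE_UND / 2`), and `PE` the mean permutation
#' entropy of the frontal channels.
#'
#' @param block One element of [segment_blocks()]'s `codes` column (integer
#'   matrix, patterns x channels), or a one-row slice of that tibble.
#' @param cfg An [entropy_config()].
#' @param m Embedding dimension used for the codes.
#' @return A list: `scores` (named numeric: PE, STE_FP, STE_PF, STE_UND,
#'   STE_MEAN) and `ste` (the 8 x 6 matrix of individual estimates).
#' @export
block_scores <- function(block, cfg = entropy_config(), m = 5L) {
  code_mat <- if (is.matrix(block)) block else block$codes[[1]]
  need <- unique(c(unlist(cfg$fp_pairs), cfg$pe_channels))
  missing <- setdiff(need, colnames(code_mat))
  if (length(missing) > 0) {
    stop(sprintf("block is missing channel(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ste <- block_ste_matrix(code_mat, cfg)
  fp_idx <- seq_along(cfg$fp_pairs)
  ste_fp <- mean(ste[fp_idx, ])
  ste_pf <- mean(ste[-fp_idx, ])
  pe <- mean(vapply(cfg$pe_channels,
                    function(ch) permutation_entropy(code_mat[, ch], m = m),
                    numeric(1)))
  list(
    scores = c(PE = pe, STE_FP = ste_fp, STE_PF = ste_pf,
               STE_UND = ste_fp + ste_pf, STE_MEAN = mean(ste)),
    ste = ste
  )
}

#' Score a preprocessed recording on the 1 s block grid
#'
#' Encodes every channel into ordinal patterns, cuts the sequences into
#' 30 s / 1 s-shift data blocks, and computes all entropy scores per block.
#'
#' @param rec Preprocessed recording tibble at 200 Hz containing Fp1, Fp2,
#'   P3 and P4 (see [preprocess_recording()]).
#' @param cfg An [entropy_config()].
#' @param m,tau Ordinal embedding dimension and lag.
#' @param window_s,shift_s Sliding-window length and shift in seconds.
#' @return Tibble with `time_s` (block timestamps) and columns `PE`,
#'   `STE_FP`, `STE_PF`, `STE_UND`, `STE_MEAN` in bits.
#' @export
score_recording <- function(rec, cfg = entropy_config(), m = 5L, tau = 1L,
                            window_s = 30, shift_s = 1) {
  fs <- infer_fs(rec$time_s)
  if (abs(fs - 200) > 1e-6 * 200) {
    stop(sprintf("score_recording expects the 200 Hz analysis rate, got %.6g Hz", fs),
         call. = FALSE)
  }
  require_channels(rec)
  codes <- encode_recording(rec, m = m, tau = tau)
  blocks <- segment_blocks(codes, window_s = window_s, shift_s = shift_s)
  rows <- purrr::map(blocks$codes, function(cm) block_scores(cm, cfg, m = m)$scores)
  tibble::tibble(time_s = blocks$timestamp_s,
                 !!!purrr::set_names(
                   lapply(names(rows[[1]]), function(nm)
                     vapply(rows, `[[`, numeric(1), nm)),
                   names(rows[[1]])))
}

#' Score every recording of a synthetic cohort
#'
#' Convenience wrapper: preprocesses (250 to 200 Hz) and scores each
#' recording of a [generate_cohort()] tibble.
#'
#' @param cohort Cohort tibble with `patient_id` and `recording` columns.
#' @param cfg An [entropy_config()].
#' @param spec Filter from [design_lowpass_fir()].
#' @return Long tibble: `patient_id`, `time_s`, and one column per score.
#' @export
score_cohort <- function(cohort, cfg = entropy_config(),
                         spec = design_lowpass_fir()) {
  purrr::map2_dfr(cohort$patient_id, cohort$recording, function(pid, rec) {
    dplyr::bind_cols(patient_id = pid,
                     score_recording(preprocess_recording(rec, spec), cfg))
  })
}
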