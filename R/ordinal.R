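#' Ordinal-pattern encoding of a signal
#'
#' Maps each length-`m` delay vector `(x[i], x[i+tau], ..., x[i+(m-1)tau])`
#' to the lexicographic rank (0-based) of the permutation of time indices
#' that sorts it ascending. Ties are broken by temporal order: the earlier
#' sample ranks lower, so the encoding is deterministic on any input. Codes
#' depend only on the order of the values, never their amplitude, which
#' makes them invariant under any strictly increasing transform of the
#' signal.
#'
#' @param x Numeric vector; length at least `(m - 1) * tau + 1`.
#' @param m Embedding dimension, 2..7. Default 5 (120 possible patterns).
#' @param tau Time lag in samples. Default 1.
#' @return Integer vector of `length(x) - (m - 1) * tau` codes in
#'   `[0, factorial(m) - 1]`.
#' @export
encode_patterns <- function(x, m = 5L, tau = 1L) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 2L || m > 7L) stop("embedding dimension m must be in 2..7", call. = FALSE)
  if (tau < 1L) stop("time lag tau must be >= 1", call. = FALSE)
  min_len <- (m - 1L) * tau + 1L
  if (length(x) < min_len) {
    stop(sprintf("input too short: need at least %d samples for m=%d, tau=%d",
                 min_len, m, tau), call. = FALSE)
  }
  npat <- length(x) - (m - 1L) * tau
  # rank of each of the m delayed values within its window, earlier index
  # winning ties; 25 vectorized comparisons for m = 5
  cols <- lapply(seq_len(m) - 1L, function(j) x[seq_len(npat) + j * tau])
  key <- integer(npat)
  pw <- 1L
  for (j in seq_len(m)) {
    rho <- integer(npat)
    for (k in seq_len(m)) {
      if (k < j) {
        rho <- rho + (cols[[k]] <= cols[[j]])
      } else if (k > j) {
        rho <- rho + (cols[[k]] < cols[[j]])
      }
    }
    key <- key + rho * pw
    pw <- pw * m
  }
  unname(perm_rank_table(m)[key + 1L])
}

# All permutations of 1:m in lexicographic order (rows).
lex_permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- lex_permutations(m - 1L)
  out <- matrix(0L, nrow(sub) * m, m)
  row <- 1L
  for (first in seq_len(m)) {
    rest <- setdiff(seq_len(m), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Lookup from the base-m digit key of the within-window rank vector to the
# lexicographic rank of the ascending-sort permutation; cached per m.
perm_rank_env <- new.env(parent = emptyenv())
perm_rank_table <- function(m) {
  key <- as.character(m)
  if (!is.null(perm_rank_env[[key]])) return(perm_rank_env[[key]])
  perms <- lex_permutations(m)
  tab <- rep(NA_integer_, m^m)
  pw <- m^(seq_len(m) - 1L)
  for (r in seq_len(nrow(perms))) {
    pi_r <- perms[r, ]          # pi_r[q] = time index of q-th smallest value
    rho <- integer(m)
    rho[pi_r] <- seq_len(m)     # rank of each time index
    tab[sum((rho - 1L) * pw) + 1L] <- r - 1L
  }
  perm_rank_env[[key]] <- tab
  tab
}

#' Encode every channel of a recording into ordinal patterns
#'
#' @param rec Recording tibble (`time_s`, optional `settled`, channels),
#'   typically from [preprocess_recording()].
#' @param m,tau Embedding dimension and lag, see [encode_patterns()].
#' @return Tibble with `time_s` (time of each pattern's rightmost underlying
#'   sample), `settled` (TRUE when all underlying samples are settled) and
#'   one integer code column per channel.
#' @export
encode_recording <- function(rec, m = 5L, tau = 1L) {
  chans <- channel_columns(rec)
  codes <- lapply(rec[chans], encode_patterns, m = m, tau = tau)
  npat <- length(codes[[1]])
  span <- (m - 1L) * tau
  settled <- if ("settled" %in% names(rec)) {
    rec$settled[seq_len(npat)]  # leftmost underlying sample (settling is monotone)
  } else {
    rep(TRUE, npat)
  }
  out <- tibble::tibble(time_s = rec$time_s[seq_len(npat) + span],
                        settled = settled, !!!codes)
  attr(out, "m") <- m
  attr(out, "tau") <- tau
  out
}

#' Cut aligned pattern sequences into sliding-window data blocks
#'
#' Windows span `window_s` seconds of underlying EEG samples and advance by
#' `shift_s`; a pattern belongs to a block when all of its underlying
#' samples fall inside the window, so a 30 s window of 6000 samples at
#' 200 Hz yields `6000 - (m - 1) * tau` patterns per channel. Each block is
#' timestamped at the right edge of its window — the first instant at which
#' its rightmost underlying EEG sample is complete, one sample period after
#' that sample's nominal time. Blocks whose window starts before the
#' signal has settled (see [preprocess_recording()]) are excluded.
#'
#' @param codes Aligned code tibble from [encode_recording()].
#' @param window_s Window length in seconds. Default 30.
#' @param shift_s Window shift in seconds. Default 1.
#' @return Tibble with `timestamp_s` and a `codes` list-column; each element
#'   is an integer matrix (patterns x channels).
#' @export
segment_blocks <- function(codes, window_s = 30, shift_s = 1) {
  chans <- channel_columns(codes)
  if (length(chans) == 0) stop("no code columns found", call. = FALSE)
  fs <- infer_fs(codes$time_s)
  m <- attr(codes, "m") %||% 5L
  tau <- attr(codes, "tau") %||% 1L
  span <- (m - 1L) * tau
  wlen <- round(window_s * fs)
  hop <- round(shift_s * fs)
  npat <- nrow(codes)
  n_samples <- npat + span
  if (n_samples < wlen) stop("recording shorter than one window", call. = FALSE)
  code_mat <- as.matrix(codes[chans])
  storage.mode(code_mat) <- "integer"
  t0 <- codes$time_s[1] - span / fs  # time of the first EEG sample
  settled <- codes$settled %||% rep(TRUE, npat)

  n_blocks <- (n_samples - wlen) %/% hop + 1L
  ks <- seq_len(n_blocks)
  first_pat <- (ks - 1L) * hop + 1L            # leftmost fully-contained pattern
  last_pat <- (ks - 1L) * hop + wlen - span
  keep <- settled[first_pat]                   # window must start on settled signal
  first_pat <- first_pat[keep]; last_pat <- last_pat[keep]; ks <- ks[keep]
  tibble::tibble(
    timestamp_s = t0 + ((ks - 1L) * hop + wlen) / fs,
    codes = purrr::map2(first_pat, last_pat,
                        function(a, b) code_mat[a:b, , drop = FALSE])
  )
}
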