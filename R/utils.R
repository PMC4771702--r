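`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
weighted_mean <- function(x, w) sum(w * x) / sum(w)

#' @keywords internal
weighted_cov <- function(x, y, w) {
  wn <- w / sum(w)
  sum(wn * x * y) - sum(wn * x) * sum(wn * y)
}

#' Integrated autocorrelation time by the initial-positive-sequence rule
#' @keywords internal
tau_int <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  lag_max <- min(n %/% 4, 400L)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  first_neg <- which(ac <= 0)[1]
  if (!is.na(first_neg)) ac <- ac[seq_len(first_neg - 1L)]
  1 + 2 * sum(ac)
}

#' Batch-means standard error of the mean of a (possibly correlated) series
#' @keywords internal
batch_se <- function(x, n_batches = 25L) {
  n <- length(x)
  if (n < 2 * n_batches) n_batches <- max(2L, n %/% 2L)
  bs <- floor(n / n_batches)
  m <- vapply(seq_len(n_batches), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
              numeric(1))
  stats::sd(m) / sqrt(n_batches)
}

#' FNV-1a hash of a character scalar, as 8 hex digits
#' @keywords internal
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h a double to stay within 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 2^8 + 147,
    # split so every intermediate stays below 2^53
    h <- ((h %% 256) * 16777216 + (h %% 16777216) * 256 + h * 147) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
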