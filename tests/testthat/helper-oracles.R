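# Independent brute-force oracles: direct O(N^2) DFT and explicit
# summations, sharing no code with the package's FFT-based estimators.

dft_oracle <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  as.vector(W %*% x)
}

hann_oracle <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# one-sided Parseval-normalized periodogram from the direct DFT
spectrum_oracle <- function(x, fs = 250, window = "hann") {
  n <- length(x)
  w <- if (window == "hann") hann_oracle(n) else rep(1, n)
  X <- dft_oracle(x * w)
  p <- Mod(X)^2 / n^2
  half <- floor(n / 2) + 1
  pow <- p[seq_len(half)]
  if (n %% 2 == 0) pow[2:(half - 1)] <- 2 * pow[2:(half - 1)] else pow[2:half] <- 2 * pow[2:half]
  list(frequencies = (seq_len(half) - 1) * fs / n, power = pow)
}

band_power_oracle <- function(sp, low, high, lower_closed = (low <= 0.5)) {
  f <- sp$frequencies
  sel <- if (lower_closed) f >= low & f <= high else f > low & f <= high
  sum(sp$power[sel])
}

# brute-force bispectral band sum: explicit loop over the principal
# domain, direct-DFT spectra, complex average across windows
bispectrum_band_oracle <- function(subs, low, high, fs = 250, window = "hann") {
  n <- length(subs[[1]])
  w <- if (window == "hann") hann_oracle(n) else rep(1, n)
  Xs <- lapply(subs, function(x) dft_oracle(x * w) / n)
  half <- floor(n / 2)
  total <- 0
  for (k1 in 0:floor(half / 2)) {
    for (k2 in k1:(half - k1)) {
      fsum <- (k1 + k2) * fs / n
      if (fsum < low || fsum > high) next
      acc <- 0i
      for (X in Xs) acc <- acc + X[k1 + 1] * X[k2 + 1] * Conj(X[k1 + k2 + 1])
      total <- total + Mod(acc / length(Xs))
    }
  }
  total
}

# Mann-Whitney U (ties counted half), normalized
auc_mw_oracle <- function(feature, positive) {
  pos <- feature[positive]; neg <- feature[!positive]
  u <- 0
  for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
  u / (length(pos) * length(neg))
}

welch_p_oracle <- function(x, y) stats::t.test(x, y, var.equal = FALSE)$p.value

# classical ANOVA sums of squares by hand
anova_oracle <- function(groups) {
  v <- unlist(groups)
  gm <- mean(v)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(v) - length(groups)
  F <- (ss_b / df_b) / (ss_w / df_w)
  list(F = F, p = stats::pf(F, df_b, df_w, lower.tail = FALSE),
       ss_between = ss_b, ss_within = ss_w, ss_total = sum((v - gm)^2))
}

# small helper: fraction of epoch spectral power above 8 Hz
high_band_fraction <- function(x, fs = 250) {
  sp <- compute_spectrum(x, fs = fs)
  band_power(sp, 8, 47, lower_closed = FALSE) / band_power(sp, 0.5, 47)
}
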