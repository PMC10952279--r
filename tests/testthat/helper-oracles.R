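# Independent brute-force oracles and small fixture builders.

# direct O(n^2) DFT periodogram of one Hann-tapered, mean-removed window;
# deliberately avoids the package's FFT path
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # symmetric Hann
  xs <- (x - mean(x)) * w
  nf <- n %/% 2 + 1
  p <- numeric(nf)
  for (k in seq_len(nf)) {
    ang <- -2 * pi * (k - 1) * (0:(n - 1)) / n
    p[k] <- (sum(xs * cos(ang))^2 + sum(xs * sin(ang))^2) / (fs * sum(w^2))
  }
  p[-c(1, if (n %% 2 == 0) nf)] <- 2 * p[-c(1, if (n %% 2 == 0) nf)]
  p
}

# exhaustive pair count for D_RS / Mann-Whitney AUC
oracle_pair_auc <- function(x_positive, y) {
  s <- 0
  for (a in x_positive) for (b in y)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(x_positive) * length(y))
}

# exhaustive scan over every candidate cut for the Youden-optimal threshold
oracle_best_J <- function(values, outcomes, direction) {
  u <- sort(unique(values))
  cuts <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  bad <- outcomes == "bad"
  best <- -Inf
  for (cut in cuts) {
    flag <- if (direction == "low") values < cut else values > cut
    best <- max(best, mean(flag[bad]) - mean(flag[!bad]))
  }
  best
}

# abnormality map built directly from given scores
make_abn <- function(z, ids = sprintf("r%02d", seq_along(z)),
                     subject = "s1") {
  structure(list(subject_id = subject, region_ids = ids,
                 max_abs_z = stats::setNames(z, ids),
                 argmax_band = rep("delta", length(z))),
            class = "abnormality_map")
}

make_mask <- function(status, ids = sprintf("r%02d", seq_along(status))) {
  resection_mask(ids, status)
}

# band-power table with given rows (rows must sum to 1)
make_bpt <- function(values, subject = "s1",
                     bands = c("delta", "theta", "alpha", "beta", "gamma")) {
  v <- matrix(values, ncol = length(bands), byrow = TRUE,
              dimnames = list(sprintf("r%02d", seq_len(length(values) %/%
                                                         length(bands))),
                              bands))
  band_power_table(v, subject_id = subject)
}
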