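# Independent oracles used to freeze expected values. These deliberately use
# different code paths (explicit sums, stats::cor, signal::specgram) from the
# implementation they check.

# Brute-force normalized cross-correlation: explicit Pearson formula on the
# overlapping samples at every lag.
xcorr_oracle <- function(a, b, rate, max_lag = 0.1) {
  n <- length(a)
  L <- round(max_lag * rate)
  lags <- -L:L
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      x <- a[1:(n - k)]; y <- b[(1 + k):n]
    } else {
      x <- a[(1 - k):n]; y <- b[1:(n + k)]
    }
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }, numeric(1))
  list(lag_s = lags / rate, r = r)
}

# Closed-form sums-of-squares one-way repeated-measures ANOVA.
# d: data.frame(y, subject, level), complete and balanced.
rm1_oracle <- function(d) {
  g <- mean(d$y)
  lv <- tapply(d$y, d$level, mean)
  sb <- tapply(d$y, d$subject, mean)
  k <- length(lv); n <- length(sb)
  ss_level <- n * sum((lv - g)^2)
  ss_subj <- k * sum((sb - g)^2)
  ss_total <- sum((d$y - g)^2)
  ss_err <- ss_total - ss_level - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  F <- (ss_level / df1) / (ss_err / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = pf(F, df1, df2, lower.tail = FALSE),
       ss = c(level = ss_level, subject = ss_subj, error = ss_err,
              total = ss_total))
}

# Closed-form mixed-design ANOVA (between: group, within: level), balanced
# within subjects, group sizes may differ.
rm2_oracle <- function(d) {
  g <- mean(d$y)
  k <- length(unique(d$level))
  subj <- unique(d[, c("subject", "group")])
  N <- nrow(subj)
  G <- length(unique(d$group))
  sb <- tapply(d$y, d$subject, mean)
  ss_between <- k * sum((sb - g)^2)
  gm <- tapply(d$y, d$group, mean)
  ng <- table(subj$group)
  ss_group <- k * sum(ng[names(gm)] * (gm - g)^2)
  ss_sw <- ss_between - ss_group
  lvm <- tapply(d$y, d$level, mean)
  ss_level <- N * sum((lvm - g)^2)
  cellm <- tapply(d$y, list(d$group, d$level), mean)
  ss_cells <- 0
  for (gg in rownames(cellm)) {
    ss_cells <- ss_cells + sum(ng[gg] * (cellm[gg, ] - g)^2)
  }
  ss_int <- ss_cells - ss_group - ss_level
  ss_total <- sum((d$y - g)^2)
  ss_err <- ss_total - ss_between - ss_level - ss_int
  df_g <- G - 1; df_sw <- N - G
  df_l <- k - 1; df_e <- (N - G) * (k - 1)
  list(F_group = (ss_group / df_g) / (ss_sw / df_sw),
       F_level = (ss_level / df_l) / (ss_err / df_e),
       F_int = (ss_int / (df_g * df_l)) / (ss_err / df_e),
       df = list(group = c(df_g, df_sw), level = c(df_l, df_e),
                 int = c(df_g * df_l, df_e)),
       ss = c(group = ss_group, sw = ss_sw, level = ss_level,
              int = ss_int, error = ss_err, total = ss_total))
}

# Random complete one-way RM design.
random_rm1 <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1); k <- sample(3:5, 1)
  expand.grid(subject = paste0("s", 1:n), level = paste0("l", 1:k),
              KEEP.OUT.ATTRS = FALSE) |>
    transform(y = rnorm(n * k, sd = runif(1, 0.5, 5)))
}

# Random mixed design (2 groups, possibly unequal sizes).
random_rm2 <- function(seed) {
  set.seed(seed)
  n1 <- sample(3:6, 1); n2 <- sample(3:6, 1); k <- sample(2:5, 1)
  subj <- data.frame(subject = paste0("s", 1:(n1 + n2)),
                     group = rep(c("a", "b"), c(n1, n2)))
  d <- merge(subj, data.frame(level = paste0("l", 1:k)))
  d$y <- rnorm(nrow(d), sd = runif(1, 0.5, 5))
  d
}

# Theta-band signal + pink background, as one uncoupled channel.
uncoupled_channel <- function(n, rate, theta_sd = 15, noise_sd = 10) {
  theta_sd * fearlfp:::bandlimited_noise(n, rate, c(4, 10)) +
    noise_sd * fearlfp:::pink_noise(n, rate, 1, c(1, rate / 2))
}

# Monte-Carlo no-coherence floor: mean theta coherence between independent
# white-noise pairs of the same length/window setup.
coherence_floor_oracle <- function(n, rate, reps, seed = 1) {
  set.seed(seed)
  vapply(seq_len(reps), function(i) {
    coherence_spectrum(rnorm(n), rnorm(n), rate)$theta_coherence
  }, numeric(1))
}

# Short-time FFT ridge frequency for each frame (oracle for the CWT ridge).
stft_ridge_oracle <- function(x, rate, wlen = 256) {
  sp <- signal::specgram(x, n = wlen, Fs = rate, overlap = wlen - 8)
  f <- sp$f[sp$f > 0]
  ridge <- apply(Mod(sp$S[sp$f > 0, , drop = FALSE]), 2, which.max)
  list(t = sp$t, f = f[ridge])
}
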