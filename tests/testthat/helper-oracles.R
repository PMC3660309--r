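# Independent brute-force oracles for the scaling estimators. These are
# deliberately naive (explicit loops, lm fits) and share no code with the
# implementation they check.

oracle_structure_function <- function(x, lags, q) {
  n <- length(x)
  S <- sapply(lags, function(tau) {
    acc <- 0
    for (t in 1:(n - tau)) acc <- acc + abs(x[t + tau] - x[t])^q
    acc / (n - tau)
  })
  fit <- lm(I(log(S) / q) ~ log(lags))
  list(S = S, H = unname(coef(fit)[2]))
}

oracle_aggvar_variances <- function(x, ms) {
  sapply(ms, function(m) {
    nb <- floor(length(x) / m)
    means <- numeric(nb)
    for (b in 1:nb) means[b] <- mean(x[((b - 1) * m + 1):(b * m)])
    var(means)
  })
}

oracle_higuchi_lengths <- function(x, kmax) {
  n <- length(x)
  sapply(1:kmax, function(k) {
    lm_vals <- numeric(k)
    for (m in 1:k) {
      nk <- floor((n - m) / k)
      s <- 0
      for (i in 1:nk) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      lm_vals[m] <- s * (n - 1) / (nk * k) / k
    }
    mean(lm_vals)
  })
}

oracle_dfa_F <- function(x, boxes) {
  y <- cumsum(x - mean(x))
  n <- length(y)
  sapply(boxes, function(w) {
    ssr <- numeric(n - w + 1)
    for (a in 1:(n - w + 1)) {
      seg <- y[a:(a + w - 1)]
      fit <- lm(seg ~ seq_len(w))
      ssr[a] <- sum(residuals(fit)^2)
    }
    sqrt(mean(ssr) / w)
  })
}

# Steps (1)-(6) of the classic rescaled-range recipe, scale by scale.
oracle_rs <- function(x) {
  L <- length(x)
  scales <- c(); ers <- c()
  k <- 1
  while (floor(L / k) >= 8) {
    slen <- floor(L / k)
    rs_vals <- numeric(k)
    for (s in 1:k) {
      seg <- x[((s - 1) * slen + 1):(s * slen)]
      Y <- cumsum(seg - mean(seg))
      rs_vals[s] <- (max(Y) - min(Y)) / sd(seg)
    }
    scales <- c(scales, slen)
    ers <- c(ers, mean(rs_vals))
    k <- k * 2
  }
  fit <- lm(log2(ers) ~ log2(scales))
  list(scales = scales, ers = ers, H = unname(coef(fit)[2]))
}
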