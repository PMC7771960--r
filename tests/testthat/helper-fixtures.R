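# Small deterministic fixtures built in code.

# A SignalExperiment whose replicate values are exact means plus a fixed
# offset pattern, so every downstream estimate is hand-checkable.
makeExactSE <- function(means, cv = 0, nRep = 3) {
  # means: data.frame(signal, dose, mu) with one row per condition group;
  # features are rows of mu (a matrix features x groups)
  mu <- means$mu
  sig <- character(); dos <- character(); rp <- integer()
  cols <- list()
  for (i in seq_len(nrow(means))) {
    for (r in seq_len(nRep)) {
      cols[[length(cols) + 1]] <- mu[[i]]
      sig <- c(sig, means$signal[i]); dos <- c(dos, means$dose[i])
      rp <- c(rp, r)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- names(mu[[1]])
  SignalExperiment(m, sig, dos, rp)
}

# One-gene design (control + one dose of A, B, both) with given replicate
# values per condition.
oneFeatureSE <- function(ctrl, a, b, both, dose = "medium",
                         id = "feat1") {
  vals <- c(ctrl, a, b, both)
  n <- c(length(ctrl), length(a), length(b), length(both))
  m <- matrix(vals, nrow = 1)
  rownames(m) <- id
  SignalExperiment(
    m,
    signal = rep(c("control", "signalA", "signalB", "both"), n),
    dose = rep(c("none", dose, dose, dose), n),
    replicate = unlist(lapply(n, seq_len)))
}

# Brute-force Welch p value from the textbook formula (independent oracle).
welchOracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

randomValidTuple <- function() {
  x0 <- runif(1, 1, 500)
  dA <- runif(1, 0.5, 300)
  dB <- runif(1, 0.5, 300)
  list(x0 = x0, dA = dA, dB = dB)
}
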