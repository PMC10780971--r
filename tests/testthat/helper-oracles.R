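# Independent oracles and shared fixtures for the test suite.

# Brute-force local-extrema scan with amplitude gates (no refractory):
# sample i (2..L-1) is a maximum when it rises into i and does not rise
# after it, mirroring the first-difference zero-crossing definition.
bruteExtrema <- function(x, sysGate = c(100, 150), diaGate = c(60, 100)) {
  L <- length(x)
  idx <- 2:(L - 1)
  isMax <- x[idx] > x[idx - 1] & x[idx + 1] <= x[idx]
  isMin <- x[idx] < x[idx - 1] & x[idx + 1] >= x[idx]
  sys <- idx[isMax]
  sys <- sys[x[sys] >= sysGate[1] & x[sys] <= sysGate[2]]
  dia <- idx[isMin]
  dia <- dia[x[dia] >= diaGate[1] & x[dia] <= diaGate[2]]
  list(sys = sys, dia = dia)
}

# Pure-R (double precision) forward pass of the stacked-LSTM regressor,
# independent of the compiled implementation. X is T x features.
lstmForwardR <- function(weights, X) {
  sigm <- function(x) 1 / (1 + exp(-x))
  nl <- (length(weights) - 2) / 3
  H <- X
  for (l in seq_len(nl)) {
    W <- weights[[3 * l - 2]]
    U <- weights[[3 * l - 1]]
    b <- weights[[3 * l]]
    u <- nrow(U)
    h <- numeric(u)
    cc <- numeric(u)
    Hs <- matrix(0, nrow(H), u)
    for (t in seq_len(nrow(H))) {
      z <- as.numeric(H[t, ] %*% W) + as.numeric(h %*% U) + b
      i <- sigm(z[1:u])
      f <- sigm(z[(u + 1):(2 * u)])
      g <- tanh(z[(2 * u + 1):(3 * u)])
      o <- sigm(z[(3 * u + 1):(4 * u)])
      cc <- f * cc + i * g
      h <- o * tanh(cc)
      Hs[t, ] <- h
    }
    H <- Hs
  }
  as.numeric(H[nrow(H), ] %*% weights[[3 * nl + 1]]) + weights[[3 * nl + 2]]
}

# Closed-form LSTM layer parameter count.
lstmParamCount <- function(units, features) {
  as.integer(4 * (units * (features + units) + units))
}

# Small preprocessed cohort cached across test files.
tinyCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- simulateCohort(4, duration = 30, masterSeed = 55)
      cache <<- lapply(cohort, preprocessRecording)
    }
    cache
  }
})
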