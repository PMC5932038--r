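# Independent oracles kept deliberately naive and separate from the
# package's code paths.

kT300 <- 0.0083144621 * 300

# Naive WHAM: plain-R, log-space, loop-based self-consistent iteration
# written directly from the estimating equations; shares no code with
# the package solver (its own binning included).
naive_wham <- function(windows, n_bins, L, kT = kT300, tol = 1e-8,
                       max_iter = 2e5) {
  samp <- lapply(windows, function(w) {
    n <- length(w$samples)
    s <- w$samples[(floor(n * w$discard_fraction) + 1):n]
    s %% L
  })
  edges <- seq(0, L, length.out = n_bins + 1)
  mid <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  nwin <- length(windows)
  n_ib <- matrix(0, nwin, n_bins)
  for (i in seq_len(nwin)) {
    h <- hist(samp[[i]], breaks = edges, plot = FALSE)
    n_ib[i, ] <- h$counts
  }
  Ntot <- colSums(n_ib)
  N_i <- rowSums(n_ib)
  logc <- matrix(0, nwin, n_bins)
  for (i in seq_len(nwin)) {
    d <- abs(mid - windows[[i]]$center)
    d <- pmin(d, L - d)
    logc[i, ] <- -0.5 * windows[[i]]$k * d^2 / kT
  }
  logf <- rep(0, nwin)
  logsumexp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(x - m)))
  }
  for (it in seq_len(max_iter)) {
    logp <- sapply(seq_len(n_bins), function(b) {
      den <- logsumexp(log(N_i) + logf + logc[, b])
      if (Ntot[b] == 0) -Inf else log(Ntot[b]) - den
    })
    logp <- logp - logsumexp(logp)
    logf_new <- -sapply(seq_len(nwin), function(i)
      logsumexp(logp + logc[i, ]))
    if (max(abs(kT * (logf_new - logf))) < tol) {
      logf <- logf_new
      break
    }
    logf <- logf_new
  }
  list(z = mid, W = -kT * logp)
}

# trapezoid on a fine grid (binding oracle)
fine_quadrature_dG0 <- function(Wfun, bound, area, kT = kT300,
                                n = 2e5) {
  z <- seq(bound[1], bound[2], length.out = n + 1)
  f <- exp(-Wfun(z) / kT)
  I <- sum(diff(z) * (f[-1] + f[-length(f)]) / 2)
  -kT * log(area * I / 1.6606)
}

# wrapped random walk with guaranteed unwrap-valid steps, plus the true
# unwrapped series (crossing-count oracle)
make_wrapped_walk <- function(n, L, drift, sd_step) {
  dz <- rnorm(n - 1, mean = drift, sd = sd_step)
  dz <- pmax(pmin(dz, 0.4 * L), -0.4 * L)
  zu <- cumsum(c(runif(1, 0, L), dz))
  list(zu = zu, zw = zu %% L)
}

# rotation about the z axis
rotate_z <- function(pos, angle) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  pos %*% R
}
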