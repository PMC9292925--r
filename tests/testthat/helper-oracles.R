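# Independent oracles, deliberately written with different machinery than
# the implementations they check.

# spreadsheet-style tally of the risk-taking score
oracle_rt <- function(pumps, exploded) {
  total <- 0
  nexp <- 0
  for (i in seq_along(pumps)) {
    total <- total + pumps[i]
    if (exploded[i]) nexp <- nexp + 1
  }
  (total / length(pumps)) * (nexp + 1) / length(pumps)
}

oracle_cov <- function(pumps) {
  m <- sum(pumps) / length(pumps)
  ss <- sum((pumps - m)^2)
  sqrt(ss / (length(pumps) - 1)) / m
}

# textbook Pearson r and t-based p
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n
  sy <- y - sum(y) / n
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# commonality via explicit normal equations (no lm)
oracle_r2 <- function(y, X) {
  X <- cbind(1, X)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- X %*% beta
  1 - sum((y - fit)^2) / sum((y - mean(y))^2)
}

# flood-fill connected components on integer lattice points
oracle_flood_fill <- function(ijk, connectivity) {
  n <- nrow(ijk)
  lab <- rep(NA_integer_, n)
  nb <- function(a, b) {
    d <- abs(ijk[a, ] - ijk[b, ])
    if (any(d > 1)) return(FALSE)
    s <- sum(d)
    if (connectivity == 6) return(s == 1)
    if (connectivity == 18) return(s >= 1 && s <= 2)
    s >= 1
  }
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(lab[i])) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      a <- queue[1]
      queue <- queue[-1]
      for (b in seq_len(n)) {
        if (is.na(lab[b]) && nb(a, b)) {
          lab[b] <- cur
          queue <- c(queue, b)
        }
      }
    }
  }
  lab
}

# small planted-cluster config on a compact grid for fast pipeline tests
small_effect_config <- function(n_subjects = 104, b = 0.35, voxel_noise = 0,
                                seed = 1L, grid = c(10, 10, 10)) {
  cl <- planted_cluster(center = c(5, 5, 5), radius_mm = 5, band = "delta",
                        trait = "extraversion", a = 0.5,
                        behaviour = "rt", b = b)
  sim_config(n_subjects = n_subjects, grid_dims = grid,
             cluster_specs = list(acc = cl),
             noise_sds = list(voxel = voxel_noise, background = 1),
             seed = seed)
}

# sinusoid recording helper
make_tone_recording <- function(freqs, amps, seconds, fs = 256, nchan = 1,
                                noise_sd = 0) {
  t <- seq_len(seconds * fs) / fs
  sig <- rep(0, length(t))
  for (i in seq_along(freqs)) sig <- sig + amps[i] * sin(2 * pi * freqs[i] * t)
  x <- matrix(rep(sig, nchan), nrow = nchan, byrow = TRUE) +
    matrix(rnorm(nchan * length(t), 0, noise_sd), nchan)
  eeg_recording(x, fs)
}
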