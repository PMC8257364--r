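# Naive loop-based reference trainer. Replays exactly the RNG protocol of
# train_cpn (seeded uniform prototype init, per-epoch shuffles) but runs
# the network equations with explicit R loops and plain double
# accumulation, so the compiled implementation must match it bit-for-bit.
reference_train_cpn <- function(train, subset, geometry, schedule, seed) {
  scaling <- fit_scaling(train, subset)
  X <- apply_scaling(scaling, train)
  d <- as.numeric(train$label)
  n <- nrow(X)
  k <- ncol(X)
  units <- geometry$units
  radius0 <- if (is.null(schedule$radius0)) {
    max(geometry$rows, geometry$cols) / 2
  } else {
    schedule$radius0
  }
  lat <- lattice_distances(geometry)

  set.seed(seed)
  w <- matrix(runif(units * k), nrow = units)
  z <- rep(0.5, units)
  n_pres <- schedule$epochs * n
  if (n_pres == 0L) return(list(w = w, z = z))
  order <- unlist(lapply(seq_len(schedule$epochs), function(e) sample.int(n)))

  for (t in seq_len(n_pres)) {
    r <- order[t]
    alpha <- schedule$alpha0 * (1 - t / n_pres)
    gamma <- schedule$gamma0 * (1 - t / n_pres)
    radius <- radius0 * max(0, 1 - 2 * t / n_pres)
    winner <- 1L
    best <- Inf
    for (l in seq_len(units)) {
      s <- 0
      for (j in seq_len(k)) {
        diff <- X[r, j] - w[l, j]
        s <- s + diff * diff
      }
      net <- sqrt(s)
      if (net < best) {
        best <- net
        winner <- l
      }
    }
    for (l in seq_len(units)) {
      if (lat[winner, l] <= radius) {
        for (j in seq_len(k)) {
          w[l, j] <- w[l, j] + alpha * (X[r, j] - w[l, j])
        }
      }
    }
    z[winner] <- z[winner] + gamma * (d[r] - z[winner])
  }
  list(w = w, z = z)
}

# Exponentially-weighted-mean oracle for a single-unit map: the lone unit
# wins every presentation, so its readout weight is the recursive weighted
# mean of the shuffled labels under the same decaying gamma sequence.
single_unit_z_oracle <- function(train, schedule, seed) {
  d <- as.numeric(train$label)
  n <- length(d)
  n_pres <- schedule$epochs * n
  set.seed(seed)
  runif(1)  # prototype init draw for a 1-unit, 1-feature map is 1 value
  order <- unlist(lapply(seq_len(schedule$epochs), function(e) sample.int(n)))
  z <- 0.5
  for (t in seq_len(n_pres)) {
    gamma <- schedule$gamma0 * (1 - t / n_pres)
    z <- z + gamma * (d[order[t]] - z)
  }
  z
}
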