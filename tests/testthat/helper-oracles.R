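# Brute-force posterior over hypotheses given a full observation sequence:
# P(h | d_1..d_T) proportional to P(h) * prod_t P(d_t | h).  Independent of
# the iterative engine; used as the enumeration oracle.
posterior_enumeration <- function(prior, likelihood, sequence) {
  w <- prior
  for (d in sequence) w <- w * likelihood[, d + 1L]
  w / sum(w)
}

# all sequences of a given length over symbols 0..n-1, as a list
all_sequences <- function(len, n) {
  if (len == 0L) return(list(integer(0)))
  grid <- do.call(expand.grid, rep(list(0:(n - 1L)), len))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# total variation distance between two discrete distributions
tv_dist <- function(p, q) sum(abs(p - q)) / 2

# lag (in steps) at which the cross-correlation of prediction with truth
# peaks; larger lag = prediction trails the truth by more
peak_lag <- function(truth, prediction, lag_max = 500) {
  cc <- stats::ccf(prediction, truth, lag.max = lag_max, plot = FALSE)
  cc$lag[which.max(cc$acf)]
}

# a small irregular likelihood for oracle tests (rows sum to 1)
oracle_likelihood <- function() {
  rbind(c(0.5, 0.3, 0.2),
        c(0.2, 0.5, 0.3),
        c(0.1, 0.2, 0.7))
}

# standard phase-alternating fixture used across pipeline tests
make_phase_fixture <- function(seed, n_phases = 4, duration = 600, N = 20) {
  sched <- phase_schedule(rep(duration, n_phases),
                          rep(c("coherent", "dispersed"),
                              length.out = n_phases))
  generate_phase_trajectories(sched, N = N, seed = seed)
}
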