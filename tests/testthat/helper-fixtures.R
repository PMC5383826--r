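# Shared fixtures and independent oracles, built in code at test time.

# default-condition bank reused across files
fixture_bank <- generate_bank(seed = 101)
fixture_tracks <- generate_aoi_tracks(fixture_bank, seed = 101)

# independent standard-normal quantile: numerical inversion of pnorm,
# never touching qnorm
qnorm_oracle <- function(p) {
  vapply(p, function(pp)
    stats::uniroot(function(z) stats::pnorm(z) - pp, c(-12, 12),
                   tol = 1e-13)$root, numeric(1))
}

# brute-force reimplementation of the SDT formula chain from raw counts
sdt_oracle <- function(hits, n_signal, fas, n_noise, s) {
  h <- (hits + 0.5) / (n_signal + 1)
  f <- (fas + 0.5) / (n_noise + 1)
  d <- qnorm_oracle(h) - qnorm_oracle(f)
  lobs <- -qnorm_oracle(f)
  lopt <- 0.5 * d - log(s / (1 - s)) / d
  list(hit_rate = h, fa_rate = f, d_prime = d, lambda_obs = lobs,
       lambda_opt = lopt, bias = lobs - lopt)
}

# hand-buildable counting-span transcript
make_transcript <- function(trial_specs, stopped_early = FALSE) {
  trials <- lapply(trial_specs, function(sp) {
    list(set_size = length(sp$true), true_tallies = sp$true,
         recalled_tallies = sp$recalled)
  })
  structure(list(trials = trials, stopped_early = stopped_early),
            class = "counting_span_transcript")
}

# constant-circle AOI track for constructed gaze fixtures
make_track <- function(appear = 1, end = 10, x = 0.7, y = 0.3, r = 0.08,
                       clip_id = "g01", target_id = "T01") {
  list(clip_id = clip_id, target_id = target_id, appear_time = appear,
       end_time = end, x = x, y = y, radius = r)
}

# gaze stream at a fixed rate whose in/out-of-AOI pattern is given
make_stream <- function(t, inside, track, valid = TRUE) {
  data.frame(t_s = t,
             x = ifelse(inside, track$x, track$x + 3 * track$radius),
             y = track$y, valid = valid)
}

flat_profile <- function(d_prime, criterion, group = "adult", ...) {
  observer_profile(group, d_prime_by_phase = rep(d_prime, 3),
                   criterion = rep(criterion, 3), ...)
}
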