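# Shared fixtures: everything is generated in code at test time.

# small, fast simulator configuration (latent/label structure identical to the
# default; only signal length is reduced)
tiny_cfg <- function(...) {
  defaults <- list(n_participants = 5, n_exercises_per_participant = 2,
                   n_repetitions = 2, duration = 2, sample_rate = 50,
                   sway_band = c(0.1, 3), seed = 11)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

make_rec <- function(pitch, roll, rate = 100, id = "r1", pid = "p1",
                     eid = "ex1") {
  sway_recording(id, pid, eid, rate, pitch, roll)
}

sine_rec <- function(A = 10, f = 1, duration = 30, rate = 100, phase = 0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  make_rec(A * cos(2 * pi * f * t + phase), A * sin(2 * pi * f * t + phase),
           rate = rate)
}

# dataset of n labeled repetitions with short random signals
quick_dataset <- function(n = 10, n_participants = 2, rate = 20,
                          duration = 2, seed = 99) {
  with_seed <- function(s, code) { # local: keep test RNG clean
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); code
  }
  with_seed(seed, {
    m <- round(duration * rate)
    recs <- lapply(seq_len(n), function(i)
      sway_recording(sprintf("r%02d", i),
                     sprintf("p%d", 1 + (i - 1) %% n_participants), "ex1",
                     rate, rnorm(m), rnorm(m)))
    rats <- lapply(seq_len(n), function(i)
      rating_set(setNames(sample(1:5, 3, replace = TRUE), paste0("pt", 1:3)),
                 self_rating = sample(1:5, 1)))
    names(rats) <- sprintf("r%02d", seq_len(n))
    sway_dataset(recs, rats)
  })
}
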