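# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Directly constructed epoch set (already at the analysis rate): per-condition
# channel mean patterns plus white noise. Cheap stand-in for a preprocessed
# session when the test targets resampling / decoding machinery.
make_label_epochs <- function(n_per_cond, conds = c("A", "B"), n_ch = 8,
                              n_t = 20, rate = 125, noise_sd = 1,
                              cond_means = NULL, seed = 1,
                              participant = "P01") {
  set.seed(seed)
  n <- n_per_cond * length(conds)
  labels <- rep(conds, each = n_per_cond)
  dat <- array(rnorm(n * n_ch * n_t, sd = noise_sd), dim = c(n, n_ch, n_t))
  if (!is.null(cond_means)) {
    for (cond in names(cond_means)) {
      idx <- which(labels == cond)
      add <- aperm(array(cond_means[[cond]],
                         dim = c(n_ch, n_t, length(idx))), c(3, 1, 2))
      dat[idx, , ] <- dat[idx, , , drop = FALSE] + add
    }
  }
  times <- seq(-200, by = 1000 / rate, length.out = n_t)
  epoch_set(dat, labels, times, rate, participant)
}

# One participant at the full default session design (6 blocks x 210 trials,
# 64 channels, 1000 Hz), preprocessed to 125 Hz. Used by the wiring and
# chance-control checks; generated once.
default_participant <- function() {
  fixture("default_participant", function() {
    spec <- session_spec(n_participants = 1, master_seed = 7101)
    one <- generate_participant(spec, 1)
    list(pre = preprocess_epochs(one$epochs), ground_truth = one$ground_truth)
  })
}

# Reduced-size signal-bearing group session for latency recovery: 6
# participants, 4 blocks (the smallest pool that supports the default
# 21 x 10 bootstrap partition).
latency_group <- function() {
  fixture("latency_group", function() {
    spec <- session_spec(n_participants = 6, n_blocks = 4, master_seed = 77)
    simulate_preprocessed(spec)
  })
}
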