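# Shared fixtures, built in code at load time. Small sizes keep the unit
# suite fast; the acceptance tests build their own study-scale runs.

tiny_config <- function(seed = 42L)
  design_config(study = 2, n_subjects = 4, blocks = 2, trials_per_block = 30,
                seed = seed)

quiet_erp <- function(...)
  generator_config(erp = utils::modifyList(
    list(background_noise_sd = 0, artifact_fraction = 0), list(...)))

# One cached small study used by several read-only tests.
tiny_sim <- simulate_study(tiny_config(), seed = 42L)

# Build a cue-locked epoch set from an explicit trial x channel x time array
# on the standard 512 Hz grid.
make_epochs <- function(data, window = c(-200, 800), anchor = "feedback") {
  times <- evcontrol:::epoch_times_ms(window)
  stopifnot(dim(data)[3] == length(times))
  epoch_set(data, times, c("Fz", "FCz", "Cz", "Pz", "P3", "P4"), anchor,
            subject = rep(1L, dim(data)[1]), trial = seq_len(dim(data)[1]))
}

flat_epochs <- function(n_trial = 1, value = 0, window = c(-200, 800),
                        anchor = "feedback") {
  times <- evcontrol:::epoch_times_ms(window)
  make_epochs(array(value, c(n_trial, 6, length(times))), window, anchor)
}
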