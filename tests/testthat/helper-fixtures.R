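# shared fixtures: reduced montages and quick simulated subjects

# a small spread-out scalp subset of the bundled montage
small_montage <- function(n = 8) {
  chans <- c("Fz", "Cz", "Pz", "Oz", "C3", "C4", "P3", "P4",
             "F3", "F4", "FCz", "CPz", "O1", "O2", "T7", "T8")
  subset_montage(default_montage(), chans[seq_len(n)])
}

# a fast null or effect subject; srate 46 Hz gives a 50-sample epoch
quick_sim <- function(seed, n_pairs = 20, n_ch = 8, srate = 46,
                      amplitude = 0, effect = NULL, noise = noise_spec(),
                      ...) {
  if (is.null(effect))
    effect <- effect_spec(amplitude_uV = amplitude)
  simulate_subject(n_pairs = n_pairs, montage = small_montage(n_ch),
                   effect = effect, noise = noise, srate = srate,
                   seed = seed, ...)
}

# hand-built epochs from an explicit array (pairs interleaved)
epochs_from_array <- function(v, srate = 100, times = NULL) {
  n_pairs <- dim(v)[1] / 2
  if (is.null(times)) times <- epoch_times(srate, c(-100, 1000))[seq_len(dim(v)[3])]
  eeg_epochs(v, times, srate,
             condition = rep(c("congruent", "incongruent"), n_pairs),
             pair_id = rep(seq_len(n_pairs), each = 2))
}
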