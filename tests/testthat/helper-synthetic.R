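# Shared fixture builders: everything is generated in code at test time.

# Minimal hand-built trial table (experiment 1 layout) with full control over
# coordinates; valid_serial TRUE everywhere unless stated.
make_trials <- function(stim, start, report, prev_report, subject = 1L) {
  n <- nrow(stim)
  data.frame(subject = subject, block = 1L, trial = seq_len(n),
             current_stimulus_x = stim[, 1], current_stimulus_y = stim[, 2],
             current_start_x = start[, 1], current_start_y = start[, 2],
             current_report_x = report[, 1], current_report_y = report[, 2],
             previous_report_x = prev_report[, 1],
             previous_report_y = prev_report[, 2],
             valid_serial = TRUE)
}

# Epoch array with fully specified data.
make_epochs <- function(data, sfreq = 100, t0 = 0, stage = "encoding") {
  nt <- dim(data)[3]
  epoch_array(data, times = seq(t0, by = 1000 / sfreq, length.out = nt),
              sfreq = sfreq, stage = stage)
}

# Default predictors of the experiment-1 encoding regression.
EXP1_PREDICTORS <- c("current_stimulus", "current_start", "previous_report")

# High-SNR planted epochs over a behavioral table; returns list(trials, epochs).
planted_exp1 <- function(n_trials_per_block = 30, n_blocks = 2, axis_angle = 180,
                         noise_sd = 0.3, n_channels = 16, sfreq = 100,
                         window = c(100, 400), epoch_window = c(-100, 500),
                         seed = 1, trial_gain = NULL, trial_axis_angle = NULL) {
  tr <- simulate_behavior_exp1(1, n_trials_per_block, n_blocks, seed = seed)
  gt <- ground_truth(axis_angle = axis_angle, neural_noise_sd = noise_sd,
                     gain_present = list(window = window, amp = 1),
                     gain_past = list(window = window, amp = 1))
  ep <- simulate_neural(tr, gt, n_channels = n_channels, sfreq = sfreq,
                        epoch_window = epoch_window,
                        trial_gain = trial_gain,
                        trial_axis_angle = trial_axis_angle,
                        seed = seed + 1000)
  list(trials = tr, epochs = ep, truth = gt)
}

in_window <- function(times, window) times >= window[1] & times <= window[2]
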