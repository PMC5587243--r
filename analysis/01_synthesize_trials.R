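#!/usr/bin/env Rscript
# Step 1 of the workflow: generate a cohort of synthetic walking trials.
#
# The motion-capture recordings this pipeline was designed for are not
# redistributable, so the cohort below emulates their statistical
# structure: 7 pairs, each contributing one solo trial per walker and one
# paired trial, with stride periods of 1.0-1.3 s, steps of 0.6-0.8 m,
# phase lags spanning the pace/trot/diagonal-sequence anchors (two of
# them drifting), and 2 mm marker noise. Paired trials use slightly
# longer stride periods than solo ones, mirroring the observed slow-down
# when carrying.
#
# Writes: results/trials/<trial>_{A,B,object}.csv + ground-truth JSONs.

suppressPackageStartupMessages(library(pairedslip))

out_dir <- "results/trials"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

pairs <- data.frame(
  pair = sprintf("pair%02d", 1:7),
  stride_solo = c(1.04, 1.10, 1.16, 1.00, 1.22, 1.12, 1.06),
  stride_paired = c(1.12, 1.18, 1.26, 1.10, 1.30, 1.22, 1.14),
  step_solo = c(0.66, 0.70, 0.74, 0.62, 0.78, 0.72, 0.66),
  step_paired = c(0.60, 0.64, 0.68, 0.58, 0.72, 0.66, 0.62),
  phase_lag = c(0, 180, 225, 0, 180, 90, 350),
  phase_drift = c(0, 0, 0, 0, 0, 8, 0),
  seed = 100 + 1:7)

manifest <- list()
for (i in seq_len(nrow(pairs))) {
  p <- pairs[i, ]
  # solo trials: one per walker, shared anthropometrics
  for (subj in c("A", "B")) {
    cf <- synthetic_trial_config(
      n_strides = 8, stride_period = p$stride_solo,
      step_length = p$step_solo, noise_sd = 0.002,
      kind = "solo", seed = p$seed + ifelse(subj == "A", 0, 50))
    trial <- generate_trial(cf)
    write_trajectory_table(trial$A,
                           file.path(out_dir,
                                     sprintf("%s_solo_%s.csv", p$pair, subj)))
  }
  # paired trial
  cf <- synthetic_trial_config(
    n_strides = 8, stride_period = p$stride_paired,
    step_length = p$step_paired, phase_lag = p$phase_lag,
    phase_drift = p$phase_drift, noise_sd = 0.002, seed = p$seed)
  trial <- generate_trial(cf)
  write_trajectory_table(trial$A,
                         file.path(out_dir, sprintf("%s_paired_A.csv", p$pair)))
  write_trajectory_table(trial$B,
                         file.path(out_dir, sprintf("%s_paired_B.csv", p$pair)))
  write_trajectory_table(trial$object,
                         file.path(out_dir,
                                   sprintf("%s_paired_object.csv", p$pair)))
  truth <- trial$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth,
                       file.path(out_dir, sprintf("%s_truth.json", p$pair)),
                       auto_unbox = TRUE, digits = NA)
  manifest[[p$pair]] <- list(phase_lag = p$phase_lag,
                             phase_drift = p$phase_drift,
                             stride_solo = p$stride_solo,
                             stride_paired = p$stride_paired)
}
jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("wrote %d trial files under %s",
                length(list.files(out_dir)), out_dir))
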