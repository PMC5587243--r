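#!/usr/bin/env Rscript
# Step 5: solo- and paired-trial fitting against reference gaits.
#
# The reference "experimental" gait is produced by the model itself at
# the documented parameter set (the motion-capture data being
# unavailable), so fitting quality is measured as parameter recovery and
# score closeness:
#   solo fitting    maximizes periodicity only (a prediction of paired
#                   behaviour from solo preferences),
#   paired fitting  maximizes S_G = S_S * S_R * S_P against the
#                   reference apex height and apex velocity.
#
# Writes: results/fit/solo_fit.json, results/fit/paired_fit.json

suppressPackageStartupMessages(library(pairedslip))
dir.create("results/fit", recursive = TRUE, showWarnings = FALSE)

ref <- reference_gait_parameters()
ic <- search_initial_conditions(3)
truth_trace <- simulate_paired(ref$p1, ref$p2, ref$coupling,
                               ic$init1, ic$init2, t_max = 60)
sm <- gait_summary(truth_trace)
subjects <- data.frame(mass = 80, leg_length = 1,
                       z_apex = sm$z_apex, velocity = sm$vx_apex)
al <- ref$p1$alpha
grids <- list(k_leg = c(15e3, 16.5e3, 17.9e3, 19.5e3, 21e3),
              alpha = c(al - 0.06, al - 0.03, al, al + 0.03),
              k_arm = c(1500, 3100, 5000),
              b_arm = c(100, 200, 320))

for (mode in c("solo", "paired")) {
  fit <- trial_fitting(mode, subjects, grids = grids, t_max = 40)
  print(fit)
  message(sprintf(
    "  reference k_leg = %g, alpha = %.4f; recovered k_leg = %g, alpha = %.4f",
    ref$p1$k_leg, al, fit$p1$k_leg, fit$p1$alpha))
  message(sprintf(
    "  simulated vs reference apex velocity: %.3f vs %.3f m/s",
    fit$summary$vx_apex[1], subjects$velocity[1]))
  write_fit_result(fit, sprintf("results/fit/%s_fit.json", mode))
}
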