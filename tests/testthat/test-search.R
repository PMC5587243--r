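test_that("grid search scores cells, zeroes falling gaits and reports the argmax", {
  al <- 72.4 * pi / 180
  # 2 x 2 step-1 grid: reference cell walks, soft-leg steep-angle cell falls
  g <- systematic_search(1, grid1 = c(1.2e4, 17.9e3),
                         grid2 = c(al, 1.36), t_max = 25)
  expect_equal(dim(g$scores), c(2L, 2L))
  expect_gt(g$scores[2, 1], 0)            # reference cell is periodic
  expect_equal(g$scores[1, 2], 0)         # falling cell scores 0
  # argmax equals a brute-force scan of the stored matrix
  ij <- which(g$scores == max(g$scores), arr.ind = TRUE)[1, ]
  expect_equal(g$best[[g$param_names[1]]], g$grid1[ij[1]])
  expect_equal(g$best[[g$param_names[2]]], g$grid2[ij[2]])
  expect_equal(g$best$score, max(g$scores))

  # deterministic tie-break toward the smallest parameter values
  fake <- g
  fake$scores[] <- 1
  ij2 <- arrayInd(which(fake$scores == max(fake$scores)),
                  dim(fake$scores))
  expect_equal(ij2[order(ij2[, 1], ij2[, 2]), , drop = FALSE][1, ],
               c(1L, 1L), ignore_attr = TRUE)

  # step prerequisites
  expect_error(systematic_search(2, t_max = 5),
               class = "pairedslip_parameter_error")
  expect_error(systematic_search(3, fixed = list(k_leg = 1, alpha = 1),
                                 t_max = 5),
               class = "pairedslip_parameter_error")
  expect_error(systematic_search(1, grid1 = numeric(), grid2 = 1,
                                 t_max = 5),
               class = "pairedslip_parameter_error")
})

test_that("the reference cell attains a positive periodicity score when paired", {
  al <- 72.4 * pi / 180
  g2 <- systematic_search(2, fixed = list(k_leg = 17.9e3, alpha = al),
                          grid1 = c(3100), grid2 = c(200), t_max = 40)
  expect_gt(g2$best$score, 0)
  expect_equal(g2$best$k_arm, 3100)

  g3 <- systematic_search(3, fixed = list(k_leg = 17.9e3, alpha = al,
                                          k_arm = 3100, b_arm = 200),
                          grid1 = c(16e3, 17.9e3), grid2 = c(al),
                          t_max = 40)
  expect_gt(g3$scores[2, 1], 0)
})

test_that("solo and paired fitting differ only through their objective", {
  tr <- ref_paired_trace(100)
  sm <- gait_summary(tr)
  subjects <- data.frame(mass = 80, leg_length = 1,
                         z_apex = sm$z_apex, velocity = sm$vx_apex)
  al <- 72.4 * pi / 180
  grids <- list(k_leg = 17.9e3, alpha = al, k_arm = 3100, b_arm = 200)
  solo <- trial_fitting("solo", subjects, grids = grids, t_max = 30)
  paired <- trial_fitting("paired", subjects, grids = grids, t_max = 30)
  # on a single-cell grid both modes settle the same parameters, and the
  # solo objective is the periodicity score alone
  expect_equal(solo$step1$objective, "S_P")
  expect_equal(paired$step1$objective, "S_G")
  expect_equal(solo$p1$k_leg, paired$p1$k_leg)
  expect_equal(solo$S_G, solo$S_S * solo$S_R * solo$S_P)
  # the fitted simulation reproduces the reference speed closely
  expect_equal(solo$summary$vx_apex, subjects$velocity, tolerance = 0.05)
  expect_equal(solo$summary$velocity[1] / subjects$velocity[1], 1,
               tolerance = 0.05)

  expect_error(trial_fitting("paired", subjects[, 1:2]),
               class = "pairedslip_parameter_error")
})
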