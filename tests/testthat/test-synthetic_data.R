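test_that("cohort generation is reproducible and respects the null config", {
  cfg <- cohort_config(n_eyes = 50)
  c1 <- generate_cohort(cfg, seed = 99)
  c2 <- generate_cohort(cfg, seed = 99)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cfg, seed = 100)
  expect_false(identical(c1$axial_length, c3$axial_length))

  # zero effects and (numerically) zero residual variance: baselines exactly
  zero <- setNames(rep(0, 8), sector_names())
  cfg0 <- cohort_config(n_eyes = 20, target_r_al = zero, target_r_pmp = zero,
                        target_r_tilt = zero,
                        sector_sd = setNames(rep(1e-9, 8), sector_names()))
  ch0 <- generate_cohort(cfg0, seed = 1)
  for (s in sector_names()) {
    expect_equal(ch0[[paste0("ppct_", s)]],
                 rep(cohort_config()$sector_mean[[s]], 20), tolerance = 1e-6)
  }
})

test_that("cohort marginals match the configured distributions", {
  ch <- generate_cohort(cohort_config(n_eyes = 5000), seed = 7)
  expect_equal(mean(ch$axial_length), 25.46, tolerance = 0.1 / 25.46)
  expect_true(all(ch$axial_length >= 22.38 & ch$axial_length <= 30.42))
  expect_equal(mean(ch$pmp), 5.43, tolerance = 0.05)
  expect_equal(sd(ch$pmp), 3.47, tolerance = 0.05)
  expect_equal(mean(ch$tilt), 53.08, tolerance = 0.05)
  expect_true(all(ch$tilt >= 0))
  expect_true(all(ch[, paste0("ppct_", sector_names())] >= 1))
  # sector SDs close to the configured totals
  expect_equal(sd(ch$ppct_T), 62.45, tolerance = 0.05)
  # PPA prevalence rises with axial length
  expect_gt(mean(ch$ppa[ch$axial_length > 26.5]),
            mean(ch$ppa[ch$axial_length < 24.5]))
})

test_that("programmed effect directions are recovered at large n", {
  ch <- generate_cohort(cohort_config(n_eyes = 5000), seed = 13)
  sp <- spearman_cor(ch$axial_length, ch$ppct_T)
  expect_lt(sp$r, 0)
  expect_lt(sp$p, 1e-6)
  expect_gt(spearman_cor(ch$pmp, ch$ppct_S)$r, 0)
  expect_lt(spearman_cor(ch$tilt, ch$ppct_IT)$r, 0)
})

test_that("trace generation realizes tilt and thickness exactly without noise", {
  cfg <- trace_config(rpe_noise_sd = 0, marking_noise_sd = 0)
  eye <- generate_cohort(cohort_config(n_eyes = 1), seed = 3)
  eye$tilt <- 0
  tr0 <- generate_trace(eye, cfg)
  expect_equal(diff(range(tr0$trace$z_rpe)), 0, tolerance = 1e-12)

  eye$tilt <- 50
  tr <- generate_trace(eye, cfg)
  fit <- fit_sine(recenter(tr$marked))
  expect_equal(fit$a, 50, tolerance = 1e-6)

  st <- measure_ppct(tr$trace, tr$sectors)
  truth <- unlist(eye[paste0("ppct_", sector_names())])
  expect_equal(unname(unclass(st)), unname(truth), tolerance = 1e-3)
})

test_that("noisy round trip recovers sector thickness and tilt", {
  cfg <- trace_config(rpe_noise_sd = 2, marking_noise_sd = 2)
  ch <- generate_cohort(cohort_config(n_eyes = 10), seed = 17)
  for (i in seq_len(nrow(ch))) {
    tr <- generate_trace(ch[i, ], cfg, seed = 1000 + i)
    st <- measure_ppct(tr$trace, tr$sectors)
    truth <- unlist(ch[i, paste0("ppct_", sector_names())])
    expect_lt(max(abs(unclass(st) - truth)), 5)
    fit <- fit_sine(recenter(tr$marked))
    expect_lt(abs(fit$a - ch$tilt[i]), 4)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(sector_shared_frac = 1))
  expect_error(
    generate_cohort(cohort_config(n_eyes = 5,
                                  tilt = list(mean = 53, sd = 23.93,
                                              al_coupling = 30)),
                    seed = 1),
    "coupling")
  expect_error(trace_config(n_ascans = 32))
})
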