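test_that("solvent diffusivity is recovered from noiseless swelling data", {
  f <- gg_form()
  sp <- fixture_swelling("gg", "SIF")
  ser <- gen_swelling_series(f, medium("SIF"), sp,
                             noise = noise_model(level = 0),
                             grid = radial_grid(100))
  fit <- fit_swelling(ser, f, medium("SIF"), S_eq = 45.80)
  expect_lt(abs(fit$estimates$D_s_sg / 1.5e-9 - 1), 0.01)
  expect_true(fit$converged)
  expect_gt(fit$n_eval, 3) # multi-start actually ran
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, "D_s_sg")
  expect_true(td$std.error >= 0)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("a 10-point subsample still pins the solvent diffusivity", {
  f <- gg_form()
  sp <- fixture_swelling("gg", "SIF")
  ser <- gen_swelling_series(f, medium("SIF"), sp,
                             times_min = c(5, 10, 15, 20, 30, 45, 60, 120,
                                           480, 1440),
                             noise = noise_model(level = 0),
                             grid = radial_grid(100))
  fit <- fit_swelling(ser, f, medium("SIF"), S_eq = 45.80)
  expect_lt(abs(fit$estimates$D_s_sg / 1.5e-9 - 1), 0.02)
})

test_that("drug diffusivity is recovered from noiseless withdrawal data", {
  sp <- fixture_swelling("gg", "SIF")
  pr <- single_stage_protocol(gg_form("tph"), "SIF", sp, D_d_sg = 2.62e-10,
                              duration_min = 120,
                              schedule = default_schedule(120))
  gs <- gen_release_series(pr, noise = noise_model(level = 0),
                           grid = radial_grid(80))
  fit <- fit_release_fickian(gs$differential, pr)
  expect_lt(abs(fit$estimates$D_d_sg / 2.62e-10 - 1), 0.01)
})

test_that("noisy triplicate withdrawals still recover D within tolerance", {
  sp <- fixture_swelling("gg", "SIF")
  pr <- single_stage_protocol(gg_form("tph"), "SIF", sp, D_d_sg = 2.62e-10,
                              duration_min = 120,
                              schedule = default_schedule(120))
  errs <- sapply(c(3, 11, 19), function(s) {
    gs <- gen_release_series(pr, noise = noise_model(level = 0.03, seed = s),
                             grid = radial_grid(64))
    fit <- fit_release_fickian(gs$differential, pr, grid = radial_grid(64))
    abs(fit$estimates$D_d_sg / 2.62e-10 - 1)
  })
  expect_lt(median(errs), 0.05)
})

test_that("two-phase fit collapses to the Fickian estimate when eps = 0", {
  sp <- fixture_swelling("gg_lapo", "SGF")
  pr <- single_stage_protocol(lapo_form("b12"), "SGF", sp, D_d_sg = 2.87e-11,
                              duration_min = 240)
  gs <- gen_release_series(pr, noise = noise_model(level = 0),
                           grid = radial_grid(64))
  fick <- fit_release_fickian(gs$differential, pr, grid = radial_grid(64))
  two <- suppressWarnings(fit_release_two_phase(
    gs$differential, pr, grid = radial_grid(64), profile_n = 0,
    epsilon_fixed = 0))
  expect_lt(abs(two$estimates$D_d_sg / fick$estimates$D_d_sg - 1), 0.01)
})

test_that("two-phase (D, k) are recovered with the bound fraction configured", {
  sp <- fixture_swelling("gg_lapo", "SGF")
  pr <- single_stage_protocol(lapo_form("b12"), "SGF", sp, D_d_sg = 2.87e-11,
                              k_bg_sg = 2.35e-4, epsilon = 0.8,
                              duration_min = 240)
  gs <- gen_release_series(pr, noise = noise_model(level = 0.02, seed = 7),
                           grid = radial_grid(64))
  fit <- fit_release_two_phase(gs$differential, pr, grid = radial_grid(64),
                               profile_n = 3, epsilon_fixed = 0.8)
  expect_lt(abs(fit$estimates$D_d_sg / 2.87e-11 - 1), 0.10)
  expect_lt(abs(fit$estimates$k_bg_sg / 2.35e-4 - 1), 0.10)
  # the profile report exists and has its minimum near the estimate
  expect_s3_class(fit$profile, "tbl_df")
  expect_named(fit$profile, c("k_bg_sg", "epsilon", "objective"))
  # Thiele modulus from the recovered pair lands in the reported SGF regime
  phi2 <- thiele_modulus(fit$estimates$k_bg_sg, 1.03e-3,
                         fit$estimates$D_d_sg)$phi2
  expect_equal(signif(phi2, 1), 9)
})

test_that("the joint three-parameter fit is flagged as weakly identified", {
  # with epsilon free the (D, k, eps) ridge admits near-equivalent fits;
  # the profile report must show a flat valley (small objective spread
  # along it compared with the off-valley walls)
  sp <- fixture_swelling("gg_lapo", "SGF")
  pr <- single_stage_protocol(lapo_form("b12"), "SGF", sp, D_d_sg = 2.87e-11,
                              k_bg_sg = 2.35e-4, epsilon = 0.8,
                              duration_min = 240)
  gs <- gen_release_series(pr, noise = noise_model(level = 0.02, seed = 7),
                           grid = radial_grid(64))
  fit <- suppressWarnings(fit_release_two_phase(
    gs$differential, pr, grid = radial_grid(64), profile_n = 4))
  pf <- fit$profile
  expect_gt(max(pf$objective) / (min(pf$objective) + 1e-12), 5)
})

test_that("objective is invariant to a common concentration scale", {
  sp <- fixture_swelling("gg", "SIF")
  f <- gg_form()
  st <- release_stage(medium("SIF"), sp, D_d_sg = 2.62e-10, V_res_mL = 100,
                      duration_min = 120, schedule = default_schedule(120))
  mk <- function(c0) release_protocol(st, f, drug_params(2.62e-10, c_d0 = c0))
  gs <- gen_release_series(mk(1), noise = noise_model(level = 0),
                           grid = radial_grid(64))
  scaled <- gs$differential
  scaled$data$value <- scaled$data$value * 5
  fit1 <- fit_release_fickian(gs$differential, mk(1), grid = radial_grid(64))
  fit5 <- fit_release_fickian(scaled, mk(5), grid = radial_grid(64))
  expect_equal(fit5$estimates$D_d_sg, fit1$estimates$D_d_sg,
               tolerance = 1e-6)
})

test_that("estimates respect the declared bounds", {
  f <- gg_form()
  sp <- fixture_swelling("gg", "SGF")
  ser <- gen_swelling_series(f, medium("SGF"), sp,
                             times_min = c(5, 15, 30, 60, 120),
                             noise = noise_model(level = 0),
                             grid = radial_grid(100))
  fit <- fit_swelling(ser, f, medium("SGF"), S_eq = 9.08,
                      bounds = c(1e-10, 1e-8))
  expect_gte(fit$estimates$D_s_sg, 1e-10)
  expect_lte(fit$estimates$D_s_sg, 1e-8)
})
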