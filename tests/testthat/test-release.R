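test_that("closed-form sphere series takes its frozen values", {
  # direct series evaluation at tau = 0.05 and the half-release time
  expect_equal(analytic_sphere_release(0.05), 0.60694, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(analytic_sphere_release(0.0305), 0.500, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(analytic_sphere_release(0, n_terms = 1e4), 0,
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_lt(attr(analytic_sphere_release(0.1, n_terms = 200),
                 "truncation_bound"), 0.005)
})

test_that("static perfect-sink release matches the analytic series", {
  f <- gg_form()
  D <- 4.26e-10
  R0 <- bead_radius_m(f)
  tD <- R0^2 / D
  pr <- single_stage_protocol(f, "SGF", fixture_swelling("gg", "SGF"),
                              D_d_sg = D, V_res_mL = 1e5,
                              duration_min = tD / 60,
                              schedule = withdrawal_schedule(numeric(0)))
  sol <- solve_release(pr, static_bead = TRUE, output_dt_min = tD / 60 / 120)
  tau <- sol$time_min * 60 / tD
  keep <- tau >= 0.001 & tau <= 1
  err <- sol$released_fraction[keep] - analytic_sphere_release(tau[keep])
  expect_lt(max(abs(err)), 1e-3)
})

test_that("withdrawal dilution is exact and composes", {
  expect_equal(apply_withdrawal(1.0, 100, 1), 0.99)
  expect_equal(apply_withdrawal(0, 100, 1), 0)
  expect_equal(apply_withdrawal(apply_withdrawal(1, 100, 1), 100, 1), 0.99^2)
  expect_error(apply_withdrawal(1, 1, 1), "V_w < V_res")
})

test_that("drug mass is conserved through withdrawals and swelling", {
  pr <- single_stage_protocol(gg_form("tph"), "SGF",
                              fixture_swelling("gg", "SGF"),
                              D_d_sg = 4.26e-10, duration_min = 120,
                              schedule = default_schedule(120))
  sol <- solve_release(pr, grid = fast_grid(), control = fast_control())
  expect_lt(sol$mass_residual, 1e-3)
  expect_true(all(sol$C_res >= 0))
  expect_true(all(diff(sol$released_fraction) >= -1e-8))
  expect_true(all(sol$released_fraction >= 0 & sol$released_fraction <= 1))
})

test_that("two-phase model with epsilon = 0 equals the Fickian model exactly", {
  sp <- fixture_swelling("gg_lapo", "SGF")
  pr_f <- single_stage_protocol(lapo_form("b12"), "SGF", sp,
                                D_d_sg = 2.87e-11, duration_min = 120,
                                schedule = default_schedule(120))
  pr_2p <- single_stage_protocol(lapo_form("b12"), "SGF", sp,
                                 D_d_sg = 2.87e-11, k_bg_sg = 2.35e-4,
                                 epsilon = 0, duration_min = 120,
                                 schedule = default_schedule(120))
  a <- solve_release(pr_f, grid = fast_grid(), control = fast_control())
  b <- solve_release(pr_2p, grid = fast_grid(), control = fast_control())
  # the bound phase stays exactly zero, so the equations coincide; only the
  # integrator's finite-difference Jacobian sees the extra rate term
  expect_equal(a$C_res, b$C_res, tolerance = 1e-4)
  expect_equal(max(abs(b$fields$cb)), 0)
  # and determinism: identical inputs give identical outputs
  a2 <- solve_release(pr_f, grid = fast_grid(), control = fast_control())
  expect_identical(a$C_res, a2$C_res)
})

test_that("large transfer rate drives the two-phase curve to the Fickian one", {
  sp <- fixture_swelling("gg_lapo", "SGF")
  mk <- function(k, eps) single_stage_protocol(
    lapo_form("b12"), "SGF", sp, D_d_sg = 2.87e-11, k_bg_sg = k,
    epsilon = eps, duration_min = 180, schedule = default_schedule(180))
  fick <- solve_release(mk(0, 0), grid = fast_grid(),
                        control = fast_control())
  dev <- sapply(c(3e-4, 3e-3, 3e-2, 3e-1), function(k) {
    s <- solve_release(mk(k, 1), grid = fast_grid(),
                       control = fast_control())
    max(abs(s$released_fraction - fick$released_fraction))
  })
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 0.02)
})

test_that("early-time release exponent separates the two transfer regimes", {
  # log-log slope of M_t/M_inf: > 1 (non-Fickian) for the transfer-limited
  # SGF parameters with everything initially bound; ~ 0.5 (Fickian) for the
  # diffusion-controlled SIF parameters
  # each slope is evaluated on the sampling schedule its assay would use
  slope_for <- function(med_name, D, k, sched) {
    sp <- fixture_swelling("gg_lapo", med_name)
    pr <- single_stage_protocol(lapo_form("b12"), med_name, sp, D_d_sg = D,
                                k_bg_sg = k, epsilon = 1,
                                duration_min = 240, V_res_mL = 100,
                                schedule = sched)
    sol <- solve_release(pr, grid = fast_grid(), control = fast_control())
    cv <- integral_release_curve(sol)
    cv <- cv[cv$time_min %in% sched$times_min, ]
    win <- cv$Mt_over_Minf > 0.05 & cv$Mt_over_Minf < 0.7
    stats::coef(stats::lm(log(Mt_over_Minf) ~ log(time_min),
                          data = cv[win, ]))[2]
  }
  n_sgf <- slope_for("SGF", 2.87e-11, 2.35e-4,
                     default_schedule(240)) # Phi^2 ~ 9
  n_sif <- slope_for("SIF", 5.33e-11, 4.12e-3,
                     withdrawal_schedule(seq(15, 240, 15))) # Phi^2 ~ 80
  expect_gt(n_sgf, 1)
  expect_lt(abs(n_sif - 0.5), 0.25)
})

test_that("released fractions are insensitive to the reservoir volume bound", {
  # perfect-sink recovery: 50 vs 175 mL curves differ by less than the
  # swollen-bead-to-reservoir volume ratio
  sp <- fixture_swelling("gg", "SGF")
  f <- gg_form("tph")
  run <- function(V) solve_release(
    single_stage_protocol(f, "SGF", sp, D_d_sg = 4.26e-10, V_res_mL = V,
                          duration_min = 120,
                          schedule = default_schedule(120)),
    grid = fast_grid(), control = fast_control())
  a <- run(50); b <- run(175)
  N <- beads_per_sample(15, f)
  V_beads_mL <- N * 4 / 3 * pi * max(a$front_radius_m)^3 * 1e6
  bound <- V_beads_mL / 50
  expect_lt(max(abs(a$released_fraction - b$released_fraction)), bound)
})

test_that("relative release outputs are invariant to the drug loading", {
  sp <- fixture_swelling("gg", "SGF")
  f <- gg_form()
  mk <- function(c0) {
    st <- release_stage(medium("SGF"), sp, D_d_sg = 4.26e-10, V_res_mL = 100,
                        duration_min = 60, schedule = default_schedule(60))
    release_protocol(st, f, drug_params(4.26e-10, c_d0 = c0))
  }
  a <- solve_release(mk(1), grid = fast_grid(), control = fast_control())
  b <- solve_release(mk(7.3), grid = fast_grid(), control = fast_control())
  expect_equal(a$released_fraction, b$released_fraction, tolerance = 1e-5)
  expect_equal(b$C_res / 7.3, a$C_res, tolerance = 1e-5)
})

test_that("integral release curve is a normalised non-decreasing ledger", {
  pr <- single_stage_protocol(gg_form("tph"), "SGF",
                              fixture_swelling("gg", "SGF"),
                              D_d_sg = 4.26e-10, duration_min = 240)
  sol <- solve_release(pr, grid = fast_grid(), control = fast_control())
  cv <- integral_release_curve(sol)
  expect_equal(cv$Mt_over_Minf[nrow(cv)], 1)
  expect_true(all(cv$Mt_over_Minf >= 0 & cv$Mt_over_Minf <= 1 + 1e-12))
  expect_true(all(diff(cv$Mt_over_Minf) >= -1e-9))
  # near-complete release: the ledger and the mass bookkeeping agree
  expect_gt(sol$released_fraction[length(sol$released_fraction)], 0.99)
  expect_equal(cv$Mt_over_Minf, sol$released_fraction /
                 sol$released_fraction[length(sol$released_fraction)],
               tolerance = 1e-6)
})

test_that("gastrointestinal staging carries bead state across the switch", {
  sol <- simulate_gi_fixture("tph", "gg", grid = fast_grid(),
                             control = fast_control())
  cv <- sol$curve
  # reservoir concentration resets to zero at the medium switch
  i_switch <- which(cv$event == "medium_switch")
  expect_length(i_switch, 1L)
  expect_equal(cv$C_res[i_switch], 0)
  # released fraction does not reset
  expect_true(all(diff(sol$released_fraction) >= -1e-8))
  # front radius is continuous at the switch and keeps growing toward the
  # larger SIF equilibrium
  expect_lt(abs(sol$front_radius_m[i_switch] /
                  sol$front_radius_m[i_switch - 1L] - 1), 1e-6)
  expect_gt(max(sol$front_radius_m), sol$front_radius_m[i_switch])
  expect_lt(sol$mass_residual, 1e-3)
})

test_that("equal-parameter gastrointestinal run equals a single-stage run", {
  # when both media share all parameters, the two-stage run with its reservoir
  # reset is the same bead trajectory as a single stage of the total duration
  f <- gg_form("tph")
  sp <- fixture_swelling("gg", "SGF")
  sol2 <- simulate_gi(
    f, drug_params(4.26e-10),
    swelling_by_medium = list(SGF = sp, SIF = sp),
    transport_by_medium = list(SGF = list(D_d_sg = 4.26e-10),
                               SIF = list(D_d_sg = 4.26e-10)),
    V_sgf_mL = 100, V_sif_mL = 100, grid = fast_grid(),
    control = fast_control())
  st <- release_stage(medium("SGF"), sp, D_d_sg = 4.26e-10, V_res_mL = 100,
                      duration_min = 240, schedule = default_schedule(120))
  sol1 <- solve_release(release_protocol(st, f, drug_params(4.26e-10)),
                        grid = fast_grid(), control = fast_control())
  # bead fields agree at the end despite the different reservoir histories
  # (the reservoir stays nearly perfect-sink in both runs)
  expect_equal(max(sol2$front_radius_m), max(sol1$front_radius_m),
               tolerance = 1e-6)
  expect_equal(released_at(sol2, 240), released_at(sol1, 240),
               tolerance = 0.01)
})
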