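# m^3 -> mL conversion for the bead/reservoir mass bookkeeping
M3_TO_ML <- 1e6

# Right-hand side of the coupled swelling + drug transport + reservoir system
# on the front-fixed grid (compiled; see src/rhs.cpp).
# State: phi (m), S, c_d (m), c_b (m), C_res; concentrations mg/mL, lengths m,
# time s. The free drug diffuses with D_d(phi) and is advected by the swelling
# velocity relative to the moving mesh (zero relative velocity at the surface,
# where the front moves with the swelling velocity); the bound phase is
# advected and transfers at k_bg(phi); the reservoir gains the surface efflux
# of all beads.
release_rhs <- function(t, y, p) {
  sp <- p$swelling
  list(release_rhs_cpp(y, p$geo, sp$D_s_sg, sp$beta, sp$phi_0, sp$phi_G,
                       sp$phi_eq, p$D_d_sg, p$k_bg_sg, p$N_beads, p$V_res,
                       as.integer(p$static_bead)))
}

#' Solve a swelling-coupled drug-release protocol
#'
#' Co-integrates the moving-boundary swelling problem with drug transport in
#' the bead and a finite, perfectly mixed reservoir. The free drug diffuses
#' with `D_d(phi) = D_d_sg * f(phi)` and is advected by the swelling velocity;
#' an optional bound phase (initial fraction `epsilon` of the loading) is
#' advected with the matrix and transfers to the free phase at rate
#' `k_bg(phi) = k_bg_sg * f(phi)`. The reservoir concentration obeys a
#' macroscopic balance over all beads; withdrawals are instantaneous dilution
#' events; at a medium switch the beads are drained (reservoir content set
#' aside as released) and transferred into fresh medium whose swelling and
#' transport parameters take over, the bead fields carrying across.
#'
#' @param protocol A [release_protocol()].
#' @param grid A [radial_grid()].
#' @param control A [solver_control()]; only the `"as_printed"` front law is
#'   supported here.
#' @param static_bead If `TRUE`, freezes the bead (no swelling, no glassy
#'   attenuation, no advection): the fixed-boundary constant-diffusivity limit
#'   used for verification against the closed-form sphere series.
#' @param output_dt_min Spacing of regular output times within each stage,
#'   minutes.
#' @return An object of class `release_solution`; see Details. Its `$curve`
#'   tibble holds (`time_min`, `C_res`, `event`, `released_fraction`,
#'   `Mt_over_Minf`); `$ledger` the withdrawal records; `$mass_residual` the
#'   worst relative drug-mass imbalance over the output times.
#' @export
solve_release <- function(protocol, grid = radial_grid(),
                          control = solver_control(), static_bead = FALSE,
                          output_dt_min = 2) {
  stopifnot(inherits(protocol, "release_protocol"))
  if (control$front_velocity != "as_printed")
    stop("the release solver supports only the `as_printed` front law",
         call. = FALSE)
  geo <- scheme_geometry(grid)
  m <- geo$m
  form <- protocol$formulation
  drug <- protocol$drug
  R0 <- bead_radius_m(form)
  N_beads <- beads_per_sample(protocol$sample_mass_mg, form)
  c_d0 <- drug$c_d0
  if (is.null(c_d0)) {
    c_d0 <- form$dry_density * form$drug_mass_fraction * 1000 # mg/mL
    if (c_d0 <= 0) c_d0 <- 1 # relative outputs are invariant to the loading
  }
  M0 <- N_beads * c_d0 * 4 / 3 * pi * R0^3 * M3_TO_ML # initial drug mass, mg

  sp1 <- protocol$stages[[1]]$swelling
  y <- c(if (static_bead) rep(sp1$phi_eq, m) else initial_phi(sp1, m),
         R0,
         rep((1 - drug$epsilon) * c_d0, m),
         rep(drug$epsilon * c_d0, m),
         0)

  rows <- list()
  ledger <- list()
  t_offset <- 0
  released_prev <- 0 # drug set aside at completed stages (drained reservoirs)
  W_cum <- 0

  push_row <- function(t_abs, y, stage_i, V_res, event) {
    phi <- y[1:m]; S <- y[m + 1L]
    cd <- y[(m + 2L):(2L * m + 1L)]; cb <- y[(2L * m + 2L):(3L * m + 1L)]
    C <- y[3L * m + 2L]
    bead_mass <- N_beads * 4 * pi * S^3 * sum(geo$w * (cd + cb)) * M3_TO_ML
    list(time_min = t_abs, stage = stage_i, C_res = C, event = event,
         V_res = V_res, W_cum = W_cum, released_prev = released_prev,
         bead_mass = bead_mass, S = S,
         phi = phi, cd = cd, cb = cb)
  }
  rows[[1]] <- push_row(0, y, 1L, protocol$stages[[1]]$V_res_mL, "start")

  for (stage_i in seq_along(protocol$stages)) {
    st <- protocol$stages[[stage_i]]
    p <- list(geo = geo, swelling = st$swelling, D_d_sg = st$D_d_sg,
              k_bg_sg = st$k_bg_sg, N_beads = N_beads, V_res = st$V_res_mL,
              static_bead = static_bead,
              front_velocity = control$front_velocity)
    if (drug$epsilon > 0 && st$k_bg_sg == 0)
      warning(sprintf(
        "stage %d: epsilon > 0 with k_bg_sg = 0; bound drug cannot desorb",
        stage_i), call. = FALSE)
    tw <- st$schedule$times_min
    seg_bounds <- sort(unique(c(0, tw[tw < st$duration_min], st$duration_min)))
    for (k in seq_len(length(seg_bounds) - 1L)) {
      t0 <- seg_bounds[k]; t1 <- seg_bounds[k + 1L]
      tt <- sort(unique(c(seq(t0, t1, by = output_dt_min), t1)))
      out <- deSolve::ode(y = y, times = tt * 60, func = release_rhs,
                          parms = p, method = control$method,
                          rtol = control$rtol, atol = control$atol)
      if (attr(out, "istate")[1L] < 0)
        stop(sprintf("release integrator failed in stage %d near t = %.3g min",
                     stage_i, max(out[, 1]) / 60), call. = FALSE)
      for (j in 2:nrow(out))
        rows[[length(rows) + 1L]] <- push_row(
          t_offset + out[j, 1] / 60, out[j, -1L], stage_i, st$V_res_mL, "")
      y <- out[nrow(out), -1L]
      # withdrawal event at t1 (unless t1 is the bare stage end)
      if (t1 %in% tw) {
        C_pre <- y[3L * m + 2L]
        removed <- st$schedule$volume_mL * C_pre
        W_cum <- W_cum + removed
        ledger[[length(ledger) + 1L]] <- list(
          stage = stage_i, t_w_min = t_offset + t1, C_w = C_pre,
          mass_removed_mg = removed)
        y[3L * m + 2L] <- apply_withdrawal(C_pre, st$V_res_mL,
                                           st$schedule$volume_mL)
        rows[[length(rows) + 1L]] <- push_row(
          t_offset + t1, y, stage_i, st$V_res_mL, "withdrawal")
      }
    }
    # stage end: drain the reservoir and (if another stage follows) transfer
    C_end <- y[3L * m + 2L]
    released_prev <- released_prev + st$V_res_mL * C_end
    if (stage_i < length(protocol$stages)) {
      y[3L * m + 2L] <- 0
      rows[[length(rows) + 1L]] <- push_row(
        t_offset + st$duration_min, y, stage_i + 1L,
        protocol$stages[[stage_i + 1L]]$V_res_mL, "medium_switch")
    }
    t_offset <- t_offset + st$duration_min
  }

  # assemble outputs
  time_min <- vapply(rows, `[[`, 0, "time_min")
  C_res <- vapply(rows, `[[`, 0, "C_res")
  event <- vapply(rows, `[[`, "", "event")
  stage <- vapply(rows, `[[`, 0L, "stage")
  V_res <- vapply(rows, `[[`, 0, "V_res")
  W_vec <- vapply(rows, `[[`, 0, "W_cum")
  prev_vec <- vapply(rows, `[[`, 0, "released_prev")
  bead_mass <- vapply(rows, `[[`, 0, "bead_mass")
  S_vec <- vapply(rows, `[[`, 0, "S")
  # at a completed stage the drained reservoir is inside released_prev and the
  # live term V_res * C_res must not double-count it
  outside <- prev_vec + V_res * C_res + W_vec
  released_fraction <- outside / M0
  total <- bead_mass + outside
  mass_residual <- max(abs(total - M0)) / M0
  Mt <- outside / outside[length(outside)]

  curve <- tibble::tibble(
    time_min = time_min, stage = stage, C_res = C_res, event = event,
    released_fraction = released_fraction, Mt_over_Minf = Mt)
  ledger_tb <- if (length(ledger)) {
    tibble::tibble(
      stage = vapply(ledger, `[[`, 0L, "stage"),
      t_w_min = vapply(ledger, `[[`, 0, "t_w_min"),
      C_w = vapply(ledger, `[[`, 0, "C_w"),
      mass_removed_mg = vapply(ledger, `[[`, 0, "mass_removed_mg"))
  } else {
    tibble::tibble(stage = integer(), t_w_min = numeric(), C_w = numeric(),
                   mass_removed_mg = numeric())
  }
  structure(
    list(curve = curve, ledger = ledger_tb,
         time_min = time_min, C_res = C_res,
         released_fraction = released_fraction,
         front_radius_m = S_vec,
         fields = list(
           phi = do.call(rbind, lapply(rows, `[[`, "phi")),
           cd = do.call(rbind, lapply(rows, `[[`, "cd")),
           cb = do.call(rbind, lapply(rows, `[[`, "cb"))),
         outside_mass_mg = outside, bead_mass_mg = bead_mass,
         initial_mass_mg = M0, c_d0 = c_d0, N_beads = N_beads,
         protocol = protocol, grid = grid, control = control,
         mass_residual = mass_residual, converged = TRUE),
    class = "release_solution"
  )
}

#' @export
print.release_solution <- function(x, ...) {
  n <- length(x$time_min)
  cat(sprintf(
    "<release_solution> %s, %d stage(s), t: 0..%.4g min\n  released fraction at end: %.4f\n  drug-mass residual: %.2e\n",
    x$protocol$formulation$name, length(x$protocol$stages),
    max(x$time_min), x$released_fraction[n], x$mass_residual))
  invisible(x)
}

#' Integral release curve (withdrawal-corrected cumulative release)
#'
#' Builds `M_t / M_inf` from the reservoir trace and the withdrawal ledger:
#' the numerator is the drug outside the beads at time `t` (live reservoir
#' content, withdrawn aliquots, and reservoirs drained at earlier medium
#' switches), the denominator its value at protocol end.
#'
#' @param sol A [solve_release()] result.
#' @return A tibble (`time_min`, `Mt_over_Minf`), non-decreasing, in `[0, 1]`.
#' @export
integral_release_curve <- function(sol) {
  stopifnot(inherits(sol, "release_solution"))
  end_mass <- sol$outside_mass_mg[length(sol$outside_mass_mg)]
  if (end_mass <= 0)
    stop("undefined integral release curve: no drug was released",
         call. = FALSE)
  tibble::tibble(time_min = sol$time_min,
                 Mt_over_Minf = sol$outside_mass_mg / end_mass)
}

#' Released fraction at a given time
#'
#' @param sol A [solve_release()] result.
#' @param t_min Time(s) in minutes.
#' @return Mass-based released fraction(s), interpolated between output rows.
#' @export
released_at <- function(sol, t_min) {
  approx(sol$time_min, sol$released_fraction, xout = t_min, ties = max)$y
}

#' Closed-form release from a sphere at constant surface concentration
#'
#' Exact series for Fickian release from a sphere of fixed radius into a
#' perfect sink: `M_t / M_inf = 1 - (6/pi^2) sum_n n^-2 exp(-n^2 pi^2 tau)`
#' with `tau = D t / R^2`. Serves as the verification oracle for the release
#' solver in its static, perfect-sink limit.
#'
#' @param tau Dimensionless time(s), >= 0.
#' @param n_terms Number of series terms (>= 1). The truncation error is below
#'   `(6/pi^2)/n_terms` uniformly in `tau` (attribute `truncation_bound`).
#' @return Release fraction(s) in `[0, 1]` with attribute `truncation_bound`.
#' @export
analytic_sphere_release <- function(tau, n_terms = 200) {
  if (any(tau < 0)) stop("`tau` must be >= 0", call. = FALSE)
  if (n_terms < 1) stop("`n_terms` must be >= 1", call. = FALSE)
  n <- seq_len(n_terms)
  out <- vapply(tau, function(tt)
    1 - 6 / pi^2 * sum(exp(-n^2 * pi^2 * tt) / n^2), 0)
  attr(out, "truncation_bound") <- 6 / pi^2 / n_terms
  out
}

#' Simulate the in-vitro gastrointestinal release protocol
#'
#' Two sequential stages: 120 min in 100 mL of simulated gastric fluid with
#' 1-mL withdrawals, then the beads are drained and transferred into 50 mL of
#' simulated intestinal fluid with 1-mL withdrawals every 15 min. Swelling and
#' drug-transport parameters are medium-specific; the bead fields (solvent
#' fraction, free and bound drug, front radius) carry across the switch and
#' the reservoir restarts at zero.
#'
#' @param formulation A [bead_formulation()].
#' @param drug A [drug_params()] (supplies `epsilon` and the loading).
#' @param swelling_by_medium Named list with elements `SGF` and `SIF`, each a
#'   [swelling_params()].
#' @param transport_by_medium Named list with elements `SGF` and `SIF`, each a
#'   list with `D_d_sg` and optionally `k_bg_sg` (1/s, default 0).
#' @param sample_mass_mg Bead sample mass, mg (default 15).
#' @param sgf_min,sif_min Stage durations, minutes (defaults 120 and 120).
#' @param V_sgf_mL,V_sif_mL Reservoir volumes (defaults 100 and 50).
#' @param sif_every_min SIF withdrawal period, minutes (default 15).
#' @param ... Passed on to [solve_release()] (`grid`, `control`, ...).
#' @return A `release_solution`.
#' @export
simulate_gi <- function(formulation, drug, swelling_by_medium,
                        transport_by_medium, sample_mass_mg = 15,
                        sgf_min = 120, sif_min = 120,
                        V_sgf_mL = 100, V_sif_mL = 50, sif_every_min = 15,
                        ...) {
  need <- c("SGF", "SIF")
  if (!all(need %in% names(swelling_by_medium)) ||
      !all(need %in% names(transport_by_medium)))
    stop("parameters for both SGF and SIF are required", call. = FALSE)
  tr <- lapply(transport_by_medium, function(x)
    modifyList(list(k_bg_sg = 0), as.list(x)))
  st1 <- release_stage(
    medium = medium("SGF"), swelling = swelling_by_medium$SGF,
    D_d_sg = tr$SGF$D_d_sg, k_bg_sg = tr$SGF$k_bg_sg,
    V_res_mL = V_sgf_mL, duration_min = sgf_min,
    schedule = default_schedule(sgf_min))
  st2 <- release_stage(
    medium = medium("SIF"), swelling = swelling_by_medium$SIF,
    D_d_sg = tr$SIF$D_d_sg, k_bg_sg = tr$SIF$k_bg_sg,
    V_res_mL = V_sif_mL, duration_min = sif_min,
    schedule = withdrawal_schedule(seq(sif_every_min, sif_min,
                                       by = sif_every_min), 1))
  solve_release(release_protocol(list(st1, st2), formulation, drug,
                                 sample_mass_mg), ...)
}
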