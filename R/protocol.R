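#' Withdrawal schedule
#'
#' Times at which an aliquot is withdrawn from the reservoir for assay and
#' replaced with fresh medium. Each withdrawal dilutes the reservoir by the
#' exact factor `(V_res - V_w) / V_res` (see [apply_withdrawal()]).
#'
#' @param times_min Strictly increasing withdrawal times, minutes.
#' @param volume_mL Withdrawn (and replaced) volume, mL. Default 1.
#' @return An object of class `withdrawal_schedule`.
#' @export
withdrawal_schedule <- function(times_min, volume_mL = 1) {
  if (length(times_min) && (is.unsorted(times_min, strictly = TRUE) ||
                            any(times_min <= 0)))
    stop("withdrawal times must be positive and strictly increasing",
         call. = FALSE)
  if (volume_mL <= 0) stop("`volume_mL` must be positive", call. = FALSE)
  structure(list(times_min = as.numeric(times_min), volume_mL = volume_mL),
            class = "withdrawal_schedule")
}

#' Default single-medium withdrawal schedule
#'
#' Withdrawals at 1, 5, 10, 15, 30, 45, 60, 90, 120, 150, 180, 210, 240 min
#' (1 mL), covering the 1-240 min assay window of the bench protocol.
#'
#' @param t_max_min Truncate the schedule at this time (default 240).
#' @return A [withdrawal_schedule()].
#' @export
default_schedule <- function(t_max_min = 240) {
  tt <- c(1, 5, 10, 15, 30, 45, 60, 90, 120, 150, 180, 210, 240)
  withdrawal_schedule(tt[tt <= t_max_min], 1)
}

#' One stage of a release protocol
#'
#' A stage is a period in a single medium: its swelling parameters, the drug
#' transport coefficients in that medium, the reservoir volume, the duration,
#' and the withdrawal schedule (stage-local times).
#'
#' @param medium A [medium()].
#' @param swelling A [swelling_params()] for this medium.
#' @param D_d_sg Drug diffusivity in the swollen gel for this medium, m^2/s.
#' @param k_bg_sg Bound-to-free transfer rate for this medium, 1/s.
#' @param V_res_mL Reservoir volume, mL.
#' @param duration_min Stage duration, minutes.
#' @param schedule A [withdrawal_schedule()]; times must not exceed
#'   `duration_min`.
#' @return An object of class `release_stage`.
#' @export
release_stage <- function(medium, swelling, D_d_sg, k_bg_sg = 0,
                          V_res_mL, duration_min,
                          schedule = default_schedule(duration_min)) {
  stopifnot(inherits(medium, "medium"), inherits(swelling, "swelling_params"))
  if (V_res_mL <= 0 || duration_min <= 0)
    stop("`V_res_mL` and `duration_min` must be positive", call. = FALSE)
  if (D_d_sg <= 0) stop("`D_d_sg` must be positive", call. = FALSE)
  if (k_bg_sg < 0) stop("`k_bg_sg` must be >= 0", call. = FALSE)
  if (length(schedule$times_min) && max(schedule$times_min) > duration_min)
    stop("withdrawal times exceed the stage duration", call. = FALSE)
  if (schedule$volume_mL >= V_res_mL)
    stop("withdrawal volume must be smaller than the reservoir volume",
         call. = FALSE)
  structure(
    list(medium = medium, swelling = swelling, D_d_sg = D_d_sg,
         k_bg_sg = k_bg_sg, V_res_mL = V_res_mL, duration_min = duration_min,
         schedule = schedule),
    class = "release_stage"
  )
}

#' Release protocol: bead sample plus ordered medium stages
#'
#' @param stages A list of [release_stage()] objects (at least one), run in
#'   order; at each medium switch the beads are drained (the old reservoir is
#'   set aside as released drug) and transferred into fresh medium.
#' @param formulation A [bead_formulation()].
#' @param drug A [drug_params()]; its `D_d_sg`/`k_bg_sg` act as defaults that
#'   the per-stage values override.
#' @param sample_mass_mg Mass of dry drug-loaded beads, mg. Default 15.
#' @return An object of class `release_protocol`.
#' @export
release_protocol <- function(stages, formulation, drug, sample_mass_mg = 15) {
  if (inherits(stages, "release_stage")) stages <- list(stages)
  stopifnot(length(stages) >= 1,
            all(vapply(stages, inherits, TRUE, "release_stage")),
            inherits(formulation, "bead_formulation"),
            inherits(drug, "drug_params"))
  if (sample_mass_mg <= 0)
    stop("`sample_mass_mg` must be positive", call. = FALSE)
  structure(
    list(stages = stages, formulation = formulation, drug = drug,
         sample_mass_mg = sample_mass_mg),
    class = "release_protocol"
  )
}

#' @export
print.release_protocol <- function(x, ...) {
  cat(sprintf("<release_protocol> %s, %.3g mg beads, %d stage(s)\n",
              x$formulation$name, x$sample_mass_mg, length(x$stages)))
  for (s in x$stages)
    cat(sprintf("  %s: %g mL, %g min, %d withdrawal(s) of %g mL\n",
                s$medium$name, s$V_res_mL, s$duration_min,
                length(s$schedule$times_min), s$schedule$volume_mL))
  invisible(x)
}

#' Reservoir concentration after one withdrawal
#'
#' Withdrawing `V_w` of perfectly mixed solution and replacing it with fresh
#' medium drops the reservoir concentration by the exact factor
#' `(V_res - V_w) / V_res`. The removed drug mass `V_w * C_res` belongs to the
#' cumulative-withdrawn ledger.
#'
#' @param C_res Pre-withdrawal concentration, mg/mL.
#' @param V_res Reservoir volume, mL.
#' @param V_w Withdrawn volume, mL; must satisfy `0 < V_w < V_res`.
#' @return Post-withdrawal concentration, mg/mL.
#' @export
apply_withdrawal <- function(C_res, V_res, V_w) {
  if (V_w <= 0 || V_w >= V_res)
    stop("invalid protocol: need 0 < V_w < V_res", call. = FALSE)
  C_res * (V_res - V_w) / V_res
}
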