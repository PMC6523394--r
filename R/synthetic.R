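#' Measurement-noise model for synthetic experiments
#'
#' Emulates the statistical structure of the bench measurements: each time
#' point is measured in `replicates` independent replicates (triplicate by
#' default) whose mean and SD are reported. Noise is Gaussian, either
#' additive (fixed SD in data units) or relative (SD proportional to the
#' value); draws are truncated at zero.
#'
#' @param kind `"relative_gaussian"` or `"additive_gaussian"`.
#' @param level Relative SD (fraction) or additive SD (data units).
#' @param seed Integer seed; every generator call is deterministic given it.
#' @param replicates Number of replicates per time point (>= 1, default 3).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("relative_gaussian", "additive_gaussian"),
                        level = 0.02, seed = 1L, replicates = 3L) {
  kind <- match.arg(kind)
  if (level < 0) stop("`level` must be >= 0", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(list(kind = kind, level = level, seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "noise_model")
}

# replicate draws for a vector of true values; rows = replicates
draw_replicates <- function(truth, noise) {
  k <- noise$replicates
  sdv <- switch(noise$kind,
                relative_gaussian = abs(truth) * noise$level,
                additive_gaussian = rep(noise$level, length(truth)))
  mat <- matrix(rnorm(k * length(truth), mean = rep(truth, each = k),
                      sd = rep(sdv, each = k)),
                nrow = k)
  pmax(mat, 0)
}

#' Experimental-series container
#'
#' A validated time series of observations (swelling degrees, withdrawal
#' concentrations, or an integral release curve) with optional per-point SD
#' and free-form metadata.
#'
#' @param kind One of `"swelling_degree"`, `"differential_release"`,
#'   `"integral_release"`.
#' @param times_min Strictly increasing observation times, minutes.
#' @param values Observed values (dimensionless or mg/mL).
#' @param sd Optional per-point SD, same units; must be >= 0.
#' @param metadata Named list (formulation, medium, protocol reference, ...).
#' @return An object of class `experimental_series` wrapping a tibble
#'   (`$data`) with columns `time_min`, `value`, `sd`.
#' @export
experimental_series <- function(kind, times_min, values, sd = NULL,
                                metadata = list()) {
  kind <- match.arg(kind, c("swelling_degree", "differential_release",
                            "integral_release"))
  if (length(times_min) != length(values))
    stop("`times_min` and `values` lengths differ", call. = FALSE)
  if (is.unsorted(times_min, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (!is.null(sd) && any(sd < 0))
    stop("`sd` must be >= 0", call. = FALSE)
  structure(
    list(kind = kind,
         data = tibble::tibble(
           time_min = as.numeric(times_min), value = as.numeric(values),
           sd = if (is.null(sd)) NA_real_ else as.numeric(sd)),
         metadata = metadata),
    class = "experimental_series")
}

#' @export
print.experimental_series <- function(x, ...) {
  cat(sprintf("<experimental_series> %s, %d points, t in [%.3g, %.3g] min\n",
              x$kind, nrow(x$data), min(x$data$time_min), max(x$data$time_min)))
  print(x$data, n = 5)
  invisible(x)
}

#' Generate a synthetic swelling-degree series
#'
#' Runs the forward swelling model and reports triplicate-style means and SDs
#' at the requested sampling times, mirroring the bench protocol (repeated
#' weighings up to 24 h).
#'
#' @param formulation A [bead_formulation()].
#' @param med A [medium()].
#' @param params A [swelling_params()] (ground truth).
#' @param times_min Sampling times, minutes. Default: the bench-style
#'   schedule 5, 10, ..., 30, 45, 60, 90, 120, 240, 480, 1440 min.
#' @param noise A [noise_model()]; default 3% relative, triplicate.
#' @param grid A [radial_grid()].
#' @return An `experimental_series` of kind `"swelling_degree"`.
#' @export
gen_swelling_series <- function(formulation, med, params,
                                times_min = c(5, 10, 15, 20, 25, 30, 45, 60,
                                              90, 120, 240, 480, 1440),
                                noise = noise_model(level = 0.03),
                                grid = radial_grid()) {
  sol <- solve_swelling(formulation, med, params,
                        t_end_s = max(times_min) * 60,
                        times = times_min * 60, grid = grid)
  truth <- approx(sol$time_s, sol$swelling_degree, xout = times_min * 60)$y
  set.seed(noise$seed)
  if (noise$level > 0) {
    reps <- draw_replicates(truth, noise)
    vals <- colMeans(reps)
    sds <- apply(reps, 2, sd)
  } else {
    vals <- truth
    sds <- rep(0, length(truth))
  }
  experimental_series(
    "swelling_degree", times_min, vals, sds,
    metadata = list(formulation = formulation$name, medium = med$name,
                    truth_D_s_sg = params$D_s_sg, noise = unclass(noise)))
}

#' Generate synthetic release series (differential and integral)
#'
#' Runs the forward release model for a protocol, samples the withdrawal
#' concentrations, applies replicate noise to each sampled value, and builds
#' the paired integral release curve from the noisy withdrawals by the
#' withdrawal-corrected cumulative ledger.
#'
#' @param protocol A [release_protocol()].
#' @param noise A [noise_model()]; default 2% relative, triplicate.
#' @param grid A [radial_grid()].
#' @param ... Passed to [solve_release()].
#' @return A list with elements `differential` and `integral` (both
#'   `experimental_series`) and `solution` (the noiseless truth).
#' @export
gen_release_series <- function(protocol, noise = noise_model(level = 0.02),
                               grid = radial_grid(), ...) {
  sol <- solve_release(protocol, grid = grid, ...)
  led <- sol$ledger
  if (nrow(led) == 0)
    stop("protocol has no withdrawals to sample", call. = FALSE)
  set.seed(noise$seed)
  if (noise$level > 0) {
    reps <- draw_replicates(led$C_w, noise)
    vals <- colMeans(reps)
    sds <- apply(reps, 2, sd)
  } else {
    vals <- led$C_w
    sds <- rep(0, nrow(led))
  }
  meta <- list(formulation = protocol$formulation$name,
               stages = length(protocol$stages), noise = unclass(noise))
  diff_series <- experimental_series("differential_release", led$t_w_min,
                                     vals, sds, metadata = meta)
  # integral curve assembled from the noisy withdrawals: at each withdrawal
  # time, outside mass = V_res * C(t) + sum of earlier withdrawn aliquots
  # (+ reservoirs drained at earlier stage switches, estimated from the last
  # sampled concentration of the stage)
  V_res <- vapply(seq_len(nrow(led)), function(i)
    protocol$stages[[led$stage[i]]]$V_res_mL, 0)
  V_w <- vapply(seq_len(nrow(led)), function(i)
    protocol$stages[[led$stage[i]]]$schedule$volume_mL, 0)
  withdrawn <- cumsum(V_w * vals)
  drained <- numeric(nrow(led))
  for (s in seq_len(length(protocol$stages) - 1L)) {
    in_stage <- which(led$stage == s)
    if (!length(in_stage)) next
    last_i <- in_stage[length(in_stage)]
    C_post <- vals[last_i] * (V_res[last_i] - V_w[last_i]) / V_res[last_i]
    drained[led$stage > s] <- drained[led$stage > s] + C_post * V_res[last_i]
  }
  outside <- drained + V_res * vals + c(0, head(withdrawn, -1))
  integ <- outside / outside[length(outside)]
  int_series <- experimental_series("integral_release", led$t_w_min, integ,
                                    metadata = meta)
  list(differential = diff_series, integral = int_series, solution = sol)
}
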