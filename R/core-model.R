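#' Bead formulation: dry geometry and density
#'
#' Describes one bead formulation as it enters the transport models: the
#' freeze-dried (dry) diameter fixes the initial radius `R0`, the dry density
#' `rho_b` converts sample masses to bead counts and swelling degrees to
#' volume fractions, and `drug_mass_fraction` sets the initial drug loading of
#' the dry matrix.
#'
#' @param name Label for the formulation (e.g. `"GG/Ca 0.3%"`).
#' @param dry_diameter_mm Freeze-dried bead diameter in mm; must be positive.
#' @param dry_density Dry bead density `rho_b` in g/cm^3 (0, 1.2).
#' @param fresh_diameter_mm Optional fresh (pre-drying) diameter in mm.
#' @param drug_mass_fraction Fraction of the dry-bead mass that is drug,
#'   in `[0, 1)`. Defaults to 0 (unloaded beads).
#'
#' @return An object of class `bead_formulation`.
#' @export
bead_formulation <- function(name, dry_diameter_mm, dry_density,
                             fresh_diameter_mm = NA_real_,
                             drug_mass_fraction = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(dry_diameter_mm) || dry_diameter_mm <= 0)
    stop("`dry_diameter_mm` must be a positive number", call. = FALSE)
  if (!is.finite(dry_density) || dry_density <= 0 || dry_density >= 1.2)
    stop("`dry_density` must lie in (0, 1.2) g/cm^3", call. = FALSE)
  if (drug_mass_fraction < 0 || drug_mass_fraction >= 1)
    stop("`drug_mass_fraction` must lie in [0, 1)", call. = FALSE)
  structure(
    list(
      name = name,
      dry_diameter_mm = dry_diameter_mm,
      fresh_diameter_mm = fresh_diameter_mm,
      dry_density = dry_density,
      drug_mass_fraction = drug_mass_fraction
    ),
    class = "bead_formulation"
  )
}

#' @export
print.bead_formulation <- function(x, ...) {
  cat(sprintf(
    "<bead_formulation> %s\n  dry diameter: %.3g mm (R0 = %.3g mm)\n  dry density: %.3g g/cm^3\n  drug mass fraction: %.3g\n",
    x$name, x$dry_diameter_mm, x$dry_diameter_mm / 2, x$dry_density,
    x$drug_mass_fraction
  ))
  invisible(x)
}

#' Initial (dry) bead radius in metres
#'
#' Half the freeze-dried diameter; swelling and release experiments start from
#' freeze-dried beads.
#'
#' @param formulation A [bead_formulation()].
#' @return Radius in metres.
#' @export
bead_radius_m <- function(formulation) {
  formulation$dry_diameter_mm / 2 * 1e-3
}

#' Release/swelling medium
#'
#' @param name Medium label, conventionally `"SGF"` (simulated gastric fluid,
#'   HCl 0.1 M) or `"SIF"` (simulated intestinal fluid, phosphate buffer
#'   pH 7.4).
#' @param solvent_density Solvent density `rho_s` in g/cm^3. Both media are
#'   dilute aqueous solutions; default 1.0.
#' @return An object of class `medium`.
#' @export
medium <- function(name, solvent_density = 1.0) {
  if (!is.finite(solvent_density) || solvent_density <= 0)
    stop("`solvent_density` must be positive", call. = FALSE)
  structure(list(name = name, solvent_density = solvent_density),
            class = "medium")
}

#' Solvent-transport parameter set
#'
#' Parameters of the diffuse-interface swelling model. The solvent diffusivity
#' is `D_s(phi) = D_s_sg * f(phi)` with `f` the glassy-core attenuation of
#' [diffusivity_factor()]: `f = 1` in the rubbery gel (`phi >= phi_G`) and an
#' exponential decay, rate `beta`, in the glassy core. `phi_0 < phi_G < phi_eq`
#' are the solvent volume fractions in the dry bead, at the swelling threshold,
#' and at equilibrium.
#'
#' @param D_s_sg Solvent diffusivity in the swollen gel, m^2/s.
#' @param phi_eq Equilibrium solvent volume fraction, usually obtained from the
#'   measured equilibrium swelling degree via [phi_eq_from_swelling_degree()].
#' @param beta Dimensionless decay rate of the diffusivity in the glassy core.
#'   Default 2, appropriate for highly porous freeze-dried beads; large values
#'   (~8) recover sharp-interface, non-porous behaviour.
#' @param phi_G Swelling-threshold volume fraction. Default `0.1 * phi_eq`,
#'   reflecting the ease of re-hydration of freeze-dried beads.
#' @param phi_0 Residual solvent volume fraction of the dry bead. Default 0.01.
#' @return An object of class `swelling_params`.
#' @export
swelling_params <- function(D_s_sg, phi_eq, beta = 2,
                            phi_G = 0.1 * phi_eq, phi_0 = 0.01) {
  if (!is.finite(D_s_sg) || D_s_sg <= 0)
    stop("`D_s_sg` must be positive", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (!(phi_0 > 0 && phi_0 < phi_G && phi_G < phi_eq && phi_eq < 1))
    stop("require 0 < phi_0 < phi_G < phi_eq < 1", call. = FALSE)
  structure(
    list(D_s_sg = D_s_sg, beta = beta, phi_0 = phi_0, phi_G = phi_G,
         phi_eq = phi_eq),
    class = "swelling_params"
  )
}

#' Drug-transport parameter set
#'
#' `D_d_sg` is the drug diffusivity in the swollen gel; the local diffusivity
#' is attenuated in the glassy core by the same factor `f(phi)` as the solvent.
#' `epsilon` is the fraction of drug initially bound to the polymer/clay
#' complex and `k_bg_sg` the linear bound-to-free transfer rate in the swollen
#' gel (also attenuated by `f(phi)` locally). `epsilon = 0` selects the purely
#' Fickian, non-interacting model.
#'
#' @param D_d_sg Drug diffusivity in the swollen gel, m^2/s.
#' @param epsilon Initially bound drug fraction in `[0, 1]`. Default 0.
#' @param k_bg_sg Bound-to-free transfer rate in the swollen gel, 1/s.
#' @param c_d0 Initial drug concentration in the dry bead, mg/cm^3. `NULL`
#'   means "derive from the formulation" (`rho_b * drug_mass_fraction`); all
#'   relative release outputs are invariant to it in this linear model.
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(D_d_sg, epsilon = 0, k_bg_sg = 0, c_d0 = NULL) {
  if (!is.finite(D_d_sg) || D_d_sg <= 0)
    stop("`D_d_sg` must be positive", call. = FALSE)
  if (epsilon < 0 || epsilon > 1)
    stop("`epsilon` must lie in [0, 1]", call. = FALSE)
  if (k_bg_sg < 0) stop("`k_bg_sg` must be >= 0", call. = FALSE)
  if (!is.null(c_d0) && c_d0 < 0) stop("`c_d0` must be >= 0", call. = FALSE)
  if (epsilon > 0 && k_bg_sg == 0)
    warning("epsilon > 0 with k_bg_sg = 0: bound drug is permanently entrapped",
            call. = FALSE)
  structure(
    list(D_d_sg = D_d_sg, epsilon = epsilon, k_bg_sg = k_bg_sg, c_d0 = c_d0),
    class = "drug_params"
  )
}

#' Equilibrium solvent volume fraction from the swelling degree
#'
#' Converts a measured equilibrium swelling degree `S_eq` (g absorbed solvent
#' per g dry bead) into the equilibrium solvent *weight* fraction
#' `x_eq = 1 - 1/(1 + S_eq)` and thence, by volume additivity, into the
#' equilibrium solvent *volume* fraction
#' `phi_eq = (x_eq/rho_s) / ((1 - x_eq)/rho_b + x_eq/rho_s)`.
#'
#' @param S_eq Equilibrium swelling degree (>= 0), dimensionless.
#' @param rho_b Dry bead density, g/cm^3.
#' @param rho_s Solvent density, g/cm^3. Default 1.
#' @return A tibble with columns `S_eq`, `x_eq`, `phi_eq`.
#' @export
phi_eq_from_swelling_degree <- function(S_eq, rho_b, rho_s = 1.0) {
  if (any(!is.finite(c(rho_b, rho_s))) || rho_b <= 0 || rho_s <= 0)
    stop("densities must be positive", call. = FALSE)
  if (any(S_eq < 0)) stop("`S_eq` must be >= 0", call. = FALSE)
  x_eq <- 1 - 1 / (1 + S_eq)
  phi_eq <- (x_eq / rho_s) / ((1 - x_eq) / rho_b + x_eq / rho_s)
  tibble::tibble(S_eq = S_eq, x_eq = x_eq, phi_eq = phi_eq)
}

#' Swelling degree implied by an equilibrium volume fraction
#'
#' Inverse of [phi_eq_from_swelling_degree()].
#'
#' @inheritParams phi_eq_from_swelling_degree
#' @param phi_eq Equilibrium solvent volume fraction in `[0, 1)`.
#' @return Swelling degree(s), dimensionless.
#' @export
swelling_degree_from_phi_eq <- function(phi_eq, rho_b, rho_s = 1.0) {
  if (any(phi_eq < 0 | phi_eq >= 1))
    stop("`phi_eq` must lie in [0, 1)", call. = FALSE)
  # invert the volume-additivity relation for x_eq, then S = x/(1-x)
  x_eq <- (phi_eq * rho_s) / ((1 - phi_eq) * rho_b + phi_eq * rho_s)
  x_eq / (1 - x_eq)
}

#' Glassy-core diffusivity attenuation factor
#'
#' The diffuse-interface model replaces the sharp glassy-rubbery front with a
#' smooth attenuation of the transport coefficients:
#' `f(phi) = 1` for `phi >= phi_G`, and
#' `f(phi) = exp(-beta * (phi - phi_G) / (phi_0 - phi_G))` for `phi < phi_G`,
#' continuous at `phi_G`. For `phi < phi_0` (numerically possible during
#' transients) the factor is clamped at `f(phi_0) = exp(-beta)`.
#'
#' @param phi Solvent volume fraction(s) in `[0, 1]`.
#' @param params A [swelling_params()] object (supplies `beta`, `phi_0`,
#'   `phi_G`).
#' @return Dimensionless factor(s) in `[exp(-beta), 1]`.
#' @export
diffusivity_factor <- function(phi, params) {
  if (params$phi_0 == params$phi_G)
    stop("degenerate parameters: phi_0 == phi_G", call. = FALSE)
  phic <- pmax(phi, params$phi_0)
  ifelse(
    phic >= params$phi_G, 1,
    exp(-params$beta * (phic - params$phi_G) / (params$phi_0 - params$phi_G))
  )
}

#' Thiele modulus of the two-phase release model
#'
#' Compares the drug diffusion time `t_D = R0^2 / D_d_sg` with the
#' bound-to-free transfer time `t_bg = 1 / k_bg_sg`:
#' `Phi^2 = t_D / t_bg = k_bg_sg * R0^2 / D_d_sg`. Large `Phi^2` means
#' diffusion controls the release (Fickian); `Phi^2` of order 10 or less
#' signals transfer-limited, non-Fickian release.
#'
#' @param k_bg_sg Transfer rate, 1/s (0 allowed: `t_bg = Inf`, `Phi^2 = 0`).
#' @param R0_m Initial bead radius, m.
#' @param D_d_sg Drug diffusivity in the swollen gel, m^2/s.
#' @return A tibble with columns `phi2`, `t_D_s`, `t_bg_s`.
#' @export
thiele_modulus <- function(k_bg_sg, R0_m, D_d_sg) {
  if (any(R0_m <= 0) || any(D_d_sg <= 0))
    stop("`R0_m` and `D_d_sg` must be positive", call. = FALSE)
  if (any(k_bg_sg < 0)) stop("`k_bg_sg` must be >= 0", call. = FALSE)
  t_D <- R0_m^2 / D_d_sg
  t_bg <- ifelse(k_bg_sg > 0, 1 / k_bg_sg, Inf)
  tibble::tibble(phi2 = k_bg_sg * R0_m^2 / D_d_sg, t_D_s = t_D, t_bg_s = t_bg)
}

#' Swelling degree from wet and dry weights
#'
#' `S = (w_swollen - w_dry) / w_dry`. Early-time blotting noise can make the
#' wet weight fall below the dry weight; such values are returned as negative
#' with a warning rather than rejected.
#'
#' @param w_swollen Swollen-bead weight(s), g.
#' @param w_dry Dry-bead weight(s), g; must be positive.
#' @return Swelling degree(s), dimensionless.
#' @export
swelling_degree_from_weights <- function(w_swollen, w_dry) {
  if (any(w_dry <= 0)) stop("`w_dry` must be positive", call. = FALSE)
  if (any(w_swollen < w_dry))
    warning("some swollen weights fall below the dry weight (blotting noise?)",
            call. = FALSE)
  (w_swollen - w_dry) / w_dry
}

#' Drug entrapment efficiency
#'
#' Percentage of the theoretically loaded drug actually retained in the beads.
#'
#' @param actual Measured drug content, mg.
#' @param theoretical Theoretical drug content from the recipe, mg (> 0).
#' @return Entrapment efficiency in percent.
#' @export
entrapment_efficiency <- function(actual, theoretical) {
  if (any(theoretical <= 0)) stop("`theoretical` must be positive", call. = FALSE)
  100 * actual / theoretical
}

#' Number of beads in a weighed sample
#'
#' Converts a sample mass into an equivalent bead count, treating the
#' population as identical spheres of the formulation's dry radius and density.
#' Fractional counts are allowed (continuum convention of the reservoir mass
#' balance).
#'
#' @param sample_mass_mg Sample mass, mg.
#' @param formulation A [bead_formulation()].
#' @return Bead count (possibly fractional).
#' @export
beads_per_sample <- function(sample_mass_mg, formulation) {
  if (any(sample_mass_mg <= 0))
    stop("`sample_mass_mg` must be positive", call. = FALSE)
  R0_cm <- formulation$dry_diameter_mm / 2 / 10
  bead_mass_mg <- formulation$dry_density * 4 / 3 * pi * R0_cm^3 * 1000
  sample_mass_mg / bead_mass_mg
}

#' Equilibrium-to-initial diameter ratio
#'
#' Evaluates the uniform-equilibrium limit of the swelling-degree integral:
#' a bead holding `S_eq` grams of solvent per gram of dry matrix at uniform
#' volume fraction `phi_eq` has swollen radius
#' `S_inf / R0 = (S_eq * rho_b / (rho_s * phi_eq))^(1/3)`.
#'
#' @inheritParams phi_eq_from_swelling_degree
#' @param phi_eq Equilibrium solvent volume fraction.
#' @return Dimensionless diameter (= radius) ratio.
#' @export
equilibrium_diameter_ratio <- function(S_eq, rho_b, rho_s, phi_eq) {
  if (any(c(S_eq, rho_b, rho_s, phi_eq) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  (S_eq * rho_b / (rho_s * phi_eq))^(1 / 3)
}
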