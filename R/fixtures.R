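#' Reference parameter registry for the characterised bead formulations
#'
#' Assembles the published characterisation of the two bead formulations
#' (gellan-gum/calcium with and without laponite, both at 0.3% CaCl2) in the
#' two dissolution media: bead geometry and dry density, equilibrium swelling
#' degrees and fitted solvent diffusivities, drug diffusivities for
#' theophylline (TPH) and vitamin B12, and the bound-to-free transfer rates of
#' B12 in the laponite beads. Every entry carries a `source` string describing
#' the measurement it came from.
#'
#' Formulation keys are `"gg"` (GG/Ca 0.3%) and `"gg_lapo"` (GG/LAPO/Ca
#' 0.3%); media are `"SGF"` and `"SIF"`; drugs are `"tph"` and `"b12"`.
#'
#' @return A nested list with elements `formulations`, `swelling` (per
#'   formulation and medium: `S_eq`, `D_s_sg`), `drugs` (per drug,
#'   formulation, medium: `D_d_sg`, `k_bg_sg`, `epsilon`,
#'   `entrapment_pct`), each value annotated with a `source` string.
#' @export
bead_fixtures <- function() {
  list(
    formulations = list(
      gg = list(
        name = "GG/Ca 0.3%", dry_diameter_mm = 1.63, fresh_diameter_mm = 2.41,
        dry_density = 0.109,
        source = "measured bead diameters (caliper) and freeze-dried density"),
      gg_lapo = list(
        name = "GG/LAPO/Ca 0.3%", dry_diameter_mm = 2.06,
        fresh_diameter_mm = 2.79, dry_density = 0.0926,
        source = "measured bead diameters (caliper) and freeze-dried density")
    ),
    swelling = list(
      gg = list(
        SGF = list(S_eq = 9.08, D_s_sg = 8.8e-10,
                   source = "24-h equilibrium swelling degree and fitted solvent diffusivity, SGF"),
        SIF = list(S_eq = 45.80, D_s_sg = 1.5e-9,
                   source = "24-h equilibrium swelling degree and fitted solvent diffusivity, SIF")),
      gg_lapo = list(
        SGF = list(S_eq = 9.14, D_s_sg = 6.5e-10,
                   source = "24-h equilibrium swelling degree and fitted solvent diffusivity, SGF"),
        SIF = list(S_eq = 20.60, D_s_sg = 1.1e-9,
                   source = "24-h equilibrium swelling degree and fitted solvent diffusivity, SIF"))
    ),
    drugs = list(
      tph = list(
        gg = list(
          SGF = list(D_d_sg = 4.26e-10, k_bg_sg = 0, epsilon = 0,
                     source = "fitted theophylline gel diffusivity, SGF (Fickian)"),
          SIF = list(D_d_sg = 2.62e-10, k_bg_sg = 0, epsilon = 0,
                     source = "fitted theophylline gel diffusivity, SIF (Fickian)"),
          entrapment_pct = 20.26),
        gg_lapo = list(
          SGF = list(D_d_sg = 2.73e-11, k_bg_sg = 0, epsilon = 0,
                     source = "fitted theophylline gel diffusivity, SGF (Fickian)"),
          SIF = list(D_d_sg = 1.43e-10, k_bg_sg = 0, epsilon = 0,
                     source = "fitted theophylline gel diffusivity, SIF (Fickian)"),
          entrapment_pct = 36.49)),
      b12 = list(
        gg = list(
          SGF = list(D_d_sg = 1.53e-10, k_bg_sg = 0, epsilon = 0,
                     source = "fitted vitamin B12 gel diffusivity, SGF (Fickian)"),
          SIF = list(D_d_sg = 1.85e-10, k_bg_sg = 0, epsilon = 0,
                     source = "fitted vitamin B12 gel diffusivity, SIF (Fickian)"),
          entrapment_pct = 53.62),
        gg_lapo = list(
          SGF = list(D_d_sg = 2.87e-11, k_bg_sg = 2.35e-4, epsilon = 1,
                     source = "fitted vitamin B12 gel diffusivity and bound-to-free transfer rate, SGF (two-phase)"),
          SIF = list(D_d_sg = 5.33e-11, k_bg_sg = 4.12e-3, epsilon = 1,
                     source = "fitted vitamin B12 gel diffusivity and bound-to-free transfer rate, SIF (two-phase)"),
          entrapment_pct = 61.26))
    )
  )
}

# theoretical drug mass fraction of the dry bead from the loading recipe:
# 0.0146 g drug in 0.165 g GG (+ 0.11 g laponite for the clay beads)
recipe_drug_fraction <- function(formulation_key) {
  solids <- switch(formulation_key,
                   gg = 0.165 + 0.0146,
                   gg_lapo = 0.165 + 0.11 + 0.0146,
                   stop("unknown formulation key", call. = FALSE))
  0.0146 / solids
}

#' Bead formulation from the fixture registry
#'
#' @param key `"gg"` or `"gg_lapo"`.
#' @param drug Optional drug key (`"tph"` or `"b12"`); when given, the
#'   formulation's `drug_mass_fraction` is set from the loading recipe times
#'   the measured entrapment efficiency.
#' @return A [bead_formulation()].
#' @export
fixture_formulation <- function(key = c("gg", "gg_lapo"), drug = NULL) {
  key <- match.arg(key)
  fx <- bead_fixtures()$formulations[[key]]
  w_d <- 0
  if (!is.null(drug)) {
    drug <- match.arg(drug, c("tph", "b12"))
    ee <- bead_fixtures()$drugs[[drug]][[key]]$entrapment_pct / 100
    w_d <- recipe_drug_fraction(key) * ee
  }
  bead_formulation(fx$name, fx$dry_diameter_mm, fx$dry_density,
                   fresh_diameter_mm = fx$fresh_diameter_mm,
                   drug_mass_fraction = w_d)
}

#' Swelling parameters from the fixture registry
#'
#' Builds a [swelling_params()] for a formulation/medium pair with the fitted
#' solvent diffusivity, `beta = 2`, `phi_G = 0.1 * phi_eq`, and `phi_eq`
#' derived from the measured equilibrium swelling degree.
#'
#' @param key `"gg"` or `"gg_lapo"`.
#' @param medium_name `"SGF"` or `"SIF"`.
#' @param rho_s Solvent density, g/cm^3.
#' @return A [swelling_params()].
#' @export
fixture_swelling <- function(key = c("gg", "gg_lapo"),
                             medium_name = c("SGF", "SIF"), rho_s = 1.0) {
  key <- match.arg(key)
  medium_name <- match.arg(medium_name)
  fx <- bead_fixtures()
  sw <- fx$swelling[[key]][[medium_name]]
  rho_b <- fx$formulations[[key]]$dry_density
  phi_eq <- phi_eq_from_swelling_degree(sw$S_eq, rho_b, rho_s)$phi_eq
  swelling_params(D_s_sg = sw$D_s_sg, phi_eq = phi_eq)
}

#' Drug transport parameters from the fixture registry
#'
#' For vitamin B12 in the laponite beads the initially bound fraction was
#' never published; the registry defaults to `epsilon = 1` (all drug initially
#' bound to the clay-polymer complex), which reproduces the strongly
#' non-Fickian gastric-release signature; override via `epsilon`.
#'
#' @param drug `"tph"` or `"b12"`.
#' @param key `"gg"` or `"gg_lapo"`.
#' @param medium_name `"SGF"` or `"SIF"`.
#' @param epsilon Optional override of the initially bound fraction.
#' @return A [drug_params()].
#' @export
fixture_drug <- function(drug = c("tph", "b12"), key = c("gg", "gg_lapo"),
                         medium_name = c("SGF", "SIF"), epsilon = NULL) {
  drug <- match.arg(drug); key <- match.arg(key)
  medium_name <- match.arg(medium_name)
  d <- bead_fixtures()$drugs[[drug]][[key]][[medium_name]]
  drug_params(D_d_sg = d$D_d_sg,
              epsilon = if (is.null(epsilon)) d$epsilon else epsilon,
              k_bg_sg = d$k_bg_sg)
}

#' Gastrointestinal simulation from fixture parameters
#'
#' Convenience wrapper: runs [simulate_gi()] for a drug/formulation pair with
#' all parameters taken from the fixture registry.
#'
#' @inheritParams fixture_drug
#' @param ... Passed to [simulate_gi()].
#' @return A `release_solution`.
#' @export
simulate_gi_fixture <- function(drug = c("tph", "b12"),
                                key = c("gg", "gg_lapo"), epsilon = NULL,
                                ...) {
  drug <- match.arg(drug); key <- match.arg(key)
  sgf <- fixture_drug(drug, key, "SGF", epsilon = epsilon)
  sif <- fixture_drug(drug, key, "SIF", epsilon = epsilon)
  simulate_gi(
    formulation = fixture_formulation(key, drug = drug),
    drug = sgf,
    swelling_by_medium = list(SGF = fixture_swelling(key, "SGF"),
                              SIF = fixture_swelling(key, "SIF")),
    transport_by_medium = list(
      SGF = list(D_d_sg = sgf$D_d_sg, k_bg_sg = sgf$k_bg_sg),
      SIF = list(D_d_sg = sif$D_d_sg, k_bg_sg = sif$k_bg_sg)),
    ...)
}
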