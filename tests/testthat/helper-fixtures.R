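# shared shorthand for the reference formulations and parameter sets
gg_form <- function(drug = NULL) fixture_formulation("gg", drug = drug)
lapo_form <- function(drug = NULL) fixture_formulation("gg_lapo", drug = drug)

# a small, fast grid for solver-heavy tests (convergence is checked separately)
fast_grid <- function(n = 64) radial_grid(n)

fast_control <- function() solver_control(rtol = 1e-5, atol = 1e-8)

# single-stage release protocol used across release/fitting tests
single_stage_protocol <- function(formulation, med_name, swelling, D_d_sg,
                                  k_bg_sg = 0, epsilon = 0, V_res_mL = 100,
                                  duration_min = 240,
                                  schedule = default_schedule(duration_min)) {
  st <- release_stage(medium(med_name), swelling, D_d_sg = D_d_sg,
                      k_bg_sg = k_bg_sg, V_res_mL = V_res_mL,
                      duration_min = duration_min, schedule = schedule)
  release_protocol(st, formulation,
                   drug_params(D_d_sg, epsilon = epsilon, k_bg_sg = k_bg_sg))
}
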