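# Reference parameter sets (fitted kinetic constants, uM / mU/mg) reused
# across tests.
ref_cd38_nad <- function() michaelis_params(Km = 10.4, Vmax = 6649)
ref_fl_nad <- function() dual_inhibition_params(Km = 30.3, Vmax = 22.4, Kia = 324)
ref_fl_nadp <- function() dual_inhibition_params(Km = 66.9, Vmax = 14.3, Kis = 132)
ref_samtir_nad <- function() catalytic_inhibition_params(Km = 69.5, Vmax = 723)
ref_samtir_nadp <- function() catalytic_inhibition_params(Km = 83.5, Vmax = 582, Kis = 151)

# Per-NMN-level fitted constants (effector level uM -> Kia / Kis columns).
ref_nmn_levels <- function() c(5, 10, 20, 50)
ref_kia_vs_nmn <- function() c(385.1, 414.9, 787.0, 1201.7)
ref_kis_nadp_vs_nmn <- function() c(52.7, 57.4, 60.0, 48.0)

default_S_grid <- function(n = 12, lo = 15, hi = 4000) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# Exact linear progress curve: constant consumption rate split into fixed
# product fractions; useful where OLS slopes must be exact.
linear_time_course <- function(times = seq(0, 30, by = 5), S0 = 250,
                               rate = 1, f_hyd = 0.9, f_cyc = 0.1,
                               protein = 3) {
  consumed <- rate * times
  time_course(
    tibble::tibble(time_min = times,
                   substrate_uM = S0 - consumed,
                   adpr_uM = f_hyd * consumed,
                   cyclic_uM = f_cyc * consumed,
                   base_uM = consumed),
    protein_conc_ug_ml = protein, S0 = S0)
}
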