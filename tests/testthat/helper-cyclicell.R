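# Shared small parameter sets: default physics, but cheap quadrature and
# ensembles so unit tests stay fast. Acceptance-scale runs live in
# test-acceptance.R only.
sfp_default <- sf_params()
cp_default <- with_suspension_energy(sfp_default, cell_params())
load_static <- cyclic_load(eps_amp = 0, f = 0)
load_1hz <- cyclic_load(eps_amp = 0.1, f = 1, r = 0)

# neutral stress-fiber parameters with no reservoir offset, for closed-form
# energy checks
sfp_plain <- function(...) sf_params(mu_ref = 0, ...)

small_ensemble <- function(load, n = 3000, seed = 42, n_time = 16) {
  homeostatic_ensemble(load, sfp_default, cp_default, n_samples = n,
                       seed = seed, n_time = n_time)
}
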