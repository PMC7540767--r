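# Shared fixtures: the baseline parameter set and quiet wrappers around the
# integrator (lsoda chatters on stderr during stiff boom-bust transients).

base_params <- function(...) eco_params(...)

quiet_integrate <- function(...) suppressWarnings(integrate_ecosystem(...))
quiet_evolve <- function(...) suppressWarnings(evolve_open_ecosystem(...))
quiet_batch <- function(...) suppressWarnings(batch_culture(...))

# closed-form total density when a single perfectly defended strain
# coexists with its phage: delta / (eta (beta - 1))
single_strain_density <- function(pr) pr$delta / (pr$eta * (pr$beta - 1))

# a small deterministic community used across tests
demo_strains <- function() {
  strain_params(gamma = c(0.9, 0.6, 0.75), omega = c(0.05, 0.001, 0.01))
}
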