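# Shared fixtures: the published typical values used as simulation truth.

ref_params <- function(sigma = 0.243) {
  structural_params(ka = 1.89, cl_f = 0.853, v_f = 5.1, c0 = 10,
                    sigma = sigma)
}

# a rich single-group design for noise-free identifiability checks
rich_design <- function(n = 1) {
  study_design(groups = list(list(
    label = "R",
    times = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 24, 30, 36,
              42, 48, 60, 72),
    n = n)),
    weights = rep(320, n), dose_per_kg = 2)
}

# the 9-rat design with every group's schedule enriched by hourly samples
# over 0-12 h (used to show precision improves with denser sampling)
enriched_design <- function() {
  d <- rat_study_design()
  groups <- lapply(d$groups, function(g) {
    g$times <- sort(unique(c(g$times, 0:12)))
    g
  })
  study_design(groups, weights = d$weights, dose_per_kg = d$dose_per_kg)
}
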