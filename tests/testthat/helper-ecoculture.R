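# Shared fixtures: short-horizon parameter sets keep the default test run
# fast while exercising the same dynamics as the full-length experiments.

std_params <- function(n_steps = 20000L, seed = 1L, ...) {
  do.call(eco_params, utils::modifyList(list(n_steps = n_steps, seed = seed),
                                        list(...)))
}

# deterministic (sigma = 0) variant of the standard rates
det_params <- function(n_steps = 5000L, ...) {
  std_params(n_steps = n_steps, sigma = 0, ...)
}
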