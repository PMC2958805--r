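# shared fixtures: the default fitted partition and constants
part <- default_partition()
st <- stoichiometry()

# partition with constant f_cho (degenerate quadratic), built through the
# public fitting surface
constant_partition <- function(value) {
  fit_partition(data.frame(intensity = c(0.3, 0.6, 0.9), f_cho = value))
}

# raw quadratic without clamping, reconstructed from the public coefficients
partition_eval_for_test <- function(fit, i) {
  co <- fit$coefficients
  co[["intercept"]] + co[["linear"]] * i + co[["quadratic"]] * i^2
}
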