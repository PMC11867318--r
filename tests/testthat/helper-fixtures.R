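# Small shared fixtures, built once per test run.

# a compact virtual population used by regimen-level tests
.tiny_cache <- new.env()

get_tiny_pop <- function() {
  if (is.null(.tiny_cache$pop))
    .tiny_cache$pop <- generate_population(pool_size = 400, n = 60, seed = 42)
  .tiny_cache$pop
}

get_tiny_dose <- function() {
  if (is.null(.tiny_cache$dose))
    .tiny_cache$dose <- calibrate_dose(get_tiny_pop())
  .tiny_cache$dose
}

# a hand-built bistable resident community: strong mutual inhibition
# between nAB and Li, oLB excluded by both
bistable_draw <- c(
  kgrow_nAB = 0.5, kgrow_Li = 0.5, kgrow_oLB = 0.3,
  alpha_nAB_to_nAB = -0.02, alpha_Li_to_Li = -0.02, alpha_oLB_to_oLB = -0.02,
  alpha_Li_to_nAB = -0.03, alpha_oLB_to_nAB = 0,
  alpha_nAB_to_Li = -0.03, alpha_oLB_to_Li = 0,
  alpha_nAB_to_oLB = -0.05, alpha_Li_to_oLB = -0.05
)

# mono-stable nAB-dominant resident community
monostable_draw <- c(
  kgrow_nAB = 0.8, kgrow_Li = 0.3, kgrow_oLB = 0.3,
  alpha_nAB_to_nAB = -0.01, alpha_Li_to_Li = -0.02, alpha_oLB_to_oLB = -0.02,
  alpha_Li_to_nAB = -0.001, alpha_oLB_to_nAB = -0.001,
  alpha_nAB_to_Li = -0.05, alpha_oLB_to_Li = 0,
  alpha_nAB_to_oLB = -0.05, alpha_Li_to_oLB = 0
)
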