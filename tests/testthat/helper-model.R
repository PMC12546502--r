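# Shared fixtures: the calibrated base case is deterministic, so compute it
# once per test run.
.fixture <- new.env(parent = emptyenv())

calibrated_base <- function() {
  if (is.null(.fixture$base)) .fixture$base <- base_case_parameters()
  .fixture$base
}

base_bc <- function() {
  if (is.null(.fixture$bc)) .fixture$bc <- build_business_case(calibrated_base())
  .fixture$bc
}

# explicit per-year discount loop, the independent oracle for all NPV sums
loop_discount <- function(values, rate, shift) {
  out <- numeric(length(values))
  for (t in seq_along(values)) out[t] <- values[t] / (1 + rate)^(t - 1 + shift)
  out
}
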