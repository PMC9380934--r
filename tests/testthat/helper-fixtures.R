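# Shared fixtures: parameter sets are cheap to build but reused everywhere.
.dp_cache <- new.env(parent = emptyenv())
dp <- function() {
  if (is.null(.dp_cache$p)) .dp_cache$p <- aba_parameters()
  .dp_cache$p
}

# a degenerate parameter set with every distribution collapsed (se = 0)
fixed_params <- function() {
  p <- dp()
  p$tbl$se <- 0
  p$tbl$dist <- "fixed"
  p
}

# zero-mortality variant: life table with qx identically zero
no_mortality <- function(p = dp()) {
  p$settings$life_table <- data.frame(age = 0:110, qx = 0)
  p
}
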