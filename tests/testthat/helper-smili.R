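# shared fixtures: small, fast configurations built in code

short_full <- function(years = 2, ...) {
  smili_preset("full_model", years = years, ...)
}

short_reference <- function(years = 2, ...) {
  smili_preset("reference", years = years, ...)
}

# a reference-state sandbox for testing the governance state operations
fresh_state <- function(cfg = short_reference(), seed = 1) {
  set.seed(seed)
  init_state(cfg)
}
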