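# shared fixtures: tiny analytic models for the integration engine and a
# cached coupled model for the slower scenario checks

decay_model <- function() {
  model_spec("x", function(t, y, p) -y, default_init = 1, name = "decay")
}

harmonic_model <- function() {
  model_spec(c("x", "y"),
             function(t, y, p) c(y[2], -y[1]),
             default_init = c(1, 0), name = "harmonic")
}

# van-der-Pol-type stiff relaxation test system
vdp_model <- function(mu = 1000) {
  model_spec(c("x", "y"),
             function(t, y, p) c(y[2], mu * ((1 - y[1]^2) * y[2]) - y[1]),
             default_init = c(2, 0), name = "vdp")
}

# session-cached expensive objects (reference period etc.)
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}
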