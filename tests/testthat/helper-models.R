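# Random valid biphasic models for property-style tests.  Gaussian widths
# are kept small enough relative to the peak location that the inversion
# at |p| = 99 stays at positive doses (no clipping).
random_model <- function(kind = sample(c("gaussian", "loggaussian"), 1)) {
  c0 <- runif(1, 0, 5)
  d0 <- c0 + runif(1, 10, 100)
  f0 <- runif(1, 0.3, 3)
  if (kind == "gaussian") {
    e0 <- runif(1, 5, 50)
    b0 <- runif(1, 0.02, 0.3) * e0 / 3.1
  } else {
    e0 <- runif(1, 0.5, 20)
    b0 <- runif(1, 0.1, 1.2)
  }
  biphasic_model(kind, b = b0, c = c0, d = d0, e = e0, f = f0)
}

# Two moderately different loggaussian components plus their 1:1
# constant-ratio spec, reused across mixture/interaction tests.
component_pair <- function() {
  a <- biphasic_model("loggaussian", b = 0.8, c = 1, d = 80, e = 2.5,
                      f = 0.8)
  b <- biphasic_model("loggaussian", b = 0.8, c = 1.5, d = 50, e = 6,
                      f = 0.9)
  list(fits = list(A = a, B = b),
       spec = constant_ratio_design(list(A = a, B = b)))
}
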