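# Shared condition helper: every package error carries class "riskcast_error"
# plus a specific subclass tests and callers can switch on.
stop_riskcast <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "riskcast_error"), ...)
}

# Gumbel (type-I extreme value) distribution, maximum convention.
qgumbel <- function(p, location = 0, scale = 1) {
  location - scale * log(-log(p))
}

pgumbel <- function(q, location = 0, scale = 1) {
  exp(-exp(-(q - location) / scale))
}

rgumbel <- function(n, location = 0, scale = 1) {
  qgumbel(stats::runif(n), location, scale)
}

# Euler-Mascheroni constant, used by the moment estimator of the Gumbel fit.
EULER_GAMMA <- 0.5772156649015329
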