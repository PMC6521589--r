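# Robust exponential convolution kernels shared by all closed-form solutions.
#
# conv_exp(l, k, t)  = int_0^t exp(-l*u) exp(-k*(t-u)) du
#                    = (exp(-l*t) - exp(-k*t)) / (k - l)        [symmetric in l, k]
# conv3(a, b, c, t)  = int_0^t conv_exp(a, b, u) exp(-c*(t-u)) du
#
# Both are evaluated with expm1-based branches so that near-degenerate rate
# pairs do not suffer catastrophic cancellation; exactly degenerate pairs
# (difference below .rate_tol, in 1/min) switch to the t*exp(-k*t) limiting
# forms.

.rate_tol <- 1e-9

conv_exp <- function(l, k, t) {
  d <- k - l
  if (abs(d) < .rate_tol) {
    return(t * exp(-0.5 * (k + l) * t))
  }
  x <- d * t
  out <- numeric(length(t))
  small <- abs(x) < 1e-4
  if (any(small)) {
    out[small] <- exp(-k * t[small]) * expm1(x[small]) / d
  }
  if (any(!small)) {
    ts <- t[!small]
    out[!small] <- (exp(-l * ts) - exp(-k * ts)) / d
  }
  out
}

# derivative in t, using the convolution ODE y' = exp(-l*t) - k*y
dconv_exp <- function(l, k, t) {
  exp(-l * t) - k * conv_exp(l, k, t)
}

conv3 <- function(a, b, c, t) {
  if (abs(b - a) >= .rate_tol) {
    return((conv_exp(a, c, t) - conv_exp(b, c, t)) / (b - a))
  }
  # b ~ a: int_0^t u exp(-a*u) exp(-c*(t-u)) du
  r <- 0.5 * (a + b)
  x <- c - r
  if (abs(x) < .rate_tol) {
    return(0.5 * t^2 * exp(-r * t))
  }
  out <- numeric(length(t))
  u <- x * t
  small <- abs(u) < 1e-3
  if (any(small)) {
    us <- u[small]
    out[small] <- 0.5 * t[small]^2 * exp(-r * t[small]) *
      (1 - us / 3 + us^2 / 12)
  }
  if (any(!small)) {
    ts <- t[!small]
    out[!small] <- ts * exp(-r * ts) / x - exp(-c * ts) * expm1(x * ts) / x^2
  }
  out
}

# derivative in t: conv3' = conv_exp(a, b, t) - c * conv3(a, b, c, t)
dconv3 <- function(a, b, c, t) {
  conv_exp(a, b, t) - c * conv3(a, b, c, t)
}
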