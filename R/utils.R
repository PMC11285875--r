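# Internal helpers shared across modules.

# Draw from a normal truncated at zero (left truncation only), via the
# inverse-CDF on the retained tail; exact and vectorised.
rtruncnorm0 <- function(n, mean, sd) {
  if (any(sd < 0)) abort("standard deviations must be >= 0", class = "coralcarb_domain_error")
  out <- numeric(n)
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  fixed <- sd == 0
  out[fixed] <- mean[fixed]
  if (any(!fixed)) {
    lo <- pnorm(0, mean[!fixed], sd[!fixed])
    u <- runif(sum(!fixed), lo, 1)
    out[!fixed] <- qnorm(u, mean[!fixed], sd[!fixed])
  }
  out
}

# Multiplicative lognormal noise with unit mean and given coefficient of
# variation; cv = 0 returns exactly 1.
rlnorm_cv <- function(n, cv) {
  if (cv < 0) abort("cv must be >= 0", class = "coralcarb_domain_error")
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

stop_domain <- function(msg) abort(msg, class = "coralcarb_domain_error")
stop_numeric <- function(msg) abort(msg, class = "coralcarb_numeric_error")
stop_usage <- function(msg) abort(msg, class = "coralcarb_usage_error")

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_domain(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}
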