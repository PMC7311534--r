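# independent brute-force oracles, deliberately different code paths from the
# package implementation

# forward-Euler integration of the compartment ODE on a fine grid (default
# 1 ms), with the inputs interpolated piecewise-linearly and causally
euler_oracle <- function(p, inputs, grid = inputs$time_s, dt = 0.001) {
  r <- params_to_rates(p)
  tau_a <- attr(inputs, "tau_a") %||% 0
  tau_p <- attr(inputs, "tau_p") %||% 0
  tf <- seq(grid[1], grid[length(grid)], by = dt)
  interp <- function(v, tau) {
    stats::approx(c(inputs$time_s[1] - 1e9, inputs$time_s[1] - 1e-9, inputs$time_s),
                  c(0, 0, v), xout = tf - tau, rule = 2)$y
  }
  u <- r$k1a * interp(inputs$aif, tau_a) + r$k1p * interp(inputs$pvif, tau_p)
  n <- length(tf)
  C <- numeric(n)
  # explicit Euler as a linear recursion
  C[-1] <- stats::filter(dt * u[-n], 1 - r$k2 * dt, method = "recursive")
  stats::approx(tf, C, xout = grid)$y
}

# naive double-loop exhaustive inner-product search
naive_match_oracle <- function(curve, dict) {
  cn <- curve / sqrt(sum(curve^2))
  n <- ncol(dict$entries)
  best_j <- 1L
  best_ip <- -Inf
  for (j in seq_len(n)) {
    ip <- sum(cn * dict$entries[, j])
    if (ip > best_ip) {   # strict: first column wins ties
      best_ip <- ip
      best_j <- j
    }
  }
  list(column = best_j, af = dict$index$af[best_j],
       mtt = dict$index$mtt[best_j], inner_product = best_ip)
}
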