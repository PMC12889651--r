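# Independent oracles, written without reference to the package internals.

# Plain double-loop Gaussian summation of a hill list at points s, time t.
oracle_bias <- function(hl, s, t = Inf) {
  out <- numeric(length(s))
  for (j in seq_along(s)) {
    acc <- 0
    for (k in seq_len(nrow(hl))) {
      if (hl$time[k] <= t) {
        acc <- acc + hl$height[k] *
          exp(-(s[j] - hl$center[k])^2 / (2 * hl$sigma[k]^2))
      }
    }
    out[j] <- acc
  }
  out
}

# High-resolution Simpson-rule evaluation of the reversible-work estimator:
# (1/beta) log( int exp(g/(g-1) * beta V) / int exp(1/(g-1) * beta V) ).
# Direct exponentials (test biases are small enough not to overflow).
oracle_ct_simpson <- function(hl, s_min, s_max, n, gamma, beta = 1, t = Inf) {
  if (n %% 2 == 0) n <- n + 1  # Simpson needs an odd node count
  s <- seq(s_min, s_max, length.out = n)
  h <- (s_max - s_min) / (n - 1)
  w <- rep(c(2, 4), length.out = n)
  w[c(1, n)] <- 1
  V <- oracle_bias(hl, s, t)
  num <- sum(w * exp(gamma / (gamma - 1) * beta * V)) * h / 3
  den <- sum(w * exp(1 / (gamma - 1) * beta * V)) * h / 3
  log(num / den) / beta
}

# Direct Truchon-Bailly evaluation from the ranks of the actives.
oracle_bedroc <- function(active_ranks, N, alpha) {
  n <- length(active_ranks)
  Ra <- n / N
  sum_term <- sum(exp(-alpha * active_ranks / N))
  rie <- (sum_term / n) / ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

# Random hill list with modest heights, for property tests.
random_hills <- function(n, seed, s_range = c(0, 5), h_max = 0.5) {
  set.seed(seed)
  hills(
    time = sort(runif(n, 0, 100)),
    center = runif(n, s_range[1], s_range[2]),
    sigma = runif(n, 0.05, 0.5),
    height = runif(n, 0, h_max)
  )
}

# Random score/label table.
random_table <- function(N, n_binders, seed) {
  set.seed(seed)
  lab <- rep("nonbinder", N)
  lab[sample.int(N, n_binders)] <- "binder"
  screen_table(sprintf("L%03d", seq_len(N)), rnorm(N), lab)
}
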