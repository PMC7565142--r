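# Independent oracles used across the suite. Each recomputes a quantity
# by a different route than the package (scalar loops, enumeration, grid
# search) so agreement is informative.

# Bliss-deviation score by scalar double loop, with Eq.-style branching
# written out case by case.
oracle_combo_score <- function(y_a, y_b, y_ab) {
  total <- 0
  n <- 0
  for (p in seq_along(y_a)) {
    for (q in seq_along(y_b)) {
      ya <- y_a[p]; yb <- y_b[q]
      if (ya <= 0 || yb <= 0) {
        z <- if (ya < yb) ya else yb
      } else {
        ya_t <- if (ya > 100) 100 else ya
        yb_t <- if (yb > 100) 100 else yb
        z <- ya_t * yb_t / 100
      }
      if (!is.na(y_ab[p, q])) {
        total <- total + (y_ab[p, q] - z)
        n <- n + 1
      }
    }
  }
  total / n
}

# Logistic regression by hand-written iteratively reweighted least
# squares; returns the two-sided Wald p for the single slope.
oracle_logistic_wald <- function(x, y, max_iter = 200) {
  X <- cbind(1, x)
  beta <- rep(0, 2)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtWX <- t(X) %*% (X * w)
    beta_new <- drop(solve(XtWX, t(X) %*% (w * z)))
    if (max(abs(beta_new - beta)) < 1e-13) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  covmat <- solve(t(X) %*% (X * (mu * (1 - mu))))
  z_stat <- beta[2] / sqrt(covmat[2, 2])
  2 * stats::pnorm(-abs(z_stat))
}

# Penalized-likelihood p for a single-predictor logistic model by nested
# grid search over (intercept, slope); Jeffreys penalty written directly.
oracle_firth_p <- function(x, y) {
  pen_ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    X <- cbind(1, x)
    info <- t(X) %*% (X * w)
    sum(y * eta - log(1 + exp(eta))) + 0.5 * log(det(info))
  }
  pen_ll_null <- function(b0) {
    mu <- 1 / (1 + exp(-b0))
    w <- mu * (1 - mu)
    sum(y * b0 - log(1 + exp(b0))) + 0.5 * log(length(y) * w)
  }
  refine <- function(f, centers, half, rounds) {
    for (r in seq_len(rounds)) {
      grid <- expand.grid(lapply(seq_along(centers), function(i) {
        seq(centers[i] - half, centers[i] + half, length.out = 21)
      }))
      vals <- apply(grid, 1, function(g) do.call(f, unname(as.list(g))))
      centers <- as.numeric(grid[which.max(vals), ])
      half <- half / 8
    }
    list(par = centers, value = max(vals))
  }
  full <- refine(pen_ll, c(0, 0), 10, 5)
  null <- refine(function(b0) pen_ll_null(b0), 0, 10, 5)
  stat <- 2 * (full$value - null$value)
  stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Observed significant counts by explicit loop.
oracle_fdr_observed <- function(p_values, threshold) {
  n <- 0
  for (p in p_values) {
    if (!is.na(p) && p <= threshold) n <- n + 1
  }
  n
}

# Shared fixtures (built once per test run).
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(name, seed = 1) {
  key <- paste(name, seed, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- make_fixture(name, seed = seed)
  }
  fixture_cache[[key]]
}
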