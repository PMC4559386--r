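# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force grids, normal equations, and a
# literal step-down loop.

fit_delays <- c(3, 6, 9, 12)

# dense 1-D grid minimizer for the hyperbolic SSE
grid_min_hyperbolic <- function(ips, step = 1e-3, k_max = 10) {
  ks <- seq(0, k_max, by = step)
  sse <- vapply(ks, function(k) sum((ips - 1 / (1 + k * fit_delays))^2),
                numeric(1))
  i <- which.min(sse)
  list(k = ks[i], sse = sse[i])
}

# dense 2-D grid minimizer for the quasi-hyperbolic SSE (vectorized)
grid_min_quasihyperbolic <- function(ips, n_grid = 1001) {
  b <- seq(0, 1, length.out = n_grid)
  d <- seq(0, 1, length.out = n_grid)
  sse <- matrix(0, n_grid, n_grid)
  for (j in seq_along(fit_delays)) {
    pred <- outer(b, d^fit_delays[j])
    sse <- sse + (ips[j] - pred)^2
  }
  i <- arrayInd(which.min(sse), dim(sse))
  list(beta = b[i[1]], delta = d[i[2]], sse = min(sse))
}

# OLS coefficients straight from the normal equations
ols_normal_equations <- function(x, y) {
  xm <- cbind(1, as.matrix(x))
  drop(solve(t(xm) %*% xm, t(xm) %*% y))
}

# literal Holm step-down: compare ordered p-values to alpha/(m - rank + 1),
# stop at the first failure
holm_stepdown <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (r in seq_len(m)) {
    if (p[ord[r]] <= alpha / (m - r + 1)) reject[ord[r]] <- TRUE else break
  }
  reject
}

# fill a design with a deterministic threshold responder: sooner iff the
# sooner amount is at least `threshold` euros
threshold_responder <- function(design, threshold) {
  design$choice <- ifelse(design$sooner_amount >= threshold,
                          "sooner", "later")
  design
}
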