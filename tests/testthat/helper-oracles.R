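# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: model matrices come from stats::model.matrix,
# regressions from explicit normal equations or closed forms, and the
# diffusion-fit oracle is a grid search plus Nelder-Mead refinement of the
# linearized objective.

# Least-squares coefficients of the full interaction model via the normal
# equations on observation-level data.
oracle_factorial_coef <- function(obs) {
  X <- stats::model.matrix(~ x1 * x2 * x3, data = obs)
  beta <- solve(t(X) %*% X, t(X) %*% obs$response)
  # map model.matrix names (x1, x1:x2, ...) onto the package's term names
  nm <- gsub(":", "", rownames(beta))
  nm[nm == "(Intercept)"] <- "b0"
  stats::setNames(drop(beta), nm)
}

# Sequential sums of squares from orthogonal contrast sums:
# SS = (contrast sum)^2 / N_obs for each effect column.
oracle_contrast_ss <- function(obs) {
  X <- stats::model.matrix(~ x1 * x2 * x3, data = obs)[, -1, drop = FALSE]
  ss <- apply(X, 2, function(col) sum(col * obs$response)^2 / nrow(X))
  stats::setNames(ss, gsub(":", "", colnames(X)))
}

# Grid search + refinement minimizing the linearized diffusion objective
# sum over points of (log(1 - q) - (log(1 - b) - k t))^2 in (b, k).
oracle_diffusion_grid <- function(time, q) {
  obj <- function(p) {
    if (p[1] < 0 || p[1] >= 1 || p[2] <= 0) return(Inf)
    sum((log(1 - q) - (log(1 - p[1]) - p[2] * time))^2)
  }
  grid <- expand.grid(b = seq(0.01, 0.95, by = 0.01),
                      k = exp(seq(log(1e-4), log(1e-1), length.out = 120)))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  list(b = fit$par[1], k = fit$par[2])
}

# Simple-regression slope/intercept in closed form.
oracle_simple_regression <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  list(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Pearson correlation from raw sums (covariance formula).
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

r_gas <- 8.314
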