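#' Solve the outcome-model intercept for a target marginal prevalence
#'
#' In the data-generating logistic model
#' \eqn{\mathrm{logit}\, P(Y=1 \mid \eta) = \beta_0 + \beta_1 \eta} with
#' \eqn{\eta \sim \mathrm{Bernoulli}(p_\eta)}, finds the intercept
#' \eqn{\beta_0} giving marginal prevalence
#' \eqn{(1-p_\eta)\,\mathrm{expit}(\beta_0) +
#'   p_\eta\,\mathrm{expit}(\beta_0+\beta_1) = } `prevalence_target`.
#' The map is strictly increasing in \eqn{\beta_0}, so monotone root
#' finding converges; the residual is driven below 1e-10.
#'
#' @param prevalence_target marginal `P(Y = 1)` in (0, 1).
#' @param beta1 true log-odds coefficient of `eta`.
#' @param p_eta prevalence of the binary characteristic `eta`.
#' @return scalar `beta0`.
#' @export
#' @examples
#' b0 <- solve_intercept(0.20, beta1 = 1, p_eta = 0.30)
#' 0.7 * plogis(b0) + 0.3 * plogis(b0 + 1)  # 0.20
solve_intercept <- function(prevalence_target, beta1, p_eta) {
  stopifnot(prevalence_target > 0, prevalence_target < 1,
            p_eta >= 0, p_eta <= 1, is.finite(beta1))
  f <- function(b0) {
    (1 - p_eta) * invlogit(b0) + p_eta * invlogit(b0 + beta1) -
      prevalence_target
  }
  monotone_root(f)
}

#' Solve the reporting intercept for a target overall sensitivity
#'
#' Reporting sensitivity follows
#' \eqn{\mathrm{logit}\, P(Y^*=1 \mid Y=1, \eta) = \alpha_0 + \alpha_1 \eta}.
#' The overall sensitivity is the average of the two group sensitivities
#' weighted by the composition of \eqn{\eta} among true cases,
#' \eqn{P(\eta = 1 \mid Y = 1) = p_\eta p_1 / [(1-p_\eta) p_0 + p_\eta p_1]}
#' with \eqn{p_\eta = \mathrm{expit}(\beta_0 + \beta_1 \eta)}. This
#' function finds \eqn{\alpha_0} so that the overall sensitivity equals
#' `overall_sensitivity` (residual below 1e-10); re-solving at every
#' \eqn{\alpha_1} holds the overall reporting level fixed while the
#' differential varies.
#'
#' @param overall_sensitivity marginal `P(report | Y = 1)` in (0, 1).
#' @param alpha1 log-odds difference in reporting for `eta = 1` vs
#'   `eta = 0`.
#' @param beta0,beta1,p_eta outcome-model parameters.
#' @return scalar `alpha0`.
#' @export
solve_reporting_intercept <- function(overall_sensitivity, alpha1,
                                      beta0, beta1, p_eta) {
  stopifnot(overall_sensitivity > 0, overall_sensitivity < 1)
  w1 <- eta_share_among_cases(beta0, beta1, p_eta)
  f <- function(a0) {
    (1 - w1) * invlogit(a0) + w1 * invlogit(a0 + alpha1) -
      overall_sensitivity
  }
  monotone_root(f)
}

eta_share_among_cases <- function(beta0, beta1, p_eta) {
  p0 <- invlogit(beta0)
  p1 <- invlogit(beta0 + beta1)
  p_eta * p1 / ((1 - p_eta) * p0 + p_eta * p1)
}

# Root of a strictly increasing function on the real line, polished past
# uniroot's default tolerance by bisection until |f| < 1e-10.
monotone_root <- function(f, lower = -40, upper = 40) {
  r <- stats::uniroot(f, c(lower, upper), tol = 1e-14)$root
  lo <- r - 1e-6; hi <- r + 1e-6
  if (f(lo) > 0 || f(hi) < 0) { lo <- lower; hi <- upper }
  for (i in 1:200) {
    if (abs(f(r)) < 1e-10) break
    if (f(r) > 0) hi <- r else lo <- r
    r <- (lo + hi) / 2
  }
  r
}

#' Bias-study scenario
#'
#' Bundles the Monte Carlo design: per-replicate sample size, prevalence
#' of the characteristic `eta`, the true coefficient, the marginal outcome
#' prevalences studied, the overall reporting sensitivity, the grid of
#' differential-reporting log-odds values, replicate count and seed.
#' Defaults are the study design this module reproduces: n = 10,000
#' women per replicate, 30% with `eta`, overall sensitivity 0.40,
#' `beta1 = 1` (odds ratio 2.7), outcome prevalences 8%, 20% and 50%,
#' 50 replicates per grid point. The differential grid spans -1.5 to 1.5
#' log-odds in steps of 0.25.
#'
#' @param n sample size per replicate.
#' @param p_eta prevalence of `eta`.
#' @param beta1 true log-odds coefficient.
#' @param prevalence_targets marginal outcome prevalences.
#' @param overall_sensitivity marginal `P(report | Y = 1)`.
#' @param differential_grid `alpha1` values.
#' @param reps replicates per grid point.
#' @param seed integer seed.
#' @return an object of class `bias_scenario`.
#' @export
bias_scenario <- function(n = 10000L, p_eta = 0.30, beta1 = 1,
                          prevalence_targets = c(0.08, 0.20, 0.50),
                          overall_sensitivity = 0.40,
                          differential_grid = seq(-1.5, 1.5, by = 0.25),
                          reps = 50L, seed = 1L) {
  stopifnot(n >= 2, reps >= 1,
            p_eta > 0, p_eta < 1,
            all(prevalence_targets > 0 & prevalence_targets < 1),
            overall_sensitivity > 0, overall_sensitivity < 1)
  structure(list(n = as.integer(n), p_eta = p_eta, beta1 = beta1,
                 prevalence_targets = prevalence_targets,
                 overall_sensitivity = overall_sensitivity,
                 differential_grid = differential_grid,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "bias_scenario")
}

#' Resolve one grid point's intercepts
#'
#' @param scenario a [bias_scenario()].
#' @param prevalence_target,alpha1 the grid coordinates.
#' @return list with all model parameters including solved `beta0` and
#'   `alpha0`, and the implied group sensitivities `s0`, `s1`.
#' @export
resolve_point <- function(scenario, prevalence_target, alpha1) {
  beta0 <- solve_intercept(prevalence_target, scenario$beta1,
                           scenario$p_eta)
  alpha0 <- solve_reporting_intercept(scenario$overall_sensitivity, alpha1,
                                      beta0, scenario$beta1,
                                      scenario$p_eta)
  list(n = scenario$n, p_eta = scenario$p_eta, beta1 = scenario$beta1,
       beta0 = beta0, alpha0 = alpha0, alpha1 = alpha1,
       prevalence_target = prevalence_target,
       s0 = invlogit(alpha0), s1 = invlogit(alpha0 + alpha1))
}

#' Simulate one replicate dataset
#'
#' Draws `eta ~ Bernoulli(p_eta)`, the true outcome
#' `Y | eta ~ Bernoulli(expit(beta0 + beta1 eta))`, and the observed
#' outcome `Y* | Y = 1, eta ~ Bernoulli(expit(alpha0 + alpha1 eta))` with
#' `Y* = 0` whenever `Y = 0`: reporting has perfect specificity and
#' imperfect, possibly differential, sensitivity.
#'
#' @param point a resolved grid point from [resolve_point()].
#' @param seed integer seed.
#' @return data.frame with columns `eta`, `y_true`, `y_observed`
#'   (`y_observed <= y_true` row-wise).
#' @export
simulate_dataset <- function(point, seed) {
  set.seed(mix_seed(seed, 3L))
  n <- point$n
  eta <- as.integer(stats::runif(n) < point$p_eta)
  p <- invlogit(point$beta0 + point$beta1 * eta)
  y <- as.integer(stats::runif(n) < p)
  s <- invlogit(point$alpha0 + point$alpha1 * eta)
  y_obs <- as.integer(y == 1L & stats::runif(n) < s)
  data.frame(eta = eta, y_true = y, y_observed = y_obs)
}

#' Logistic-regression slope on the observed outcome
#'
#' Maximum-likelihood \eqn{\hat\beta_1} of
#' `logit P(Y* = 1) = beta0 + beta1 eta`. For a single binary covariate
#' the MLE is the closed-form log odds ratio of the 2x2 table of `Y*` by
#' `eta` (the saturated model), which this uses directly; an iterative
#' `glm` fit agrees to numerical precision and serves as the cross-check
#' in the test suite. A zero margin cell (separation) is an error; grid
#' runs catch it and count the replicate as dropped.
#'
#' @param data data.frame with columns `eta` and `y_observed`.
#' @return scalar `beta1_hat`.
#' @export
estimate_beta1 <- function(data) {
  a <- sum(data$eta == 1L & data$y_observed == 1L)
  b <- sum(data$eta == 1L & data$y_observed == 0L)
  c_ <- sum(data$eta == 0L & data$y_observed == 1L)
  d <- sum(data$eta == 0L & data$y_observed == 0L)
  if (a == 0L || b == 0L || c_ == 0L || d == 0L) {
    stop("separation: a cell of the 2x2 table of y_observed by eta is empty")
  }
  log((a / b) / (c_ / d))
}

#' Exact asymptotic bias of the observed-outcome slope
#'
#' With perfect specificity, \eqn{P(Y^*=1 \mid \eta) = p_\eta s_\eta}
#' where \eqn{p_\eta = \mathrm{expit}(\beta_0+\beta_1\eta)} and
#' \eqn{s_\eta = \mathrm{expit}(\alpha_0+\alpha_1\eta)}; the
#' large-sample limit of \eqn{\hat\beta_1} is therefore
#' \eqn{\mathrm{logit}(p_1 s_1) - \mathrm{logit}(p_0 s_0)} and the bias is
#' that limit minus \eqn{\beta_1}. Nondifferential under-reporting
#' (\eqn{\alpha_1 = 0}, \eqn{s < 1}) makes this strictly negative for
#' \eqn{\beta_1 > 0}: attenuation toward the null.
#'
#' @param point a resolved grid point from [resolve_point()].
#' @return scalar asymptotic bias on the log-odds scale.
#' @export
analytic_bias <- function(point) {
  p0 <- invlogit(point$beta0)
  p1 <- invlogit(point$beta0 + point$beta1)
  (logit(p1 * point$s1) - logit(p0 * point$s0)) - point$beta1
}

#' Run the full Monte Carlo bias grid
#'
#' For every (outcome prevalence, differential-reporting) grid point:
#' solve both intercepts, simulate `reps` replicate datasets with
#' deterministic per-replicate sub-seeds, fit the logistic slope on the
#' observed outcome, and summarise the mean bias, its Monte Carlo standard
#' error and the exact analytic bias. Replicates hitting separation are
#' dropped and counted; a grid point losing more than 10% of its
#' replicates is flagged.
#'
#' @param scenario a [bias_scenario()].
#' @return data.frame of class `bias_grid` with one row per grid point:
#'   `prevalence`, `alpha1`, `s0`, `s1`, `mean_bias`, `mc_se`,
#'   `analytic_bias`, `n_dropped`, `flagged`. The per-replicate estimates
#'   are attached as the `"replicates"` attribute.
#' @export
run_grid <- function(scenario) {
  grid <- expand.grid(prevalence = scenario$prevalence_targets,
                      alpha1 = scenario$differential_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$prevalence, grid$alpha1), , drop = FALSE]
  rows <- vector("list", nrow(grid))
  reps_out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    point <- resolve_point(scenario, grid$prevalence[g], grid$alpha1[g])
    est <- rep(NA_real_, scenario$reps)
    for (r in seq_len(scenario$reps)) {
      d <- simulate_dataset(point, mix_seed(scenario$seed, g, r))
      est[r] <- tryCatch(estimate_beta1(d), error = function(e) NA_real_)
    }
    ok <- est[!is.na(est)]
    n_drop <- sum(is.na(est))
    mean_bias <- mean(ok) - scenario$beta1
    mc_se <- if (length(ok) > 1L) stats::sd(ok) / sqrt(length(ok)) else NA_real_
    rows[[g]] <- data.frame(
      prevalence = grid$prevalence[g], alpha1 = grid$alpha1[g],
      s0 = point$s0, s1 = point$s1,
      mean_bias = mean_bias, mc_se = mc_se,
      analytic_bias = analytic_bias(point),
      n_dropped = n_drop,
      flagged = n_drop > 0.1 * scenario$reps)
    reps_out[[g]] <- est
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- reps_out
  class(out) <- c("bias_grid", "data.frame")
  out
}

#' Plot a bias grid
#'
#' One panel per outcome prevalence: mean Monte Carlo bias (points) and
#' the exact analytic bias (line) against the differential-reporting
#' log-odds parameter. Requires ggplot2.
#'
#' @param grid output of [run_grid()].
#' @return a ggplot object.
#' @export
plot_bias_grid <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bias_grid() requires the ggplot2 package")
  }
  df <- as.data.frame(grid)
  df$panel <- sprintf("prevalence %g%%", 100 * df$prevalence)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$analytic_bias),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_bias)) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "differential reporting (log-odds, alpha1)",
                  y = "bias in estimated log odds")
}

#' @export
print.bias_grid <- function(x, ...) {
  cat(sprintf("<bias_grid> %d grid points, prevalences: %s\n",
              nrow(x), paste(unique(x$prevalence), collapse = ", ")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
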