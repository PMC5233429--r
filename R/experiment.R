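# Monte Carlo harness: replicate loop, true (empirical) variance of the
# coefficient estimates, and variance-ratio diagnostics for the naive
# and cluster-robust estimators.

#' Monte Carlo true variance of coefficient estimates
#'
#' Unbiased sample variance, per coefficient, of the replicate
#' estimates: `V_T = sum_r (beta_r - mean(beta))^2 / (R - 1)`. This is
#' the benchmark both variance estimators are judged against.
#'
#' @param beta_hats `R x P` matrix of replicate coefficient estimates.
#' @return Length-`P` vector of variances.
#' @export
true_variance <- function(beta_hats) {
  beta_hats <- as.matrix(beta_hats)
  if (nrow(beta_hats) < 2L)
    stop("design error: true_variance needs at least 2 replicates",
         call. = FALSE)
  apply(beta_hats, 2L, stats::var)
}

#' Summarize variance-estimator ratios against the true variance
#'
#' For each coefficient, averages the per-replicate ratios `V_R / V_T`
#' and `V_N / V_T`, attaches a parametric 95% confidence interval of
#' the mean (`mean +/- z * SE`), the nonparametric (0.025, 0.975)
#' quantile interval of the per-replicate ratios, and an "unbiased at
#' the 5% level" flag (parametric CI contains 1).
#'
#' @param V_R `R x P` matrix of per-replicate robust variance estimates
#'   (diagonal entries).
#' @param V_N `R x P` matrix of per-replicate naive variance estimates.
#' @param V_T Length-`P` true variances from [true_variance()].
#' @param conf Confidence level.
#'
#' @details Because every per-replicate ratio shares the single Monte
#' Carlo denominator `V_T`, the replicate-level standard error of the
#' mean ratio understates its true sampling error: `V_T` itself carries
#' a relative Monte Carlo error of about `sqrt(2 / (R - 1))`, which
#' dominates for estimators (like the naive one) whose per-replicate
#' spread is small. The "unbiased" flag therefore uses a total-error CI
#' whose standard error adds, by the delta method, the chi-square
#' uncertainty of the denominator:
#' `SE_total^2 = sd(ratios)^2 / R + mean_ratio^2 * 2 / (R - 1)`.
#' The narrower replicate-level CI (`ci_*`) and the nonparametric
#' quantile interval are also reported.
#'
#' @return List with, for each estimator suffix `R` / `N`:
#'   `mean_ratio_*` (length `P`), `ci_*` (replicate-level `P x 2`),
#'   `ci_total_*` (denominator-error-propagated `P x 2`, the basis of
#'   the unbiasedness flag), `ci_quantile_*` (`P x 2`), `unbiased_*`
#'   (logical length `P`); plus `ratios_R`, `ratios_N` (the
#'   per-replicate ratio matrices).
#' @export
ratio_summary <- function(V_R, V_N, V_T, conf = 0.95) {
  V_R <- as.matrix(V_R); V_N <- as.matrix(V_N)
  R <- nrow(V_R)
  if (R < 2L)
    stop("design error: ratio_summary needs at least 2 replicates",
         call. = FALSE)
  if (any(V_T == 0))
    stop("undefined ratio: true variance is zero for some coefficient",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  one <- function(V) {
    ratios <- sweep(V, 2L, V_T, "/")
    mu <- colMeans(ratios)
    se <- apply(ratios, 2L, stats::sd) / sqrt(R)
    ci <- cbind(lower = mu - z * se, upper = mu + z * se)
    se_tot <- sqrt(se^2 + mu^2 * 2 / (R - 1))
    ci_tot <- cbind(lower = mu - z * se_tot, upper = mu + z * se_tot)
    qi <- t(apply(ratios, 2L, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE))
    colnames(qi) <- c("q0.025", "q0.975")
    list(mean = mu, ci = ci, ci_tot = ci_tot, qi = qi,
         unbiased = ci_tot[, 1] <= 1 & 1 <= ci_tot[, 2], ratios = ratios)
  }
  r <- one(V_R); n <- one(V_N)
  list(mean_ratio_R = r$mean, ci_R = r$ci, ci_total_R = r$ci_tot,
       ci_quantile_R = r$qi, unbiased_R = r$unbiased, ratios_R = r$ratios,
       mean_ratio_N = n$mean, ci_N = n$ci, ci_total_N = n$ci_tot,
       ci_quantile_N = n$qi, unbiased_N = n$unbiased, ratios_N = n$ratios)
}

#' Run one Monte Carlo scenario
#'
#' For each replicate: simulate a dataset, apply the requested
#' processing scheme, fit the CLR model, and record the coefficient
#' estimates with the diagonal naive and robust variances. Replicates
#' whose fit fails (separation, rank deficiency, non-convergence,
#' insufficient series) are dropped and counted. Summaries follow
#' [true_variance()] and [ratio_summary()].
#'
#' For `processing = "destructive"` with `L_K = NULL`, a pilot batch of
#' `n_pilot` independent datasets (their own substreams) first supplies
#' the decorrelation lag as the batch maximum.
#'
#' @param config A [sim_config()].
#' @param processing One of `"balanced"`, `"weak"`, `"strong"`,
#'   `"destructive"`.
#' @param R Number of measured replicates (default `config$R`).
#' @param L_K Decorrelation lag for destructive sampling; estimated
#'   from a pilot batch when `NULL`.
#' @param n_pilot Pilot batch size for lag estimation.
#' @param max_fail_frac Scenario is flagged unusable (with a warning)
#'   when more than this fraction of replicates fail.
#' @return An object of class `scenario_result`.
#' @examples
#' cfg <- sim_config(K = 5, S = 6, T = 2000, R = 10, seed = 42)
#' res <- run_scenario(cfg, "balanced")
#' res$mean_ratio_N
#' @export
run_scenario <- function(config, processing = c("balanced", "weak", "strong",
                                                "destructive"),
                         R = config$R, L_K = NULL, n_pilot = 100L,
                         max_fail_frac = 0.1) {
  processing <- match.arg(processing)
  stopifnot(inherits(config, "sim_config"))
  if (processing == "destructive" && is.null(L_K)) {
    # one lag per pilot dataset; pilots that cannot be simulated or
    # fitted (extreme heterogeneity draws) are skipped, like failed
    # replicates in the measured run
    lags <- vapply(seq_len(n_pilot), function(i)
      tryCatch(
        as.integer(estimate_decorrelation_lag(
          simulate_dataset(config, replicate = 500000L + i))),
        error = function(e) NA_integer_), integer(1))
    if (all(is.na(lags)))
      stop("scenario failed: no pilot dataset could be simulated and fitted",
           call. = FALSE)
    L_K <- max(lags, na.rm = TRUE)
  }
  P <- config$P
  beta_mat <- matrix(NA_real_, R, P)
  vn_mat <- matrix(NA_real_, R, P)
  vr_mat <- matrix(NA_real_, R, P)
  failures <- character(0)
  for (r in seq_len(R)) {
    res <- tryCatch({
      d <- simulate_dataset(config, replicate = r)
      d <- switch(processing,
                  balanced = d,
                  weak = unbalance(d, "weak"),
                  strong = unbalance(d, "strong"),
                  destructive = destructive_sample(d, L_K))
      fit <- fit_clr(d)
      if (!fit$converged) stop("fit did not converge", call. = FALSE)
      fit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
    } else {
      beta_mat[r, ] <- res$beta_hat
      vn_mat[r, ] <- diag(res$V_N)
      vr_mat[r, ] <- diag(res$V_R)
    }
  }
  ok <- !is.na(beta_mat[, 1L])
  n_failed <- sum(!ok)
  usable <- n_failed <= max_fail_frac * R
  if (!usable)
    warning(sprintf("scenario unusable: %d of %d replicates failed",
                    n_failed, R), call. = FALSE)
  if (sum(ok) < 2L)
    stop("scenario failed: fewer than 2 successful replicates", call. = FALSE)
  V_T <- true_variance(beta_mat[ok, , drop = FALSE])
  summ <- ratio_summary(vr_mat[ok, , drop = FALSE],
                        vn_mat[ok, , drop = FALSE], V_T)
  structure(
    list(config = config, processing = processing, R = R,
         n_failed = n_failed, usable = usable, L_K = L_K,
         failures = utils::head(failures, 10L),
         beta_hat_matrix = beta_mat[ok, , drop = FALSE],
         mean_beta = colMeans(beta_mat[ok, , drop = FALSE]),
         V_T = V_T,
         mean_ratio_R = summ$mean_ratio_R, ci_R = summ$ci_R,
         ci_total_R = summ$ci_total_R,
         ci_quantile_R = summ$ci_quantile_R, unbiased_R = summ$unbiased_R,
         mean_ratio_N = summ$mean_ratio_N, ci_N = summ$ci_N,
         ci_total_N = summ$ci_total_N,
         ci_quantile_N = summ$ci_quantile_N, unbiased_N = summ$unbiased_N),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Scenario: K = %d, S = %d, P = %d, rho = %g, sigma_H2 = %g, %s\n",
              cfg$K, cfg$S, cfg$P, cfg$rho, cfg$sigma_H2, x$processing))
  if (!is.null(x$L_K)) cat(sprintf("  destructive lag L_K = %d\n", x$L_K))
  cat(sprintf("  replicates: %d requested, %d failed%s\n", x$R, x$n_failed,
              if (x$usable) "" else "  [UNUSABLE]"))
  tab <- data.frame(V_T = x$V_T,
                    ratio_R = x$mean_ratio_R,
                    R_lo = x$ci_R[, 1], R_hi = x$ci_R[, 2],
                    ratio_N = x$mean_ratio_N,
                    N_lo = x$ci_N[, 1], N_hi = x$ci_N[, 2],
                    mean_beta = x$mean_beta)
  rownames(tab) <- paste0("x", seq_len(cfg$P))
  print(tab, digits = 3)
  invisible(x)
}

#' The full scenario grid of the simulation study
#'
#' Cartesian product of cluster counts `K` in \{3, 5, 10, 20, 30, 50\}
#' (with `S = floor(600 / K)`), temporal autocorrelation `rho` in
#' \{0, 0.3, 0.5, 0.7\}, heterogeneity `sigma_H2` in
#' \{0, 0.2, 0.5, 1, 1.5, 2.5\}, covariate counts `P` in \{2, 10\} and
#' the four processing schemes -- 1152 scenario descriptors.
#'
#' @return Data frame with columns `K`, `S`, `rho`, `sigma_H2`, `P`,
#'   `processing`.
#' @export
default_grid <- function() {
  g <- expand.grid(K = c(3L, 5L, 10L, 20L, 30L, 50L),
                   rho = c(0, 0.3, 0.5, 0.7),
                   sigma_H2 = c(0, 0.2, 0.5, 1, 1.5, 2.5),
                   P = c(2L, 10L),
                   processing = c("balanced", "weak", "strong",
                                  "destructive"),
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g$S <- 600L %/% g$K
  g[, c("K", "S", "rho", "sigma_H2", "P", "processing")]
}
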