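#' Simulation configuration for correlated matched case-control data
#'
#' Bundles every parameter of the data-generating process and the Monte
#' Carlo experiment: `K` independent clusters (one per animal), each
#' providing `S` matched strata of `N` locations with `m` used (case)
#' locations, drawn from a length-`T` correlated Bernoulli series whose
#' selection coefficients follow AR(1) paths around cluster-level random
#' effects.
#'
#' @param K Number of independent clusters (animals). At least 1.
#' @param S Strata per cluster. Defaults to `floor(N_tot / K)` so the
#'   total number of strata is held (approximately) constant as `K`
#'   varies; any remainder of `N_tot / K` is dropped.
#' @param N Locations per stratum (1 case plus `N - m` controls).
#' @param m Cases per stratum; the estimator supports `m = 1`.
#' @param T Length of each cluster's underlying Bernoulli series. The
#'   stratum sampler consumes the series from the front, so `T` acts as a
#'   cap: a series that cannot supply `S` cases and `S * (N - m)` controls
#'   within `T` steps raises an insufficient-series error.
#' @param P Number of habitat covariates (2 or 10 have default
#'   coefficient vectors; any `P` is accepted with an explicit
#'   `beta_fixed`).
#' @param beta_fixed Length-`P` fixed (population-level) selection
#'   coefficients. Defaults: `c(0.75, 0.5)` for `P = 2` and
#'   `c(0.75, 0.75, 0.75, 0.5, 0.5, 0.5, 0.2, 0.2, 0.2, 0.2)` for
#'   `P = 10`.
#' @param sigma_H2 Inter-individual heterogeneity variance (>= 0) of the
#'   cluster-level random intercept and random slopes.
#' @param rho AR(1) coefficient in `[0, 1)` of the temporal paths
#'   followed by the selection coefficients.
#' @param sigma_X2 Variance of the i.i.d. Gaussian covariates.
#' @param R Monte Carlo replicates for experiments built on this
#'   configuration.
#' @param seed Master RNG seed; all cluster/replicate substreams are
#'   derived from it (see [substream_seed()]).
#' @param N_tot Target total number of strata across clusters, used only
#'   to derive the default `S`.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [simulate_dataset()], [run_scenario()]
#' @examples
#' cfg <- sim_config(K = 30)          # S defaults to 20
#' cfg$S
#' sim_config(K = 10, P = 10, sigma_H2 = 1, rho = 0.5)
#' @export
sim_config <- function(K = 30, S = NULL, N = 10, m = 1, T = 20000, P = 2,
                       beta_fixed = NULL, sigma_H2 = 0, rho = 0,
                       sigma_X2 = 0.5, R = 500, seed = 1L, N_tot = 600) {
  num_scalar <- function(x, nm) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
      stop("configuration error: '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    as.numeric(x)
  }
  K <- num_scalar(K, "K")
  if (K < 1) stop("configuration error: K >= 1 required", call. = FALSE)
  if (is.null(S)) S <- N_tot %/% K
  if (is.null(beta_fixed)) beta_fixed <- default_beta_fixed(P)
  S <- num_scalar(S, "S"); N <- num_scalar(N, "N")
  m <- num_scalar(m, "m"); T <- num_scalar(T, "T"); P <- num_scalar(P, "P")
  sigma_H2 <- num_scalar(sigma_H2, "sigma_H2")
  rho <- num_scalar(rho, "rho")
  sigma_X2 <- num_scalar(sigma_X2, "sigma_X2")
  R <- num_scalar(R, "R"); seed <- num_scalar(seed, "seed")
  if (!all(is.finite(beta_fixed)))
    stop("configuration error: 'beta_fixed' must be finite", call. = FALSE)
  if (length(beta_fixed) != P)
    stop("configuration error: length(beta_fixed) must equal P", call. = FALSE)
  if (S < 1) stop("configuration error: S >= 1 required", call. = FALSE)
  if (N < 2) stop("configuration error: N >= 2 required", call. = FALSE)
  if (m < 1 || m >= N)
    stop("configuration error: 1 <= m < N required", call. = FALSE)
  if (sigma_H2 < 0)
    stop("configuration error: sigma_H2 >= 0 required", call. = FALSE)
  if (rho < 0 || rho >= 1)
    stop("configuration error: rho must lie in [0, 1)", call. = FALSE)
  if (sigma_X2 < 0)
    stop("configuration error: sigma_X2 >= 0 required", call. = FALSE)
  if (T < N) stop("configuration error: T >= N required", call. = FALSE)
  if (R < 1) stop("configuration error: R >= 1 required", call. = FALSE)
  structure(
    list(K = as.integer(K), S = as.integer(S), N = as.integer(N),
         m = as.integer(m), T = as.integer(T), P = as.integer(P),
         beta_fixed = as.numeric(beta_fixed), sigma_H2 = sigma_H2,
         rho = rho, sigma_X2 = sigma_X2, R = as.integer(R),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Default fixed selection coefficients
#'
#' @param P Number of covariates; defaults exist for `P = 2` and `P = 10`.
#' @return A length-`P` numeric vector.
#' @export
default_beta_fixed <- function(P) {
  if (P == 2) return(c(0.75, 0.5))
  if (P == 10) return(c(0.75, 0.75, 0.75, 0.5, 0.5, 0.5, 0.2, 0.2, 0.2, 0.2))
  stop("configuration error: no default beta_fixed for P = ", P,
       "; supply beta_fixed explicitly", call. = FALSE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  clusters K = %d, strata/cluster S = %d, N = %d (m = %d case)\n",
              x$K, x$S, x$N, x$m))
  cat(sprintf("  series length T = %d, covariates P = %d\n", x$T, x$P))
  cat(sprintf("  beta_fixed = (%s)\n", paste(format(x$beta_fixed), collapse = ", ")))
  cat(sprintf("  sigma_H2 = %g, rho = %g, sigma_X2 = %g\n",
              x$sigma_H2, x$rho, x$sigma_X2))
  cat(sprintf("  replicates R = %d, seed = %d\n", x$R, x$seed))
  invisible(x)
}

#' Derive a reproducible RNG substream seed
#'
#' Hashes a master seed together with any number of non-negative integer
#' indices (replicate, cluster, scenario, ...) into a 31-bit seed for
#' [set.seed()]. Each `(seed, indices...)` combination maps to a fixed
#' substream, so replicates and clusters can be simulated in any order
#' (or any subset) without correlating their draws.
#'
#' @param seed Master seed (integer-valued scalar).
#' @param ... Integer indices identifying the substream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' substream_seed(1, 3, 7)   # replicate 3, cluster 7
#' @export
substream_seed <- function(seed, ...) {
  h <- (abs(as.numeric(seed)) %% 2147483647) + 1
  for (v in c(...)) {
    if (!is.finite(v)) stop("substream index must be finite", call. = FALSE)
    h <- (h * 48271 + abs(as.numeric(v)) + 1) %% 2147483647
  }
  as.integer(h + (h == 0))
}
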