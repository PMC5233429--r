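# Generation of one cluster's correlated Bernoulli series and its
# assembly into matched case-control strata.
#
# The series for cluster k is built step by step:
#   theta^(k)  ~ N(0, sigma_H2)                  cluster random intercept
#   b_p^(k)    ~ N(0, sigma_H2)                  cluster random slopes
#   gamma_p0   ~ N(0, 1); gamma_pt = rho * gamma_p,t-1 + eps_pt, eps ~ N(0,1)
#   beta_pt    = beta_fixed_p + b_p + gamma_pt
#   X_pt       ~ N(0, sigma_X2) i.i.d.
#   W_t        = theta + sum_p beta_pt X_pt;  p_t = plogis(W_t)
#   Y_t        ~ Bernoulli(p_t)
#
# The AR(1) path is deliberately NOT variance-stationary for rho > 0:
# it starts at unit variance and drifts toward 1 / (1 - rho^2), matching
# the printed recursion, and is never rescaled.
#
# Draws are strictly forward-sequential, so the distribution of any
# prefix of the series does not depend on how far generation continues.
# Generation happens in chunks whose sizes depend only on the
# configuration; the dataset simulator stops at the first chunk boundary
# where the stratum quota is met, which is bitwise identical to the
# prefix of a full-length run under the same substream seed.

chunk_plan <- function(config) {
  need <- config$S * config$N
  first <- min(config$T, 64L + as.integer(ceiling(2.6 * need)))
  step <- max(256L, as.integer(ceiling(1.3 * need)))
  sizes <- first
  total <- first
  while (total < config$T) {
    s <- min(step, config$T - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  as.integer(sizes)
}

series_state_init <- function(config) {
  sd_H <- sqrt(config$sigma_H2)
  theta <- stats::rnorm(1L, 0, sd_H)
  b <- stats::rnorm(config$P, 0, sd_H)
  gamma0 <- stats::rnorm(config$P)
  list(theta = theta, b = b, gamma0 = gamma0, gamma_prev = gamma0)
}

series_next_chunk <- function(config, state, L) {
  P <- config$P
  eps <- matrix(stats::rnorm(L * P), L, P)
  gamma <- matrix(0, L, P)
  for (p in seq_len(P)) {
    gamma[, p] <- stats::filter(eps[, p], config$rho, method = "recursive",
                                init = state$gamma_prev[p])
  }
  X <- matrix(stats::rnorm(L * P, 0, sqrt(config$sigma_X2)), L, P)
  W <- state$theta + drop(X %*% (config$beta_fixed + state$b)) +
    rowSums(gamma * X)
  pt <- stats::plogis(W)
  y <- stats::rbinom(L, 1L, pt)
  state$gamma_prev <- gamma[L, ]
  list(state = state, eps = eps, gamma = gamma, X = X, p = pt, y = y)
}

#' Generate one cluster's correlated Bernoulli series
#'
#' Realizes the full latent and observed process for a single cluster:
#' cluster-level random intercept and slopes, AR(1) coefficient paths,
#' i.i.d. Gaussian covariates, success probabilities and the Bernoulli
#' outcomes. Latent paths are retained so the generator itself can be
#' tested; the estimator never sees them.
#'
#' @param config A [sim_config()].
#' @param cluster_index Cluster number (used to derive the substream).
#' @param replicate Replicate number (used to derive the substream).
#' @param seed Substream seed; defaults to
#'   `substream_seed(config$seed, replicate, cluster_index)`.
#' @param n_steps Number of time steps to realize (default `config$T`).
#'   Generation proceeds over the same chunk schedule regardless of
#'   `n_steps`, so shorter runs are exact prefixes of longer ones.
#'
#' @return An object of class `correlated_series`: a list with
#'   `y_tilde` (0/1 outcomes), `X` (steps x P covariates), `gamma`
#'   (steps x P AR(1) paths), `eps` (AR(1) innovations), `p`
#'   (success probabilities), `theta`, `b`, `gamma0`.
#' @examples
#' cfg <- sim_config(K = 2, S = 5, T = 500)
#' ser <- generate_cluster_series(cfg, cluster_index = 1)
#' mean(ser$y_tilde)
#' @export
generate_cluster_series <- function(config, cluster_index = 1L,
                                    replicate = 1L,
                                    seed = substream_seed(config$seed,
                                                          replicate,
                                                          cluster_index),
                                    n_steps = config$T) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  state <- series_state_init(config)
  plan <- chunk_plan(config)
  acc <- list(y = list(), X = list(), gamma = list(), eps = list(), p = list())
  total <- 0L
  for (L in plan) {
    ch <- series_next_chunk(config, state, L)
    state <- ch$state
    acc$y[[length(acc$y) + 1L]] <- ch$y
    acc$X[[length(acc$X) + 1L]] <- ch$X
    acc$gamma[[length(acc$gamma) + 1L]] <- ch$gamma
    acc$eps[[length(acc$eps) + 1L]] <- ch$eps
    acc$p[[length(acc$p) + 1L]] <- ch$p
    total <- total + L
    if (total >= n_steps) break
  }
  keep <- seq_len(min(total, n_steps))
  structure(
    list(y_tilde = unlist(acc$y)[keep],
         X = do.call(rbind, acc$X)[keep, , drop = FALSE],
         gamma = do.call(rbind, acc$gamma)[keep, , drop = FALSE],
         eps = do.call(rbind, acc$eps)[keep, , drop = FALSE],
         p = unlist(acc$p)[keep],
         theta = state$theta, b = state$b, gamma0 = state$gamma0),
    class = "correlated_series")
}

# Successive sampling of a 0/1 series into S strata of m cases +
# (N - m) controls: stratum j consumes the j-th block of m unconsumed
# 1s and the j-th block of (N - m) unconsumed 0s, each channel scanned
# forward in time. Consecutive strata thus sit directly adjacent in
# both channels (cases ~ 1/p steps apart), which preserves the AR(1)
# dependence between neighbouring strata -- the mechanism under study.
# Returns either the index matrix (cases first) or a shortfall record.
scan_strata <- function(y, S, N, m) {
  ones <- which(y == 1L)
  zeros <- which(y == 0L)
  nc <- N - m
  if (length(ones) < S * m || length(zeros) < S * nc) {
    short_at <- min(length(ones) %/% m, length(zeros) %/% nc) + 1L
    return(list(ok = FALSE, stratum = short_at,
                need_cases = S * m, have_cases = length(ones),
                need_controls = S * nc, have_controls = length(zeros)))
  }
  idx <- cbind(
    matrix(ones[seq_len(S * m)], S, m, byrow = TRUE),
    matrix(zeros[seq_len(S * nc)], S, nc, byrow = TRUE))
  list(ok = TRUE, idx = idx)
}

insufficient_series_error <- function(sc, T) {
  stop(sprintf(paste0("insufficient series: needed %d cases and %d controls ",
                      "but found only %d cases and %d controls within %d ",
                      "steps (failed at stratum %d)"),
               sc$need_cases, sc$need_controls, sc$have_cases,
               sc$have_controls, T, sc$stratum), call. = FALSE)
}

#' Assemble matched strata from a realized series
#'
#' Successively samples the series: stratum `j` consumes the earliest
#' `m` unconsumed cases (`y_tilde == 1`) and the earliest `N - m`
#' unconsumed controls (`y_tilde == 0`), each channel scanned forward
#' in time, carrying their covariates. Consumed indices are never
#' reused; within each channel the time indices increase strictly from
#' stratum to stratum, so neighbouring strata stay temporally adjacent.
#'
#' @param series A `correlated_series` from [generate_cluster_series()].
#' @param S Number of strata to form.
#' @param N Locations per stratum.
#' @param m Cases per stratum.
#' @return A list of `S` strata; each is a list with `y` (length `N`,
#'   cases first), `X` (`N x P` covariates) and `time_indices` (source
#'   positions in the series, cases first).
#' @examples
#' cfg <- sim_config(K = 1, S = 3, N = 4, T = 200)
#' ser <- generate_cluster_series(cfg)
#' st <- build_strata(ser, S = 3, N = 4, m = 1)
#' sapply(st, function(s) sum(s$y))   # one case each
#' @export
build_strata <- function(series, S, N, m = 1L) {
  stopifnot(is.numeric(series$y_tilde), is.matrix(series$X))
  sc <- scan_strata(series$y_tilde, S, N, m)
  if (!sc$ok) insufficient_series_error(sc, length(series$y_tilde))
  lapply(seq_len(S), function(j) {
    ix <- sc$idx[j, ]
    list(y = c(rep(1L, m), rep(0L, N - m)),
         X = series$X[ix, , drop = FALSE],
         time_indices = ix)
  })
}

#' Construct / validate a matched case-control dataset
#'
#' A `matched_dataset` is a flat data frame with columns `cluster_id`,
#' `stratum_id`, `case_flag` (0/1), covariates `x1..xP`, and optionally
#' `t` (the source position in the generating series). Strata within a
#' cluster are ordered by `stratum_id`, which preserves generation
#' (time) order. The `provenance` attribute records which processing
#' scheme produced the data.
#'
#' @param df Data frame with the columns above.
#' @param provenance One of `"balanced"`, `"weak_unbalanced"`,
#'   `"strong_unbalanced"`, `"destructive"`, `"unknown"`.
#' @param m Cases per stratum (validated).
#' @param validate Check the stratum invariants (every stratum sums to
#'   `m` cases; cluster ids present).
#' @return The data frame with class `matched_dataset`.
#' @export
matched_dataset <- function(df, provenance = "balanced", m = 1L,
                            validate = TRUE) {
  need <- c("cluster_id", "stratum_id", "case_flag")
  if (!all(need %in% names(df)))
    stop("design error: dataset must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  if (length(xcols) == 0L)
    stop("design error: dataset must have covariate columns x1..xP",
         call. = FALSE)
  if (validate) {
    key <- paste(df$cluster_id, df$stratum_id, sep = ".")
    sums <- rowsum(df$case_flag, key)
    if (any(sums != m))
      stop("design error: every stratum must contain exactly ", m,
           " case(s); offending strata: ",
           paste(utils::head(rownames(sums)[sums != m], 5), collapse = ", "),
           call. = FALSE)
  }
  structure(df,
            provenance = provenance,
            m = as.integer(m),
            class = c("matched_dataset", "data.frame"))
}

#' @export
print.matched_dataset <- function(x, ...) {
  K <- length(unique(x$cluster_id))
  Stot <- nrow(unique(x[, c("cluster_id", "stratum_id")]))
  cat(sprintf("Matched case-control dataset: %d clusters, %d strata, %d rows (%s)\n",
              K, Stot, nrow(x), attr(x, "provenance")))
  invisible(x)
}

#' Provenance of a matched dataset
#' @param x A `matched_dataset`.
#' @return Character scalar (e.g. `"balanced"`, `"destructive"`).
#' @export
provenance <- function(x) attr(x, "provenance") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full matched case-control dataset
#'
#' Generates `K` independent cluster series (one RNG substream per
#' cluster and replicate) and assembles each into `S` strata of `N`
#' locations with `m` cases. Each cluster's series is realized only as
#' far as needed to fill its strata (capped at `config$T`); the result
#' is identical to building strata from the full-length series.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index; datasets with different replicate
#'   indices are independent.
#' @return A [matched_dataset()] with provenance `"balanced"`.
#' @examples
#' cfg <- sim_config(K = 3, S = 4, T = 2000)
#' d <- simulate_dataset(cfg)
#' table(d$cluster_id)   # S * N rows per cluster
#' @export
simulate_dataset <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  S <- config$S; N <- config$N; m <- config$m; P <- config$P
  plan <- chunk_plan(config)
  parts <- vector("list", config$K)
  for (k in seq_len(config$K)) {
    set.seed(substream_seed(config$seed, replicate, k))
    state <- series_state_init(config)
    y_all <- integer(0)
    X_all <- matrix(numeric(0), 0L, P)
    sc <- NULL
    for (L in plan) {
      ch <- series_next_chunk(config, state, L)
      state <- ch$state
      y_all <- c(y_all, ch$y)
      X_all <- rbind(X_all, ch$X)
      sc <- scan_strata(y_all, S, N, m)
      if (sc$ok) break
    }
    if (!sc$ok) insufficient_series_error(sc, length(y_all))
    ix <- as.vector(t(sc$idx))            # row-major: stratum by stratum
    parts[[k]] <- data.frame(
      cluster_id = k,
      stratum_id = rep(seq_len(S), each = N),
      case_flag = rep(c(rep(1L, m), rep(0L, N - m)), times = S),
      t = ix,
      X_all[ix, , drop = FALSE])
  }
  out <- do.call(rbind, parts)
  names(out)[5:(4 + P)] <- paste0("x", seq_len(P))
  rownames(out) <- NULL
  matched_dataset(out, provenance = "balanced", m = m, validate = FALSE)
}

#' Write / read the flat dataset CSV dialect
#'
#' Plain CSV with header: `cluster_id`, `stratum_id`, `case_flag`,
#' `x1..xP` (plus `t` when present). Round-trips losslessly.
#'
#' @param x A `matched_dataset` (or compatible data frame).
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns a [matched_dataset()].
#' @export
write_dataset <- function(x, path) {
  xcols <- grep("^x[0-9]+$", names(x), value = TRUE)
  cols <- c("cluster_id", "stratum_id", "case_flag",
            intersect("t", names(x)), xcols)
  out <- as.data.frame(x)[, cols]
  # 17 significant digits so doubles survive the text round trip exactly
  out[xcols] <- lapply(out[xcols], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param provenance Provenance to record on the read dataset (the CSV
#'   itself does not carry it; run manifests do).
#' @param m Cases per stratum expected by validation.
#' @export
read_dataset <- function(path, provenance = "balanced", m = 1L) {
  df <- utils::read.csv(path)
  matched_dataset(df, provenance = provenance, m = m, validate = TRUE)
}
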