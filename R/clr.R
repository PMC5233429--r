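# Conditional logistic regression via the GEE score under an
# independence working structure. With one case per stratum the
# estimating equation reduces to the conditional-likelihood (softmax)
# score, the same estimator the stratified proportional-hazards routine
# computes; here it is solved directly by Newton-Raphson with
# step-halving.

# Pull the pieces fit functions need out of a dataset: covariate matrix,
# case indicator, integer stratum index (first-appearance order) and
# cluster labels. Row order is free; strata are identified by
# (cluster_id, stratum_id).
clr_design <- function(data) {
  df <- as.data.frame(data)
  need <- c("cluster_id", "stratum_id", "case_flag")
  if (!all(need %in% names(df)))
    stop("design error: dataset must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  if (length(xcols) == 0L)
    stop("design error: no covariate columns x1..xP found", call. = FALSE)
  key <- paste(df$cluster_id, df$stratum_id, sep = "\r")
  g <- match(key, unique(key))
  sums <- rowsum(df$case_flag, g)
  if (any(sums != 1L))
    stop("design error: every stratum must contain exactly one case ",
         "(m = 1); found strata with case counts ",
         paste(unique(sums[sums != 1L]), collapse = ", "), call. = FALSE)
  list(X = unname(as.matrix(df[, xcols, drop = FALSE])),
       y = as.numeric(df$case_flag),
       g = g,
       n_strata = max(g),
       cluster = df$cluster_id,
       P = length(xcols))
}

# Softmax pieces at a coefficient vector: per-observation case
# probabilities w, log-likelihood, score and information, all summed
# over strata. Group maxima guard the exponentials.
clr_eval <- function(des, beta, want_info = TRUE) {
  eta <- drop(des$X %*% beta)
  if (any(!is.finite(eta)))
    stop("numerical error: non-finite linear predictor", call. = FALSE)
  mx <- as.numeric(tapply(eta, des$g, max))[des$g]
  e <- exp(eta - mx)
  denom <- rowsum(e, des$g)          # rows ordered by group 1..S
  w <- as.numeric(e / denom[des$g])
  loglik <- sum(log(w[des$y == 1]))
  resid <- des$y - w
  score <- drop(crossprod(des$X, resid))
  out <- list(loglik = loglik, score = score, w = w)
  if (want_info) {
    Xw <- des$X * w
    A <- crossprod(des$X, Xw)
    Mns <- rowsum(Xw, des$g)
    out$information <- A - crossprod(Mns)
  }
  out
}

#' Within-stratum case probabilities (conditional logistic model)
#'
#' For one stratum of `N` locations, the probability that location `i`
#' is the used one is the softmax of the linear predictors
#' `exp(x_i' beta) / sum_j exp(x_j' beta)`. Computed with
#' max-subtraction so large predictors cannot overflow.
#'
#' @param X `N x P` covariate matrix for one stratum.
#' @param beta Length-`P` coefficient vector.
#' @return Length-`N` probability vector summing to 1.
#' @examples
#' stratum_case_probabilities(matrix(c(1, 0), 2, 1), log(4))  # 0.8, 0.2
#' @export
stratum_case_probabilities <- function(X, beta) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("design error: a stratum needs N >= 2", call. = FALSE)
  eta <- drop(X %*% beta)
  if (any(!is.finite(eta)))
    stop("numerical error: non-finite linear predictor", call. = FALSE)
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Conditional log-likelihood, score and information
#'
#' Evaluates, at a given coefficient vector, the conditional (matched
#' case-control) log-likelihood of a dataset with one case per stratum,
#' its score vector `sum_strata (x_case - sum_i pi_i x_i)` and the
#' information matrix `sum_strata sum_i pi_i (x_i - xbar)(x_i - xbar)'`.
#' Under the independence working structure this score is exactly the
#' GEE estimating function.
#'
#' @param data A [matched_dataset()] or data frame in the flat dialect.
#' @param beta Length-`P` coefficient vector.
#' @return List with elements `loglik` (always `<= 0`), `score` and
#'   `information`.
#' @export
conditional_loglik_score <- function(data, beta) {
  des <- clr_design(data)
  ev <- clr_eval(des, beta)
  list(loglik = ev$loglik, score = ev$score, information = ev$information)
}

#' Fit conditional logistic regression by Newton-Raphson
#'
#' Solves the GEE score equation under the independence working
#' structure (equivalently, maximizes the conditional likelihood)
#' starting from `beta = 0`, with step-halving whenever a full Newton
#' step would decrease the log-likelihood. On convergence the naive
#' (model-based, inverse-information) and cluster-robust sandwich
#' covariance matrices are attached.
#'
#' @param data A [matched_dataset()] or data frame in the flat dialect.
#' @param tol Convergence tolerance on the score sup-norm.
#' @param max_iter Maximum Newton iterations.
#' @param beta_bound Divergence guard: `|beta|` exceeding this bound
#'   with a non-vanishing score raises a separation error.
#' @return An object of class `clr_fit` with elements `beta_hat`,
#'   `V_N`, `V_R`, `components` (bread, meat, per-cluster scores),
#'   `loglik`, `n_iterations`, `converged`, `score_norm`, `n_clusters`.
#' @examples
#' cfg <- sim_config(K = 4, S = 10, T = 2000, seed = 7)
#' fit <- fit_clr(simulate_dataset(cfg))
#' fit$beta_hat
#' sqrt(diag(fit$V_R))     # cluster-robust standard errors
#' @export
fit_clr <- function(data, tol = 1e-8, max_iter = 100L, beta_bound = 50) {
  des <- clr_design(data)
  if (des$n_strata < 1L) stop("design error: empty dataset", call. = FALSE)
  beta <- numeric(des$P)
  cur <- clr_eval(des, beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (max(abs(cur$score)) < tol) { converged <- TRUE; break }
    delta <- tryCatch(solve(cur$information, cur$score),
                      error = function(e)
                        stop("rank error: singular information matrix",
                             call. = FALSE))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ev <- clr_eval(des, cand)
      if (ev$loglik >= cur$loglik - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    beta <- cand
    cur <- ev
    if (max(abs(beta)) > beta_bound && max(abs(cur$score)) >= tol)
      stop("separation error: |beta| exceeded ", beta_bound,
           " with non-vanishing score (likely complete separation)",
           call. = FALSE)
  }
  if (max(abs(cur$score)) < tol) converged <- TRUE
  # Complete separation drives the case probabilities to 1, so the score
  # vanishes at a finite but drifting beta; catch the perfect-fit limit.
  if (converged && cur$loglik > -1e-6 && max(abs(beta)) > 5)
    stop("separation error: perfect prediction of all cases ",
         "(complete separation)", call. = FALSE)
  B <- solve_spd(cur$information)
  K <- length(unique(des$cluster))
  rb <- sandwich_pieces(des, cur$w, B)
  structure(
    list(beta_hat = beta, V_N = B, V_R = rb$V_R, components = rb$components,
         loglik = cur$loglik, n_iterations = it, converged = converged,
         score_norm = max(abs(cur$score)), n_clusters = K,
         n_strata = des$n_strata, P = des$P),
    class = "clr_fit")
}

solve_spd <- function(M) {
  out <- tryCatch(solve(M), error = function(e)
    stop("rank error: singular information matrix", call. = FALSE))
  (out + t(out)) / 2
}

sandwich_pieces <- function(des, w, B) {
  U <- rowsum((des$y - w) * des$X, des$cluster)   # K x P cluster scores
  meat <- crossprod(U)
  V_R <- B %*% meat %*% B
  V_R <- (V_R + t(V_R)) / 2
  list(V_R = V_R,
       components = list(bread = B, meat = meat, per_cluster_scores = U))
}

#' Naive (model-based) covariance of the CLR coefficients
#'
#' The inverse of the total information at `beta_hat` -- the "bread" of
#' the sandwich. It is the correct covariance only if strata really are
#' independent (working structure correctly specified).
#'
#' @param data A [matched_dataset()] or compatible data frame.
#' @param beta_hat Coefficients from a converged fit.
#' @return Symmetric `P x P` matrix.
#' @export
naive_variance <- function(data, beta_hat) {
  des <- clr_design(data)
  ev <- clr_eval(des, beta_hat)
  solve_spd(ev$information)
}

#' Cluster-robust sandwich covariance of the CLR coefficients
#'
#' Computes the per-cluster score contributions
#' `U_k = sum_{strata in k} (x_case - sum_i pi_i x_i)` at `beta_hat`,
#' the empirical "meat" `sum_k U_k U_k'` and the sandwich
#' `B (sum_k U_k U_k') B`, where `B` is the naive covariance. No
#' small-sample (e.g. `K/(K-1)`) inflation is applied.
#'
#' @inheritParams naive_variance
#' @return List with `V_R` (symmetric `P x P` matrix) and `components`
#'   (`bread`, `meat`, `per_cluster_scores`, a `K x P` matrix).
#' @details With a single cluster the total score vanishes at the
#'   optimum, so the sandwich degenerates to the zero matrix; a warning
#'   signals this rather than failing.
#' @export
robust_variance <- function(data, beta_hat) {
  des <- clr_design(data)
  ev <- clr_eval(des, beta_hat)
  B <- solve_spd(ev$information)
  K <- length(unique(des$cluster))
  if (K < 2L)
    warning("robust variance is degenerate with a single cluster: ",
            "the total score vanishes at the optimum", call. = FALSE)
  sandwich_pieces(des, ev$w, B)
}

#' @export
print.clr_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic regression (GEE, independence working structure)\n"))
  cat(sprintf("  %d strata in %d cluster(s); loglik = %.4f; %s in %d iter (|score| = %.2e)\n",
              x$n_strata, x$n_clusters, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$score_norm))
  tab <- data.frame(estimate = x$beta_hat,
                    naive_se = sqrt(diag(x$V_N)),
                    robust_se = sqrt(diag(x$V_R)))
  rownames(tab) <- paste0("x", seq_len(x$P))
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.clr_fit <- function(object, ...) object$beta_hat

#' Covariance matrix of a CLR fit
#' @param object A `clr_fit`.
#' @param type `"robust"` (sandwich) or `"naive"` (model-based).
#' @param ... Unused.
#' @return `P x P` covariance matrix.
#' @export
vcov.clr_fit <- function(object, type = c("robust", "naive"), ...) {
  switch(match.arg(type), robust = object$V_R, naive = object$V_N)
}
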