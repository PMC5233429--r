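# Re-clustering schemes: estimating the stratum-scale decorrelation lag,
# destructive sampling (split each animal into two temporally separated
# clusters), and weak/strong unbalancing.

require_balanced <- function(data, op) {
  pv <- provenance(data)
  if (!identical(pv, "balanced"))
    stop("provenance error: ", op, " expects an unprocessed (balanced) ",
         "dataset, got provenance '", pv, "'", call. = FALSE)
}

cluster_sizes <- function(data) {
  u <- unique(data[, c("cluster_id", "stratum_id")])
  table(u$cluster_id)
}

# Per-stratum score residual for one coefficient: x_case,p minus the
# softmax-weighted stratum mean of x_p, evaluated at beta_hat. One
# scalar per stratum, in stratum (time) order, split by cluster.
stratum_residuals <- function(data, beta_hat, coef = 1L) {
  des <- clr_design(data)
  ev <- clr_eval(des, beta_hat, want_info = FALSE)
  xp <- des$X[, coef]
  r <- rowsum((des$y - ev$w) * xp, des$g)   # per-stratum scalar
  first <- !duplicated(des$g)
  ord <- data.frame(cluster = des$cluster[first],
                    stratum = as.data.frame(data)$stratum_id[first])
  split(r[order(ord$cluster, ord$stratum)],
        ord$cluster[order(ord$cluster, ord$stratum)])
}

#' Estimate the stratum-scale decorrelation lag over a batch of datasets
#'
#' For each dataset, fits the CLR model (unless fits are supplied),
#' forms per-stratum score residuals for one coefficient, computes each
#' cluster's autocorrelation function over stratum lags, averages the
#' ACF across the `K` clusters, and records the smallest lag at which
#' the absolute averaged ACF drops below the white-noise band of the
#' *averaged* estimator, `z_{1 - alpha/2} / sqrt(K * S)` (averaging
#' over clusters shrinks the null sd of the ACF by `sqrt(K)`). The
#' returned lag is the maximum over the batch -- the number of strata a
#' destructive split must drop so the two halves of any cluster are
#' temporally decorrelated.
#'
#' @param datasets A `matched_dataset` or list of them.
#' @param alpha Significance level of the white-noise band.
#' @param fits Optional list of [fit_clr()] results matching `datasets`.
#' @param coef Which coefficient's residuals to use (default the first;
#'   the choice shifts the lag slightly and is therefore exposed).
#' @param lag_max Largest stratum lag examined; defaults to
#'   `min(S_k) - 2` capped at 25.
#' @return Integer lag (>= 1), with attribute `"lags"` giving the
#'   per-dataset lags.
#' @export
estimate_decorrelation_lag <- function(datasets, alpha = 0.05, fits = NULL,
                                       coef = 1L, lag_max = NULL) {
  if (inherits(datasets, "matched_dataset")) datasets <- list(datasets)
  lags <- vapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    fit <- if (is.null(fits)) fit_clr(d) else fits[[i]]
    res <- stratum_residuals(d, fit$beta_hat, coef = coef)
    sizes <- lengths(res)
    if (min(sizes) < 3L)
      stop("design error: need at least 3 strata per cluster to estimate ",
           "a decorrelation lag", call. = FALSE)
    L <- if (is.null(lag_max)) min(min(sizes) - 2L, 25L) else lag_max
    acfs <- vapply(res, function(r)
      drop(stats::acf(r, lag.max = L, plot = FALSE,
                      demean = TRUE)$acf)[-1L], numeric(L))
    mean_acf <- if (is.matrix(acfs)) rowMeans(acfs) else mean(acfs)
    band <- stats::qnorm(1 - alpha / 2) / sqrt(sum(sizes))
    below <- which(abs(mean_acf) < band)
    if (length(below) == 0L) L else below[1L]
  }, integer(1))
  structure(max(lags), lags = lags)
}

#' Destructive sampling: split each cluster into two decorrelated halves
#'
#' Each original cluster of `S` strata becomes two clusters: the first
#' `floor((S - L_K) / 2)` strata and the last `floor((S - L_K) / 2)`
#' strata, with the middle `L_K` strata (plus any odd remainder)
#' dropped so the halves are at least `L_K` strata apart. The output
#' has `2 K` clusters and provenance `"destructive"`.
#'
#' @param data A balanced [matched_dataset()].
#' @param L_K Decorrelation lag in strata (>= 0), typically from
#'   [estimate_decorrelation_lag()].
#' @return A [matched_dataset()] with `2 K` clusters.
#' @examples
#' cfg <- sim_config(K = 2, S = 8, T = 4000)
#' d2 <- destructive_sample(simulate_dataset(cfg), L_K = 2)
#' table(d2$cluster_id)   # 4 clusters of 3 strata
#' @export
destructive_sample <- function(data, L_K) {
  require_balanced(data, "destructive_sample")
  stopifnot(length(L_K) == 1L, L_K >= 0)
  L_K <- as.integer(L_K)
  df <- as.data.frame(data)
  parts <- lapply(split(df, df$cluster_id), function(cl) {
    sid <- sort(unique(cl$stratum_id))
    h <- (length(sid) - L_K) %/% 2L
    if (h < 1L)
      stop("nothing retainable: L_K = ", L_K, " leaves no strata from ",
           "clusters of ", length(sid), call. = FALSE)
    k <- cl$cluster_id[1L]
    lo <- cl[cl$stratum_id %in% sid[seq_len(h)], ]
    hi <- cl[cl$stratum_id %in% sid[seq.int(length(sid) - h + 1L,
                                            length(sid))], ]
    lo$cluster_id <- 2L * k - 1L
    hi$cluster_id <- 2L * k
    rbind(lo, hi)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  matched_dataset(out, provenance = "destructive", m = attr(data, "m") %||% 1L,
                  validate = FALSE)
}

#' Unbalance a dataset by truncating some clusters' strata
#'
#' `weak`: the first `floor(K / 3)` clusters keep only their first
#' `floor(S / 2)` strata; the rest keep all `S`. `strong`: the first
#' `floor(K / 3)` clusters keep their first `floor(S / 4)` strata, the
#' next `floor(K / 3)` keep their first `floor(S / 2)`, the remainder
#' keep all. Cluster count is unchanged; selection of which clusters
#' shrink is deterministic (first by index) -- clusters are exchangeable
#' by construction so this is distributionally irrelevant.
#'
#' @param data A balanced [matched_dataset()].
#' @param mode `"weak"` or `"strong"`.
#' @return A [matched_dataset()] with provenance `"weak_unbalanced"` or
#'   `"strong_unbalanced"`.
#' @export
unbalance <- function(data, mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  require_balanced(data, "unbalance")
  df <- as.data.frame(data)
  ids <- sort(unique(df$cluster_id))
  K <- length(ids)
  if (K < 3L) stop("design error: unbalancing needs K >= 3", call. = FALSE)
  n3 <- K %/% 3L
  frac <- rep(1, K)
  if (mode == "weak") {
    frac[seq_len(n3)] <- 1 / 2
  } else {
    frac[seq_len(n3)] <- 1 / 4
    frac[seq.int(n3 + 1L, 2L * n3)] <- 1 / 2
  }
  parts <- lapply(seq_len(K), function(i) {
    cl <- df[df$cluster_id == ids[i], ]
    sid <- sort(unique(cl$stratum_id))
    keep <- floor(length(sid) * frac[i])
    if (keep < 1L)
      stop("design error: unbalancing would leave cluster ", ids[i],
           " with 0 strata", call. = FALSE)
    cl[cl$stratum_id %in% sid[seq_len(keep)], ]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  matched_dataset(out,
                  provenance = paste0(mode, "_unbalanced"),
                  m = attr(data, "m") %||% 1L, validate = FALSE)
}
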