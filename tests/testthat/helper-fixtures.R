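# Shared fixtures and independent oracles for the test suite.
# Everything is built in code; no stored data files.

# Build a flat matched dataset from a list of strata. Each stratum is a
# list(cluster, X) with the case in row 1 (one case per stratum).
df_from_strata <- function(strata) {
  parts <- lapply(seq_along(strata), function(j) {
    s <- strata[[j]]
    X <- as.matrix(s$X)
    data.frame(cluster_id = s$cluster,
               stratum_id = s$stratum %||% j,
               case_flag = c(1L, rep(0L, nrow(X) - 1L)),
               X)
  })
  df <- do.call(rbind, parts)
  names(df)[4:ncol(df)] <- paste0("x", seq_len(ncol(df) - 3L))
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random toy dataset: S strata of N rows, P covariates, one cluster per
# `clusters` block of strata.
random_toy <- function(S, N, P = 1, clusters = 1, seed = 1) {
  set.seed(seed)
  strata <- lapply(seq_len(S), function(j)
    list(cluster = ((j - 1L) %% clusters) + 1L,
         stratum = j,
         X = matrix(rnorm(N * P), N, P)))
  df_from_strata(strata)
}

# Synthetic processed-shape dataset: K clusters x S strata of N = 2 rows
# (case first). Cheap fixture for the re-clustering schemes.
grid_dataset <- function(K, S, P = 1, seed = 1) {
  set.seed(seed)
  parts <- lapply(seq_len(K), function(k)
    lapply(seq_len(S), function(j)
      list(cluster = k, stratum = j, X = matrix(rnorm(2 * P), 2, P))))
  matched_dataset(df_from_strata(do.call(c, parts)), provenance = "balanced")
}

# Conditional log-likelihood computed through an independent softmax
# path (no shared code with clr_eval).
oracle_loglik <- function(df, beta) {
  key <- paste(df$cluster_id, df$stratum_id)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  sum(vapply(split(seq_len(nrow(df)), key), function(ix) {
    eta <- as.matrix(df[ix, xcols, drop = FALSE]) %*% beta
    case <- which(df$case_flag[ix] == 1L)
    log(exp(eta[case] - max(eta)) / sum(exp(eta - max(eta))))
  }, numeric(1)))
}

# Central finite differences of a scalar function.
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(f, x, h = 1e-4) {
  P <- length(x)
  H <- matrix(0, P, P)
  for (i in seq_len(P)) for (j in seq_len(P)) {
    ei <- replace(numeric(P), i, h)
    ej <- replace(numeric(P), j, h)
    H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                  f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
  }
  (H + t(H)) / 2
}

# Brute-force 1-D maximizer: coarse grid then golden-section refinement.
# Independent of the Newton path.
brute_force_beta1 <- function(df, lo = -5, hi = 5) {
  f <- function(b) oracle_loglik(df, b)
  grid <- seq(lo, hi, length.out = 401)
  b0 <- grid[which.max(vapply(grid, f, numeric(1)))]
  a <- b0 - 0.05; b <- b0 + 0.05
  phi <- (sqrt(5) - 1) / 2
  for (i in 1:60) {
    c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
    if (f(c1) < f(c2)) a <- c1 else b <- c2
  }
  (a + b) / 2
}

# Type-7 sample quantile implemented from the order statistics.
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[pmin(lo + 1, n)] - xs[lo])
}

strata_count <- function(d) nrow(unique(as.data.frame(d)[, c("cluster_id", "stratum_id")]))
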