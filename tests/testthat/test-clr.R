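test_that("within-stratum case probabilities are a proper softmax", {
  expect_equal(stratum_case_probabilities(matrix(rnorm(10), 10, 1), 0),
               rep(0.1, 10))
  X <- matrix(rep(c(1.3, -0.2), each = 6), 6, 2)   # identical rows
  expect_equal(stratum_case_probabilities(X, c(2, -1)), rep(1 / 6, 6))
  expect_equal(stratum_case_probabilities(matrix(c(1, 0), 2, 1), log(4)),
               c(0.8, 0.2), tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    pr <- stratum_case_probabilities(matrix(rnorm(8 * 3), 8, 3), rnorm(3))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr > 0))
  }
  # large linear predictors must not overflow
  pr <- stratum_case_probabilities(matrix(c(500, 0), 2, 1), 2)
  expect_equal(pr, c(1, 0), tolerance = 1e-12)
})

test_that("conditional log-likelihood, score and information are coherent", {
  df <- random_toy(S = 6, N = 10, P = 2, seed = 4)
  at0 <- conditional_loglik_score(df, c(0, 0))
  expect_equal(at0$loglik, 6 * log(0.1), tolerance = 1e-12)
  for (seed in 1:4) {
    set.seed(seed)
    beta <- rnorm(2)
    ev <- conditional_loglik_score(df, beta)
    expect_lte(ev$loglik, 0)
    expect_equal(ev$loglik, oracle_loglik(df, beta), tolerance = 1e-10)
    expect_equal(ev$score,
                 fd_gradient(function(b) oracle_loglik(df, b), beta),
                 tolerance = 1e-5)
    # information = negative Hessian of the conditional log-likelihood
    expect_equal(ev$information,
                 -fd_hessian(function(b) oracle_loglik(df, b), beta),
                 tolerance = 1e-4)
  }
  bad <- df; bad$case_flag[1:2] <- 1L
  expect_error(fit_clr(bad), "design error")
})

test_that("mirror-image strata are fitted at zero by antisymmetry", {
  df <- df_from_strata(list(
    list(cluster = 1, X = matrix(c(1, 0), 2, 1)),
    list(cluster = 2, X = matrix(c(-1, 0), 2, 1))))
  fit <- fit_clr(df)
  expect_equal(fit$beta_hat, 0, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("Newton solution matches brute-force maximization on 1-D toys", {
  for (seed in c(2, 9)) {
    df <- random_toy(S = 5, N = 4, P = 1, seed = seed)
    fit <- fit_clr(df)
    expect_equal(fit$beta_hat, brute_force_beta1(df), tolerance = 1e-4)
    expect_lt(fit$score_norm, 1e-8)
  }
})

test_that("complete separation raises a separation error", {
  df <- df_from_strata(list(list(cluster = 1, X = matrix(c(1, 0), 2, 1))))
  expect_error(fit_clr(df), "separation")
  # several strata, case always on top
  df2 <- df_from_strata(lapply(1:4, function(j)
    list(cluster = 1, X = matrix(c(2, 1, 0), 3, 1))))
  expect_error(fit_clr(df2), "separation")
})

test_that("naive variance is the inverse information", {
  df <- df_from_strata(list(list(cluster = 1, X = matrix(c(1, 0), 2, 1))))
  expect_equal(naive_variance(df, 0)[1, 1], 4)   # 1 / (p (1 - p)), p = 1/2
  df2 <- random_toy(S = 8, N = 6, P = 2, seed = 11, clusters = 2)
  fit <- fit_clr(df2)
  H <- fd_hessian(function(b) oracle_loglik(df2, b), fit$beta_hat)
  expect_equal(fit$V_N, solve(-H), tolerance = 1e-4)
  # information additivity: duplicating every stratum halves the variance
  dup <- df2
  dup$stratum_id <- dup$stratum_id + 100L
  both <- rbind(df2, dup)
  expect_equal(naive_variance(both, fit$beta_hat),
               naive_variance(df2, fit$beta_hat) / 2, tolerance = 1e-10)
})

test_that("sandwich equals the direct per-cluster matrix oracle", {
  df <- random_toy(S = 6, N = 5, P = 2, seed = 21, clusters = 2)
  fit <- fit_clr(df)
  xcols <- c("x1", "x2")
  # hand-rolled: per-stratum score contributions via the softmax, summed
  # by cluster, outer products, wrapped in the bread
  U <- matrix(0, 2, 2)
  for (k in 1:2) {
    Uk <- numeric(2)
    cl <- df[df$cluster_id == k, ]
    for (j in unique(cl$stratum_id)) {
      s <- cl[cl$stratum_id == j, ]
      pr <- stratum_case_probabilities(as.matrix(s[, xcols]), fit$beta_hat)
      Uk <- Uk + as.numeric(s[s$case_flag == 1, xcols]) -
        colSums(pr * as.matrix(s[, xcols]))
    }
    U[k, ] <- Uk
  }
  meat <- t(U) %*% U
  B <- fit$V_N
  expect_equal(fit$V_R, B %*% meat %*% B, tolerance = 1e-10)
  expect_equal(unname(fit$components$per_cluster_scores), U,
               tolerance = 1e-10)
  # the cluster scores sum to the total score, which vanishes at the fit
  expect_lt(max(abs(colSums(fit$components$per_cluster_scores))), 1e-7)
})

test_that("a single cluster degenerates the sandwich to zero, with a warning", {
  df <- random_toy(S = 10, N = 4, P = 1, seed = 3, clusters = 1)
  fit <- fit_clr(df)
  expect_warning(rv <- robust_variance(df, fit$beta_hat), "single cluster")
  expect_equal(max(abs(rv$V_R)), 0, tolerance = 1e-12)
})

test_that("fits are invariant to row, stratum and cluster relabelling", {
  df <- random_toy(S = 12, N = 5, P = 2, seed = 8, clusters = 3)
  fit <- fit_clr(df)
  set.seed(1)
  shuffled <- df[sample(nrow(df)), ]
  fit2 <- fit_clr(shuffled)
  relab <- df
  relab$cluster_id <- c(3L, 1L, 2L)[relab$cluster_id]
  fit3 <- fit_clr(relab)
  for (f in list(fit2, fit3)) {
    expect_equal(f$beta_hat, fit$beta_hat, tolerance = 1e-10)
    expect_equal(f$V_N, fit$V_N, tolerance = 1e-10)
    expect_equal(f$V_R, fit$V_R, tolerance = 1e-10)
  }
  expect_equal(fit$V_N, t(fit$V_N))
  expect_equal(fit$V_R, t(fit$V_R))
  expect_true(all(eigen(fit$V_N, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("estimates and both variances agree with the stratified Cox route", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  cfg <- sim_config(K = 10, S = 12, T = 4000, sigma_H2 = 0.5, rho = 0.3,
                    seed = 33)
  d <- simulate_dataset(cfg)
  fit <- fit_clr(d)
  df <- as.data.frame(d)
  df$sid <- paste(df$cluster_id, df$stratum_id)
  cf <- survival::clogit(
    case_flag ~ x1 + x2 + strata(sid) + cluster(cluster_id),
    data = df, method = "breslow")
  expect_equal(unname(coef(cf)), fit$beta_hat, tolerance = 1e-6)
  expect_equal(unname(cf$naive.var), fit$V_N, tolerance = 1e-6)
  expect_equal(unname(vcov(cf)), fit$V_R, tolerance = 1e-6)
})

test_that("under independence the sandwich agrees with the naive variance on average", {
  # independent strata, each its own cluster: both estimators target the
  # same quantity; their replicate means must agree within Monte Carlo
  # error (the sandwich carries a small-sample deflation ~ (K-1)/K).
  cfg <- sim_config(K = 1, S = 30, N = 5, T = 2500, sigma_H2 = 0,
                    rho = 0, seed = 12)
  R <- 120
  vr <- vn <- numeric(R)
  for (r in seq_len(R)) {
    d <- as.data.frame(simulate_dataset(cfg, replicate = r))
    d$cluster_id <- d$stratum_id          # one cluster per stratum
    fit <- fit_clr(d)
    vr[r] <- fit$V_R[1, 1]; vn[r] <- fit$V_N[1, 1]
  }
  expect_equal(mean(vr) / mean(vn), 1, tolerance = 0.08)
})
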