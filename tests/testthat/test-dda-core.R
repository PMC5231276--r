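test_that("huge lambda kills couplings and reduces fields to marginal logits", {
  sp <- sim_spec(400, 2, 3, couplings_case = list(coupling(1, 2, 0.8)),
                 seed = 51)
  X <- simulate_genotypes(sp)$gm$genotypes[1:400 + 2, ]
  f <- fit_group_pseudolikelihood(X, lambda = 1e6)
  expect_lt(max(abs(f$couplings)), 1e-4)
  for (i in 1:3) {
    cnt <- tabulate(X[, i] + 1L, 3)
    expect_equal(f$fields[i, ], log(cnt[2:3] / cnt[1]), tolerance = 1e-9)
  }
  # a large but sub-threshold lambda also drives couplings toward zero
  f2 <- fit_group_pseudolikelihood(X, lambda = 1e4)
  expect_lt(max(abs(f2$couplings)), 1e-1)
})

test_that("pseudo-likelihood at lambda 0 recovers truth within 3 s.e. (m=2)", {
  H <- matrix(c(0.4, -0.3, -0.2, 0.5), 2, 2)
  J <- matrix(c(0.7, -0.2, 0.3, -0.5), 2, 2)
  sp <- sim_spec(5000, 2, 2, fields_case = H,
                 couplings_case = list(coupling(1, 2, J)),
                 gibbs_sweeps = 150, seed = 52)
  X <- simulate_genotypes(sp)$gm$genotypes[1:5000 + 2, ]
  f <- fit_group_pseudolikelihood(X, lambda = 0, tol = 1e-10)
  theta_true <- c(as.vector(t(H)), as.vector(t(J)))
  se <- enum_ml_se(theta_true, 2, nrow(X))
  theta_hat <- c(as.vector(t(f$fields)), as.vector(t(f$couplings)))
  expect_true(all(abs(theta_hat - theta_true) < 3.5 * se))
  # and coincides with the saturated closed-form MLE on m=2
  sat <- saturated_m2_params(counts_m2(X))
  expect_equal(f$fields, sat$H, tolerance = 1e-4)
  expect_equal(as.vector(t(matrix(f$couplings, 1)[1, ])),
               as.vector(t(sat$J)), tolerance = 1e-4)
})

test_that("duplicating every individual leaves the fit unchanged", {
  sp <- sim_spec(150, 2, 2, couplings_case = list(coupling(1, 2, 0.6)),
                 seed = 53)
  X <- simulate_genotypes(sp)$gm$genotypes[1:150 + 2, ]
  f1 <- fit_group_pseudolikelihood(X, lambda = 0.1, tol = 1e-10)
  f2 <- fit_group_pseudolikelihood(rbind(X, X), lambda = 0.2, tol = 1e-10)
  # penalty must scale with the data for exact argmax invariance
  expect_equal(f1$fields, f2$fields, tolerance = 1e-5)
  expect_equal(f1$couplings, f2$couplings, tolerance = 1e-5)
})

test_that("optimum is unique: random initializations agree (concavity)", {
  sp <- sim_spec(200, 2, 3, couplings_case = list(coupling(1, 3, 0.5)),
                 seed = 54)
  X <- simulate_genotypes(sp)$gm$genotypes[1:200 + 2, ]
  pairs <- snp_pairs(3)
  K <- 2 * 3 + 4 * nrow(pairs)
  grp <- list(X = X, map = seq_len(K), fixed = numeric(K))
  set.seed(1)
  vals <- vapply(1:4, function(i) {
    th0 <- rnorm(K, sd = 0.5)
    epistcell:::optim_plik(list(grp), pairs, 0.05, th0, 1e-10, 2000)$value
  }, numeric(1))
  expect_lt(diff(range(vals)), 1e-6)
})

test_that("missing-data policy drops conditionals and pair terms", {
  sp <- sim_spec(300, 2, 2, couplings_case = list(coupling(1, 2, 0.7)),
                 missing_rate = 0.15, seed = 55)
  X <- simulate_genotypes(sp)$gm$genotypes[1:300 + 2, ]
  f <- fit_group_pseudolikelihood(X, lambda = 0.05)
  expect_true(f$converged)
  expect_true(all(is.finite(f$fields)), all(is.finite(f$couplings)))
  # complete-case subset gives a broadly similar coupling estimate
  cc <- X[stats::complete.cases(X), ]
  f2 <- fit_group_pseudolikelihood(cc, lambda = 0.05)
  expect_lt(abs(f$couplings[1, 1] - f2$couplings[1, 1]), 0.8)
})

test_that("mean-field couplings vanish for independent SNPs and balanced designs", {
  set.seed(56)
  X <- matrix(rbinom(20000, 2, 0.35), 10000, 2)
  f <- fit_group_meanfield(X, ridge = 0.01)
  expect_lt(max(abs(f$couplings)), 0.06)
  # exactly balanced 9-cell design: dummy covariance off-diagonal blocks are
  # exactly zero, hence couplings exactly zero
  Xb <- as.matrix(expand.grid(0:2, 0:2))[rep(1:9, 10), ]
  fb <- fit_group_meanfield(Xb, ridge = 0.1)
  expect_lt(max(abs(fb$couplings)), 1e-10)
  # duplicated column without ridge: singular covariance is an error
  expect_error(fit_group_meanfield(cbind(X[, 1], X[, 1]), ridge = 0),
               "ridge")
})

test_that("mean-field approximates pseudo-likelihood for weak coupling", {
  sp <- sim_spec(10000, 2, 2,
                 couplings_case = list(coupling(1, 2, 0.25)), seed = 57)
  X <- simulate_genotypes(sp)$gm$genotypes[1:10000 + 2, ]
  f_pl <- fit_group_pseudolikelihood(X, lambda = 0, tol = 1e-9)
  f_mf <- fit_group_meanfield(X, ridge = 1e-4)
  expect_lt(abs(f_mf$couplings[1, 1] - f_pl$couplings[1, 1]),
            0.25 * abs(f_pl$couplings[1, 1]))
})

test_that("bayes_risk matches closed-form posteriors and prior behavior", {
  # identical parameters, prior 0.5 -> probability exactly 0.5
  sp <- sim_spec(100, 100, 2, seed = 58)
  gm <- simulate_genotypes(sp)$gm
  model <- fit_dda(gm, lambda = 0.1)
  model$fields$control <- model$fields$case
  model$couplings$control <- model$couplings$case
  model$calib <- epistcell:::calibrate_intercept(
    epistcell:::score_log_ratio(model, gm$genotypes),
    as.integer(gm$phenotypes == 2L))
  p <- bayes_risk(model, gm$genotypes, prior_case = 0.5)
  expect_equal(p, rep(0.5, nrow(gm$genotypes)), tolerance = 1e-9)
  # prior 1 forces probability 1; prior 0 forces 0; monotone in between
  model2 <- fit_dda(gm, lambda = 0.1)
  expect_equal(bayes_risk(model2, gm$genotypes[1, ], prior_case = 1), 1)
  expect_equal(bayes_risk(model2, gm$genotypes[1, ], prior_case = 0), 0)
  pr <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(q)
    bayes_risk(model2, gm$genotypes[1, ], prior_case = q), numeric(1))
  expect_true(all(diff(pr) > 0))
  # m=1: closed-form posterior from the two 3-state distributions
  h_case <- c(0.8, -0.5); h_ctrl <- c(-0.2, 0.4)
  sp1 <- sim_spec(3000, 3000, 1, fields_case = h_case,
                  fields_control = h_ctrl, seed = 59)
  gm1 <- simulate_genotypes(sp1)$gm
  m1 <- fit_dda(gm1, lambda = 0.01)
  pc <- c(1, exp(h_case)) / (1 + sum(exp(h_case)))
  pk <- c(1, exp(h_ctrl)) / (1 + sum(exp(h_ctrl)))
  post_exact <- pc / (pc + pk)                    # oracle, prior 0.5
  for (g in 0:2) {
    got <- bayes_risk(m1, g, prior_case = 0.5)
    expect_lt(abs(got - post_exact[g + 1]), 0.05)
  }
})

test_that("AUC follows the Mann-Whitney pair-counting definition", {
  expect_equal(auc_mw(c(3, 4, 1, 2), c(2, 2, 1, 1))$auc, 1)
  expect_equal(auc_mw(rep(1, 10), rep(c(1, 2), 5))$auc, 0.5)
  # oracle: exhaustive counting over the 4 case-control pairs
  a <- auc_mw(c(0.9, 0.4, 0.6, 0.1), c(2, 2, 1, 1))
  expect_equal(a$auc, 3 / 4)
  expect_error(auc_mw(1:4, rep(1, 4)), "both classes")
  # independent check against pROC on a random vector
  set.seed(60)
  sc <- runif(50); lb <- rbinom(50, 1, 0.5) + 1
  expect_equal(auc_mw(sc, lb)$auc,
               as.numeric(suppressMessages(pROC::auc(lb, sc))),
               tolerance = 1e-12)
})

test_that("collective single-SNP p reduces to the independent test", {
  sp <- sim_spec(150, 150, 1, fields_case = c(0.5, -0.2), seed = 61)
  gm <- simulate_genotypes(sp)$gm
  model <- fit_dda(gm, lambda = 0.01)
  res <- collective_single_snp_pvalue(model, gm, 1)
  ref <- genotypic_test(gm, 1)
  expect_equal(res$statistic, ref$statistic, tolerance = 1e-12)
  # with interactions on, the collective p differs from p_i in general
  sp2 <- sim_spec(400, 400, 3,
                  couplings_case = list(coupling(1, 2, 0.9)),
                  fields_case = c(0.3, 0.1), seed = 62)
  gm2 <- simulate_genotypes(sp2)$gm
  m2 <- fit_dda(gm2, lambda = 0.05, tol = 1e-9)
  res2 <- collective_single_snp_pvalue(m2, gm2, 1)
  expect_gte(res2$statistic, 0)
  expect_identical(res2$df, 2L)
  expect_true(is.na(res2$flag))
})

test_that("parameter RMSE decreases with sample size (consistency)", {
  H <- matrix(c(0.2, -0.1, 0.3, 0.1), 2, 2)
  J <- matrix(c(0.5, 0.1, -0.2, 0.3), 2, 2)
  theta_true <- c(as.vector(t(H)), as.vector(t(J)))
  rmse <- vapply(c(500, 2000, 8000), function(n) {
    sp <- sim_spec(n, 2, 2, fields_case = H,
                   couplings_case = list(coupling(1, 2, J)),
                   gibbs_sweeps = 120, seed = 63)
    X <- simulate_genotypes(sp)$gm$genotypes[seq_len(n) + 2, ]
    f <- fit_group_pseudolikelihood(X, lambda = 0, tol = 1e-9)
    th <- c(as.vector(t(f$fields)), as.vector(t(f$couplings)))
    sqrt(mean((th - theta_true)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})
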