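# ---- parameter plumbing -----------------------------------------------------
#
# A group's parameter vector packs the fields (2 per SNP, levels 1 and 2) and
# then the couplings (4 per pair, order (1,1),(1,2),(2,1),(2,2)):
#   theta = c(as.vector(t(fields)), as.vector(t(couplings)))
# Reduced-parameter fits (tied pairs, tied fields, fixed couplings) are
# expressed through per-group injective maps full-coordinate -> reduced index
# (0 = held fixed at the value supplied in `fixed`).

n_par_group <- function(m, P) 2L * m + 4L * P

theta_pack <- function(fields, couplings) {
  c(as.vector(t(fields)), if (length(couplings)) as.vector(t(couplings)))
}

theta_unpack <- function(theta, m, P) {
  list(fields = matrix(theta[seq_len(2L * m)], m, 2L, byrow = TRUE),
       couplings = if (P > 0L)
         matrix(theta[2L * m + seq_len(4L * P)], P, 4L, byrow = TRUE)
       else matrix(0, 0L, 4L))
}

# maximize sum over groups of the penalized pseudo-likelihood over a reduced
# parameter vector; groups: list of list(X, map, fixed); pairs shared.
optim_plik <- function(groups, pairs, lambda, theta0, tol, max_iter) {
  pi0 <- pairs[, 1L] - 1L
  pj0 <- pairs[, 2L] - 1L
  expand <- function(red, grp) {
    full <- grp$fixed
    free <- grp$map > 0L
    full[free] <- red[grp$map[free]]
    full
  }
  cache <- new.env(parent = emptyenv())
  evaluate <- function(red) {
    if (!is.null(cache$key) && identical(cache$key, red)) return()
    val <- 0
    grad <- numeric(length(red))
    for (grp in groups) {
      full <- expand(red, grp)
      vg <- plik_value_grad(full, grp$X, pi0, pj0, lambda, TRUE)
      val <- val + vg$value
      free <- grp$map > 0L
      grad[grp$map[free]] <- grad[grp$map[free]] + vg$grad[free]
    }
    cache$key <- red; cache$value <- val; cache$grad <- grad
  }
  fn <- function(red) { evaluate(red); cache$value }
  gr <- function(red) { evaluate(red); cache$grad }
  res <- optim(theta0, fn, gr, method = "L-BFGS-B",
               control = list(fnscale = -1, maxit = max_iter,
                              factr = tol / .Machine$double.eps))
  list(par = res$par, value = res$value, converged = res$convergence == 0L,
       message = res$message)
}

# closed-form independent-SNP fields: h(a) = log(n_a / n_0), clamped so that
# empty cells stay finite (|h| <= 30 on the log scale)
fields_marginal <- function(X) {
  m <- ncol(X)
  H <- matrix(0, m, 2L)
  for (i in seq_len(m)) {
    cnt <- tabulate(X[, i] + 1L, nbins = 3L)
    h <- log(pmax(cnt[2:3], 1e-13) / max(cnt[1L], 1e-13))
    H[i, ] <- pmin(pmax(h, -30), 30)
  }
  H
}

#' Penalizer value treated as the non-interacting limit
#'
#' Penalizer values at or above this constant (`1e6`) are interpreted as
#' `lambda = Inf`: couplings are exactly zero and the fields reduce to the
#' independent-SNP multinomial logits of the marginal genotype frequencies.
#' This makes the documented reduction of collective single-SNP p-values to
#' the independent-SNP test exact rather than approximate.
#' @export
LAMBDA_NONINTERACTING <- 1e6

#' Fit one group's pairwise genotype model by penalized pseudo-likelihood
#'
#' Maximizes `sum_rows sum_i log P(g_i | g_-i) - lambda * sum_pairs ||J||_F^2`
#' where `P(g_i = a | g_-i) ~ exp(h_i(a) + sum_j J_ij(a, g_j))`, with the
#' baseline level 0 carrying zero parameters.  The penalty acts on couplings
#' only, so fields survive the `lambda -> Inf` (non-interacting) limit.  The
#' objective is concave; optimization starts from zero (deterministic) and
#' uses L-BFGS with a relative-objective-change tolerance.  Missing genotypes:
#' a missing `g_j` drops the `(i, j)` term from SNP `i`'s conditional, a
#' missing `g_i` drops that individual's `i`-th conditional.
#'
#' @param X integer matrix of one group's genotypes (`{0, 1, 2}`, `NA`
#'   missing), individuals in rows.
#' @param lambda nonnegative coupling penalizer; values `>=`
#'   [LAMBDA_NONINTERACTING] switch to the exact non-interacting limit.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param pairs optional 2-column matrix restricting which pairs carry
#'   couplings (default: all pairs).
#' @return List with `fields` (`m x 2`), `couplings` (`P x 4`, column order
#'   `J(1,1), J(1,2), J(2,1), J(2,2)`), `pairs`, `value` (objective at the
#'   optimum), `converged`.
#' @export
fit_group_pseudolikelihood <- function(X, lambda, tol = 1e-6, max_iter = 500L,
                                       pairs = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "integer"
  if (nrow(X) < 2L) stop("need at least 2 individuals")
  if (!is.finite(lambda) || lambda < 0) {
    if (is.infinite(lambda) && lambda > 0) lambda <- LAMBDA_NONINTERACTING
    else stop("lambda must be a nonnegative number")
  }
  m <- ncol(X)
  if (is.null(pairs)) pairs <- snp_pairs(m)
  P <- nrow(pairs)
  if (lambda >= LAMBDA_NONINTERACTING || P == 0L) {
    H <- fields_marginal(X)
    theta <- theta_pack(H, matrix(0, P, 4L))
    val <- plik_value_grad(theta, X, pairs[, 1L] - 1L, pairs[, 2L] - 1L,
                           0, FALSE)$value
    return(list(fields = H, couplings = matrix(0, P, 4L), pairs = pairs,
                value = val, converged = TRUE))
  }
  K <- n_par_group(m, P)
  grp <- list(X = X, map = seq_len(K), fixed = numeric(K))
  # deterministic initialization: fields at their closed-form marginal
  # logits, couplings at zero -- the concave objective has a unique optimum,
  # so this only shortens the optimization path
  theta0 <- c(as.vector(t(fields_marginal(X))), numeric(4L * P))
  res <- optim_plik(list(grp), pairs, lambda, theta0, tol, max_iter)
  if (!res$converged)
    warning("pseudo-likelihood fit did not converge: ", res$message)
  out <- theta_unpack(res$par, m, P)
  out$pairs <- pairs
  out$value <- res$value
  out$converged <- res$converged
  out
}

#' Fit one group's model by the mean-field (inverse covariance) approximation
#'
#' Couplings are taken from the negative inverse of the ridge-regularized
#' sample covariance of the `2m` dummy indicators `1[g_i = 1], 1[g_i = 2]`;
#' fields are the marginal logits minus the mean-field correction
#' `sum_j J_ij(a, b) p_j(b)`.  Runtime is `O(m^3)` independent of the number
#' of pairs, which is what makes pathway-scale models feasible.
#'
#' @inheritParams fit_group_pseudolikelihood
#' @param ridge nonnegative ridge added to the covariance diagonal; with
#'   `ridge = 0` a singular covariance is an error instructing a ridge value.
#' @return Same structure as [fit_group_pseudolikelihood()].
#' @export
fit_group_meanfield <- function(X, ridge = 0.1) {
  X <- as.matrix(X); storage.mode(X) <- "integer"
  m <- ncol(X)
  D <- matrix(NA_real_, nrow(X), 2L * m)
  for (i in seq_len(m)) {
    D[, 2L * i - 1L] <- as.numeric(X[, i] == 1L)
    D[, 2L * i] <- as.numeric(X[, i] == 2L)
  }
  p <- colMeans(D, na.rm = TRUE)
  C <- cov(D, use = "pairwise.complete.obs")
  C[is.na(C)] <- 0
  diag(C) <- diag(C) + ridge
  K <- tryCatch(solve(C), error = function(e)
    stop("singular dummy-genotype covariance; supply a positive `ridge` ",
         "(e.g. ridge = 0.1)", call. = FALSE))
  pairs <- snp_pairs(m)
  J <- matrix(0, nrow(pairs), 4L)
  for (p_idx in seq_len(nrow(pairs))) {
    i <- pairs[p_idx, 1L]; j <- pairs[p_idx, 2L]
    blk <- -K[c(2L * i - 1L, 2L * i), c(2L * j - 1L, 2L * j)]
    J[p_idx, ] <- as.vector(t(blk))
  }
  H <- matrix(0, m, 2L)
  p0 <- pmax(1 - vapply(seq_len(m), function(i) p[2L * i - 1L] + p[2L * i],
                        numeric(1)), 1e-12)
  for (i in seq_len(m)) {
    for (a in 1:2) {
      h <- log(max(p[2L * (i - 1L) + a], 1e-12) / p0[i])
      corr <- 0
      for (p_idx in which(pairs[, 1L] == i | pairs[, 2L] == i)) {
        j <- if (pairs[p_idx, 1L] == i) pairs[p_idx, 2L] else pairs[p_idx, 1L]
        for (b in 1:2) {
          Jab <- if (pairs[p_idx, 1L] == i) J[p_idx, 2L * (a - 1L) + b]
                 else J[p_idx, 2L * (b - 1L) + a]
          corr <- corr + Jab * p[2L * (j - 1L) + b]
        }
      }
      H[i, a] <- h - corr
    }
  }
  list(fields = H, couplings = J, pairs = pairs, value = NA_real_,
       converged = TRUE)
}

#' Fit the two-group collective model
#'
#' Fits the case and control genotype distributions separately (shared SNP
#' panel and pair list) and calibrates the Bayes-risk intercept on the
#' training data by an intercept-only logistic recalibration of the
#' unnormalized log-ratio, absorbing the intractable normalizing constants.
#'
#' @param gm a [genotype_matrix()] already restricted to the selected SNPs.
#' @param lambda coupling penalizer (pseudo-likelihood method).
#' @param method `"pl"` (penalized pseudo-likelihood) or `"mf"` (mean-field).
#' @param ridge ridge used by the mean-field method.
#' @param prior_case prior disease probability used by [bayes_risk()];
#'   defaults to the training prevalence.
#' @param tol,max_iter optimizer controls for `method = "pl"`.
#' @param interactions set `FALSE` to force all couplings to zero (the
#'   non-interacting model) regardless of `lambda`.
#' @return An object of class `dda_model`.
#' @export
fit_dda <- function(gm, lambda = 0.01, method = c("pl", "mf"), ridge = 0.1,
                    prior_case = NULL, tol = 1e-6, max_iter = 500L,
                    interactions = TRUE) {
  method <- match.arg(method)
  Xc <- gm$genotypes[case_rows(gm), , drop = FALSE]
  Xk <- gm$genotypes[control_rows(gm), , drop = FALSE]
  if (nrow(Xc) == 0L || nrow(Xk) == 0L)
    stop("both phenotype groups must be present")
  if (!interactions) lambda <- LAMBDA_NONINTERACTING
  fit1 <- function(X) {
    if (method == "pl")
      fit_group_pseudolikelihood(X, lambda, tol = tol, max_iter = max_iter)
    else if (!interactions)
      fit_group_pseudolikelihood(X, LAMBDA_NONINTERACTING)
    else fit_group_meanfield(X, ridge = ridge)
  }
  fc <- fit1(Xc)
  fk <- fit1(Xk)
  prev <- nrow(Xc) / (nrow(Xc) + nrow(Xk))
  model <- structure(list(
    snp_ids = gm$snps$id, pairs = fc$pairs,
    fields = list(case = fc$fields, control = fk$fields),
    couplings = list(case = fc$couplings, control = fk$couplings),
    lambda = lambda, fit_method = method, ridge = ridge,
    prior_case = if (is.null(prior_case)) prev else prior_case,
    train_prev = prev, calib = 0,
    converged = fc$converged && fk$converged,
    objective = c(case = fc$value, control = fk$value)
  ), class = "dda_model")
  s <- score_log_ratio(model, gm$genotypes)
  y <- as.integer(gm$phenotypes == 2L)
  model$calib <- calibrate_intercept(s, y, fallback = qlogis(prev))
  model
}

# intercept-only logistic recalibration of an offset score: the scalar c
# maximizing sum y*log p + (1-y)*log(1-p) with p = plogis(s + c).  The
# 1-D log-likelihood is concave; damped Newton from 0 converges in a few
# steps.  Equivalent to glm(y ~ 1, offset = s, family = binomial).
calibrate_intercept <- function(s, y, fallback = 0, tol = 1e-10,
                                max_iter = 50L) {
  cc <- 0
  for (it in seq_len(max_iter)) {
    p <- plogis(s + cc)
    g <- sum(y - p)
    h <- sum(p * (1 - p))
    if (h < 1e-12) break
    step <- g / h
    step <- max(min(step, 5), -5)
    cc <- cc + step
    if (abs(step) < tol) break
  }
  if (!is.finite(cc) || abs(cc) > 50) cc <- fallback
  cc
}

#' @export
print.dda_model <- function(x, ...) {
  cat(sprintf("dda_model: %d SNPs, %d pairs, lambda = %g, method = %s\n",
              length(x$snp_ids), nrow(x$pairs), x$lambda, x$fit_method))
  invisible(x)
}
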