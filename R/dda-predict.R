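# unnormalized per-group log-probability ratio log q_case - log q_control for
# each genotype row; missing entries contribute 0 to the exponent
score_log_ratio <- function(model, G) {
  G <- as.matrix(G)
  n <- nrow(G); m <- length(model$snp_ids)
  dH <- model$fields$case - model$fields$control      # m x 2
  s <- numeric(n)
  for (a in 1:2) {
    Ia <- (G == a)
    Ia[is.na(Ia)] <- FALSE
    s <- s + Ia %*% dH[, a]
  }
  pairs <- model$pairs
  if (nrow(pairs)) {
    dJ <- model$couplings$case - model$couplings$control  # P x 4
    for (p in seq_len(nrow(pairs))) {
      if (all(dJ[p, ] == 0)) next
      gi <- G[, pairs[p, 1L]]; gj <- G[, pairs[p, 2L]]
      ok <- !is.na(gi) & !is.na(gj) & gi > 0L & gj > 0L
      if (!any(ok)) next
      idx <- 2L * (gi[ok] - 1L) + gj[ok]                  # (a,b) -> column
      s[ok] <- s[ok] + dJ[p, idx]
    }
  }
  as.numeric(s)
}

#' Bayes-risk disease probability
#'
#' Posterior probability of case status by Bayes' theorem:
#' `prior * q_case / (prior * q_case + (1 - prior) * q_control)`, where the
#' per-group unnormalized densities `q_y` come from the fitted fields and
#' couplings.  The two groups' normalizing constants are intractable for
#' large models; their log-ratio is absorbed into a single intercept
#' calibrated on the training data when the model was fitted, which preserves
#' the score ranking (hence AUC) exactly.
#'
#' @param model a [fit_dda()] model.
#' @param G genotype matrix (or single row) over the model's SNPs; missing
#'   entries contribute 0 to the exponent.
#' @param prior_case prior case probability; defaults to the model's.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
bayes_risk <- function(model, G, prior_case = model$prior_case) {
  if (is.null(dim(G))) G <- matrix(G, nrow = 1L)
  s <- score_log_ratio(model, G)
  plogis(s + model$calib - qlogis(model$train_prev) + qlogis(prior_case))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUC with ties counted 1/2, with a Hanley-McNeil standard error
#' and 95 percent confidence interval.
#'
#' @param scores numeric risk scores.
#' @param labels case/control labels: 2/1, `TRUE`/`FALSE`, or a factor whose
#'   larger level is "case".
#' @return List with `auc`, `se`, `ci` (length-2 vector).
#' @export
auc_mw <- function(scores, labels) {
  y <- if (is.logical(labels)) labels else labels == max(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  A <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  v <- (A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n0 - 1) * (Q2 - A^2)) /
    (n1 * n0)
  se <- sqrt(max(v, 0))
  list(auc = A, se = se,
       ci = pmin(pmax(A + c(-1, 1) * qnorm(0.975) * se, 0), 1))
}

#' Collective single-SNP p-value
#'
#' Significance of the additive part of one SNP's contribution within the
#' collective model: a likelihood-ratio statistic comparing the fitted model
#' to a refit in which SNP `i`'s case and control field vectors are
#' constrained equal (all other fields re-optimized, couplings held fixed),
#' referred to chi-square with 2 degrees of freedom.  When interactions are
#' off (one SNP, no pairs, or `lambda >=` [LAMBDA_NONINTERACTING]) this
#' reduces exactly to the independent-SNP genotypic test.
#'
#' @param model a converged [fit_dda()] pseudo-likelihood model.
#' @param gm the [genotype_matrix()] the model was fitted to (same SNPs).
#' @param snp_index SNP column to test.
#' @param tol,max_iter optimizer controls for the constrained refit.
#' @return One-row data frame: `snp_id`, `statistic`, `df`, `p_value`, `flag`.
#' @export
collective_single_snp_pvalue <- function(model, gm, snp_index,
                                         tol = 1e-9, max_iter = 1000L) {
  m <- length(model$snp_ids)
  P <- nrow(model$pairs)
  no_inter <- P == 0L || model$lambda >= LAMBDA_NONINTERACTING ||
    (all(model$couplings$case == 0) && all(model$couplings$control == 0))
  if (no_inter) {
    res <- genotypic_test(gm, snp_index)
    res$snp_id <- model$snp_ids[snp_index]
    return(res)
  }
  Xc <- gm$genotypes[case_rows(gm), , drop = FALSE]
  Xk <- gm$genotypes[control_rows(gm), , drop = FALSE]
  th_c <- theta_pack(model$fields$case, model$couplings$case)
  th_k <- theta_pack(model$fields$control, model$couplings$control)
  pi0 <- model$pairs[, 1L] - 1L; pj0 <- model$pairs[, 2L] - 1L
  lam <- model$lambda
  obj_alt <- plik_value_grad(th_c, Xc, pi0, pj0, lam, FALSE)$value +
    plik_value_grad(th_k, Xk, pi0, pj0, lam, FALSE)$value
  # reduced parameterization: free fields of both groups with SNP i tied
  K <- n_par_group(m, P)
  fi <- c(2L * snp_index - 1L, 2L * snp_index)     # SNP i's field coords
  other <- setdiff(seq_len(2L * m), fi)
  map_c <- integer(K); map_k <- integer(K)
  nf <- length(other)
  map_c[other] <- seq_len(nf)
  map_k[other] <- nf + seq_len(nf)
  map_c[fi] <- map_k[fi] <- 2L * nf + 1:2
  theta0 <- c(th_c[other], th_k[other],
              (th_c[fi] + th_k[fi]) / 2)
  groups <- list(list(X = Xc, map = map_c, fixed = th_c),
                 list(X = Xk, map = map_k, fixed = th_k))
  res <- optim_plik(groups, model$pairs, lam, theta0, tol, max_iter)
  flag <- if (res$converged) NA_character_ else "refit non-convergence"
  stat <- max(0, 2 * (obj_alt - res$value))
  data.frame(snp_id = model$snp_ids[snp_index], statistic = stat, df = 2L,
             p_value = pchisq(stat, 2L, lower.tail = FALSE), flag = flag,
             stringsAsFactors = FALSE)
}
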