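# Independent enumeration oracles for the pairwise genotype model.  These are
# deliberately written without reusing the package's fitting machinery: exact
# state enumeration, closed-form multinomial MLEs, and generic optimization of
# the exact likelihood.

# all 3^m genotype states, rows = states
enum_states <- function(m) {
  as.matrix(do.call(expand.grid, rep(list(0:2), m)))
}

# log-weight of each state under fields H (m x 2) and couplings given as a
# list of list(i, j, J = 2x2)
enum_logweights <- function(states, H, couplings = list()) {
  lw <- numeric(nrow(states))
  for (r in seq_len(nrow(states))) {
    g <- states[r, ]
    v <- 0
    for (i in seq_along(g)) if (g[i] > 0) v <- v + H[i, g[i]]
    for (cp in couplings) {
      a <- g[cp$i]; b <- g[cp$j]
      if (a > 0 && b > 0) v <- v + cp$J[a, b]
    }
    lw[r] <- v
  }
  lw
}

enum_probs <- function(states, H, couplings = list()) {
  lw <- enum_logweights(states, H, couplings)
  w <- exp(lw - max(lw))
  w / sum(w)
}

# saturated m=2 MLE from a 3x3 count table: log cell-probability ratios
saturated_m2_params <- function(tab) {
  lp <- log(tab)
  H <- rbind(c(lp[2, 1] - lp[1, 1], lp[3, 1] - lp[1, 1]),
             c(lp[1, 2] - lp[1, 1], lp[1, 3] - lp[1, 1]))
  J <- outer(1:2, 1:2, Vectorize(function(a, b)
    lp[a + 1, b + 1] + lp[1, 1] - lp[a + 1, 1] - lp[1, b + 1]))
  list(H = H, J = J)
}

# sufficient-statistic design matrix for m SNPs with all pairs: columns are
# h_i(1), h_i(2) then per pair J(1,1), J(1,2), J(2,1), J(2,2)
enum_design <- function(states) {
  m <- ncol(states)
  pr <- if (m >= 2) t(combn(m, 2)) else matrix(integer(0), 0, 2)
  cols <- list()
  for (i in seq_len(m)) for (a in 1:2) cols[[length(cols) + 1L]] <-
      as.numeric(states[, i] == a)
  if (nrow(pr)) for (p in seq_len(nrow(pr))) for (a in 1:2) for (b in 1:2)
    cols[[length(cols) + 1L]] <-
      as.numeric(states[, pr[p, 1L]] == a & states[, pr[p, 2L]] == b)
  do.call(cbind, cols)
}

# exact log-likelihood of state counts under packed parameters
enum_loglik <- function(theta, S, counts) {
  lw <- as.numeric(S %*% theta)
  mx <- max(lw)
  sum(counts * lw) - sum(counts) * (mx + log(sum(exp(lw - mx))))
}

enum_loglik_grad <- function(theta, S, counts) {
  lw <- as.numeric(S %*% theta)
  p <- exp(lw - max(lw)); p <- p / sum(p)
  as.numeric(t(S) %*% counts - sum(counts) * t(S) %*% p)
}

# exact (full-likelihood) MLE by BFGS over the enumeration
enum_ml_fit <- function(X, theta0 = NULL) {
  m <- ncol(X)
  states <- enum_states(m)
  S <- enum_design(states)
  key <- apply(states, 1, paste, collapse = ",")
  cnt <- table(factor(apply(X, 1, paste, collapse = ","), levels = key))
  counts <- as.numeric(cnt)
  if (is.null(theta0)) theta0 <- numeric(ncol(S))
  opt <- optim(theta0, enum_loglik, enum_loglik_grad, S = S, counts = counts,
               method = "BFGS",
               control = list(fnscale = -1, maxit = 2000, reltol = 1e-14))
  list(theta = opt$par, value = opt$value, counts = counts, S = S)
}

# asymptotic standard errors of the exact MLE at parameters theta:
# inverse Fisher information (covariance of sufficient statistics) / n
enum_ml_se <- function(theta, m, n) {
  states <- enum_states(m)
  S <- enum_design(states)
  lw <- as.numeric(S %*% theta)
  p <- exp(lw - max(lw)); p <- p / sum(p)
  mu <- as.numeric(t(S) %*% p)
  I <- t(S * p) %*% S - outer(mu, mu)
  sqrt(diag(solve(I)) / n)
}

# state counts of one group's m=2 data as a 3x3 table
counts_m2 <- function(X) {
  table(factor(X[, 1L], 0:2), factor(X[, 2L], 0:2)) + 0
}

# multinomial log-likelihood of counts at their own MLE
saturated_loglik <- function(counts) {
  counts <- as.numeric(counts)
  sum(ifelse(counts > 0, counts * log(counts / sum(counts)), 0))
}

# exact-likelihood interaction LR on m=2: saturated per-group fits vs a
# joint fit with the coupling block shared between groups
exact_pair_lr_m2 <- function(Xc, Xk) {
  states <- enum_states(2)
  S <- enum_design(states)
  key <- apply(states, 1, paste, collapse = ",")
  cnt <- function(X) as.numeric(table(factor(apply(X, 1, paste,
                                                   collapse = ","),
                                            levels = key)))
  cc <- cnt(Xc); ck <- cnt(Xk)
  nll <- function(par) {
    -(enum_loglik(c(par[1:4], par[9:12]), S, cc) +
        enum_loglik(c(par[5:8], par[9:12]), S, ck))
  }
  opt <- optim(rep(0, 12), nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  2 * (saturated_loglik(cc) + saturated_loglik(ck) + opt$value)
}

# fixture: differential couplings with identical marginals.  The case group
# couples levels (1,1)/(2,2), the control group (1,2)/(2,1); by level-swap
# symmetry the single-SNP marginals coincide across groups.
diff_coupling_spec <- function(n_case, n_control, m, pairs, J = 1.2,
                               seed = 1L) {
  Jc <- matrix(c(J, 0, 0, J), 2)
  Jk <- matrix(c(0, J, J, 0), 2)
  sim_spec(n_case, n_control, m,
           couplings_case = lapply(seq_len(nrow(pairs)), function(k)
             coupling(pairs[k, 1L], pairs[k, 2L], Jc)),
           couplings_control = lapply(seq_len(nrow(pairs)), function(k)
             coupling(pairs[k, 1L], pairs[k, 2L], Jk)),
           seed = seed)
}

# small helper: genotype matrix from an explicit integer matrix
gm_from <- function(G, phen) genotype_matrix(G, phen)
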