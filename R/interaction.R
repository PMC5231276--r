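# ---- per-pair interaction likelihood-ratio tests ---------------------------

# joint tied-pair refit: both groups' parameters free except that the tested
# pair's coupling block is shared; warm-started from the per-group fits
# (concave objective, unique optimum).  Returns the constrained optimum value.
#
# Scale note: each pair's coupling enters two conditionals of the
# pseudo-likelihood, so the raw objective counts the tested pair's
# information twice.  The interaction statistic is therefore
# PLobj(alt) - PLobj(null) (not twice that), which restores the
# likelihood-ratio scale: on m = 2 it coincides with the exact-likelihood
# statistic 2*(ll_alt - ll_null) to optimizer precision, and under a true
# null its mean matches the 4 constrained degrees of freedom.
tied_pair_value <- function(Xc, Xk, pairs, lambda, p_idx, fit_c, fit_k,
                            tol, max_iter) {
  m <- ncol(Xc); P <- nrow(pairs)
  K <- n_par_group(m, P)
  th_c <- theta_pack(fit_c$fields, fit_c$couplings)
  th_k <- theta_pack(fit_k$fields, fit_k$couplings)
  pc <- 2L * m + 4L * (p_idx - 1L) + 1:4      # tested pair's coordinates
  other <- setdiff(seq_len(K), pc)
  map_c <- integer(K); map_k <- integer(K)
  no <- length(other)
  map_c[other] <- seq_len(no)
  map_k[other] <- no + seq_len(no)
  map_c[pc] <- map_k[pc] <- 2L * no + 1:4
  theta0 <- c(th_c[other], th_k[other], (th_c[pc] + th_k[pc]) / 2)
  groups <- list(list(X = Xc, map = map_c, fixed = numeric(K)),
                 list(X = Xk, map = map_k, fixed = numeric(K)))
  res <- optim_plik(groups, pairs, lambda, theta0, tol, max_iter)
  res
}

#' Interaction likelihood-ratio statistic for one SNP pair
#'
#' Tests whether the pair's coupling parameters differ between the case and
#' control groups: the alternative is the standard per-group fit, the null a
#' joint refit with the single constraint `J_pair^case = J_pair^control`
#' (all other parameters re-optimized).  The statistic is the
#' duplication-corrected pseudo-likelihood ratio `PLobj(alt) - PLobj(null)`
#' (each pair factor appears in two conditionals, so the conventional factor
#' 2 is already built in); it is `>= 0`, equals the exact-likelihood LR on
#' enumerable models, and has null mean ~4, the constraint's degrees of
#' freedom (the genotypic model's interaction part).  Its null distribution
#' is sampled by phenotype permutation ([permutation_pvalues()]).
#'
#' @param gm a [genotype_matrix()].
#' @param selection SNP ids or column indices defining the model panel.
#' @param lambda coupling penalizer.
#' @param pair length-2 vector: the pair to test, as ids or indices *within
#'   the selection*.
#' @param tol,max_iter optimizer controls (tight default: the statistic is a
#'   difference of optima).
#' @return The statistic (numeric scalar) with attribute `converged`.
#' @export
pair_lr_statistic <- function(gm, selection, lambda, pair,
                              tol = 1e-9, max_iter = 1000L) {
  gm <- gm[, selection]
  if (is.character(pair)) pair <- match(pair, gm$snps$id)
  pair <- sort(as.integer(pair))
  pairs <- snp_pairs(ncol(gm$genotypes))
  p_idx <- which(pairs[, 1L] == pair[1L] & pairs[, 2L] == pair[2L])
  if (!length(p_idx)) stop("pair not within the selection")
  Xc <- gm$genotypes[case_rows(gm), , drop = FALSE]
  Xk <- gm$genotypes[control_rows(gm), , drop = FALSE]
  if (lambda >= LAMBDA_NONINTERACTING)
    return(structure(0, converged = TRUE))
  fc <- fit_group_pseudolikelihood(Xc, lambda, tol = tol, max_iter = max_iter)
  fk <- fit_group_pseudolikelihood(Xk, lambda, tol = tol, max_iter = max_iter)
  null <- tied_pair_value(Xc, Xk, pairs, lambda, p_idx, fc, fk, tol, max_iter)
  structure(max(0, fc$value + fk$value - null$value),
            converged = fc$converged && fk$converged && null$converged)
}

# all tested pairs' statistics for one labelling; group fits done once
pair_stats_once <- function(Xc, Xk, pairs, test_idx, lambda, tol, max_iter) {
  fc <- fit_group_pseudolikelihood(Xc, lambda, tol = tol, max_iter = max_iter)
  fk <- fit_group_pseudolikelihood(Xk, lambda, tol = tol, max_iter = max_iter)
  vapply(test_idx, function(p_idx) {
    null <- tied_pair_value(Xc, Xk, pairs, lambda, p_idx, fc, fk,
                            tol, max_iter)
    max(0, fc$value + fk$value - null$value)
  }, numeric(1))
}

#' Permutation p-values for SNP-pair interactions
#'
#' Computes the interaction statistic for every tested pair, then samples its
#' null distribution by randomly shuffling phenotype labels and repeating the
#' collective inference.  One shared set of `n_perm` permutation replicates
#' provides null statistics for all pairs (each replicate is one collective
#' inference), and p-values use the add-one estimator
#' `p = (1 + #(stat_perm >= stat_obs)) / (1 + n_perm)`, which is never zero.
#'
#' @inheritParams pair_lr_statistic
#' @param n_perm number of permutation replicates (>= 19).
#' @param seed integer seed; results are reproducible given the seed.
#' @param pairs optional 2-column matrix of pairs (indices within the
#'   selection) to test; default all pairs.
#' @param tol,max_iter optimizer controls.
#' @return Data frame of class `interaction_result`: `snp_i`, `snp_j`,
#'   `statistic`, `p_value`, `n_perm`.
#' @export
permutation_pvalues <- function(gm, selection, lambda, n_perm = 99L,
                                seed = 1L, pairs = NULL,
                                tol = 1e-7, max_iter = 500L) {
  if (n_perm < 19L) stop("n_perm must be >= 19")
  gm <- gm[, selection]
  m <- ncol(gm$genotypes)
  all_pairs <- snp_pairs(m)
  if (is.null(pairs)) pairs <- all_pairs
  key <- paste(all_pairs[, 1L], all_pairs[, 2L])
  test_idx <- match(paste(pmin(pairs[, 1L], pairs[, 2L]),
                          pmax(pairs[, 1L], pairs[, 2L])), key)
  stopifnot(!anyNA(test_idx))
  G <- gm$genotypes
  phen <- gm$phenotypes
  obs <- pair_stats_once(G[phen == 2L, , drop = FALSE],
                         G[phen == 1L, , drop = FALSE],
                         all_pairs, test_idx, lambda, tol, max_iter)
  set.seed(seed)
  perms <- replicate(n_perm, sample(length(phen)))
  exceed <- integer(length(test_idx))
  for (b in seq_len(n_perm)) {
    ph <- phen[perms[, b]]
    st <- pair_stats_once(G[ph == 2L, , drop = FALSE],
                          G[ph == 1L, , drop = FALSE],
                          all_pairs, test_idx, lambda, tol, max_iter)
    exceed <- exceed + (st >= obs)
  }
  out <- data.frame(
    snp_i = gm$snps$id[all_pairs[test_idx, 1L]],
    snp_j = gm$snps$id[all_pairs[test_idx, 2L]],
    i = all_pairs[test_idx, 1L], j = all_pairs[test_idx, 2L],
    statistic = obs,
    p_value = (1 + exceed) / (1 + n_perm),
    n_perm = as.integer(n_perm),
    stringsAsFactors = FALSE)
  class(out) <- c("interaction_result", "data.frame")
  out
}

#' Select significant interaction pairs
#'
#' Threshold filter on permutation p-values; the cutoff is exclusive
#' (`p < cutoff`), matching a liberal-pool selection where moderate pairs are
#' analyzed in aggregate downstream.
#'
#' @param results an [permutation_pvalues()] result.
#' @param cutoff exclusive p-value threshold (default `1e-3`).
#' @return The subset of `results` with `p_value < cutoff`, in `(i, j)` order.
#' @export
significant_pairs <- function(results, cutoff = 1e-3) {
  out <- results[results$p_value < cutoff, , drop = FALSE]
  out[order(out$i, out$j), , drop = FALSE]
}
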