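#' Cross-validation configuration
#'
#' @param k_folds number of stratified folds (default 5).
#' @param lambda_grid nonnegative penalizer values; the largest value is the
#'   non-interacting proxy used as the reference for `delta_auc`.
#' @param p_cut in-fold SNP-selection p-value cutoff (`p_i < p_cut`, training
#'   data only); ignored when `top_m` is given.
#' @param top_m alternative selection rule: the `top_m` SNPs with smallest
#'   training `p_i`.
#' @param n_perm permutation replicates for [delta_auc_significance()].
#' @param seed integer seed driving fold assignment and permutations.
#' @param method `"pl"` or `"mf"` model fits.
#' @param ridge mean-field ridge.
#' @param tol,max_iter optimizer controls for `"pl"` fits.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(k_folds = 5L, lambda_grid = c(0.01, LAMBDA_NONINTERACTING),
                      p_cut = NULL, top_m = NULL, n_perm = 99L, seed = 1L,
                      method = c("pl", "mf"), ridge = 0.1,
                      tol = 1e-6, max_iter = 500L) {
  stopifnot(k_folds >= 2L, all(lambda_grid >= 0))
  structure(list(k_folds = as.integer(k_folds), lambda_grid = lambda_grid,
                 p_cut = p_cut, top_m = top_m, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), method = match.arg(method),
                 ridge = ridge, tol = tol, max_iter = as.integer(max_iter)),
            class = "cv_config")
}

# stratified fold assignment by seeded shuffle: cases and controls are each
# shuffled and dealt round-robin so every fold contains both classes
assign_folds <- function(phenotypes, k, seed) {
  fold <- integer(length(phenotypes))
  set.seed(seed)
  for (cls in c(1L, 2L)) {
    idx <- which(phenotypes == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

select_training_snps <- function(gm_train, p_cut, top_m) {
  p <- scan_pvalues(gm_train$genotypes, gm_train$phenotypes)
  if (!is.null(top_m)) {
    ord <- order(p, gm_train$snps$pos, gm_train$snps$id)
    return(sort(head(ord, top_m)))
  }
  which(!is.na(p) & p < p_cut)
}

#' Five-fold cross-validated AUC over a penalizer grid
#'
#' For each fold, SNPs are selected on the training data only (`p_i < p_cut`
#' or `top_m`), per-group models are fitted at each `lambda`, and held-out
#' individuals are scored by [bayes_risk()].  Predictions from all folds are
#' pooled into one AUC per `lambda` (Mann-Whitney, Hanley-McNeil 95 percent
#' CI).  `delta_auc` is the maximum AUC minus the AUC at the largest `lambda`
#' in the grid (the non-interacting proxy).  A fold whose selection is empty
#' contributes prior-only scores with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [cv_config()].
#' @return An object of class `cv_result`: list with `curve` (data frame
#'   `lambda`, `auc`, `se`, `ci_lo`, `ci_hi`), `mean_selected_m`,
#'   `delta_auc`, and the pooled `scores`/`labels`.
#' @export
run_cv <- function(gm, config) {
  stopifnot(inherits(config, "cv_config"))
  if (is.null(config$p_cut) && is.null(config$top_m))
    stop("config must give p_cut or top_m")
  n <- nrow(gm$genotypes)
  fold <- assign_folds(gm$phenotypes, config$k_folds, config$seed)
  L <- length(config$lambda_grid)
  scores <- matrix(NA_real_, n, L)
  m_sel <- numeric(config$k_folds)
  for (k in seq_len(config$k_folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    gm_tr <- gm[tr, ]
    sel <- select_training_snps(gm_tr, config$p_cut, config$top_m)
    m_sel[k] <- length(sel)
    if (!length(sel)) {
      warning(sprintf("fold %d: empty SNP selection; prior-only scores", k))
      scores[te, ] <- mean(gm_tr$phenotypes == 2L)
      next
    }
    gm_tr_s <- gm_tr[, sel]
    G_te <- gm$genotypes[te, sel, drop = FALSE]
    for (l in seq_len(L)) {
      model <- fit_dda(gm_tr_s, lambda = config$lambda_grid[l],
                       method = config$method, ridge = config$ridge,
                       tol = config$tol, max_iter = config$max_iter)
      scores[te, l] <- bayes_risk(model, G_te)
    }
  }
  labels <- gm$phenotypes
  curve <- do.call(rbind, lapply(seq_len(L), function(l) {
    a <- auc_mw(scores[, l], labels)
    data.frame(lambda = config$lambda_grid[l], auc = a$auc, se = a$se,
               ci_lo = a$ci[1L], ci_hi = a$ci[2L])
  }))
  ref <- which.max(config$lambda_grid)
  structure(list(curve = curve, mean_selected_m = mean(m_sel),
                 delta_auc = max(curve$auc) - curve$auc[ref],
                 scores = scores, labels = labels),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  print(x$curve, row.names = FALSE)
  cat(sprintf("mean selected m = %.1f; delta AUC = %.4f\n",
              x$mean_selected_m, x$delta_auc))
  invisible(x)
}

#' Permutation significance of the interaction AUC gain
#'
#' Treats `delta_auc` (maximum cross-validated AUC minus the non-interacting
#' limit) as a statistic and samples its null distribution by permuting
#' phenotype labels over all individuals before fold assignment; each
#' permutation reruns the full cross-validation including in-fold SNP
#' selection.  `p = (1 + #(delta_perm >= delta_obs)) / (1 + n_perm)`.
#'
#' @inheritParams run_cv
#' @return List with `delta_auc`, `p_value`, `n_perm`, `perm_delta`.
#' @export
delta_auc_significance <- function(gm, config) {
  if (config$n_perm < 19L) stop("n_perm must be >= 19")
  obs <- run_cv(gm, config)$delta_auc
  n <- nrow(gm$genotypes)
  set.seed(config$seed)
  perms <- replicate(config$n_perm, sample.int(n))
  perm_delta <- vapply(seq_len(config$n_perm), function(b) {
    gm_b <- gm
    gm_b$phenotypes <- gm$phenotypes[perms[, b]]
    run_cv(gm_b, config)$delta_auc
  }, numeric(1))
  list(delta_auc = obs,
       p_value = (1 + sum(perm_delta >= obs)) / (1 + config$n_perm),
       n_perm = config$n_perm, perm_delta = perm_delta)
}
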