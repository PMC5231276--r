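# ---- pathway-based SNP-set construction and scoring ------------------------

#' Assign SNPs to genes within a window around the coding region
#'
#' A SNP is assigned to a gene iff its position lies within
#' `[coding_start - window, coding_end + window]`, both boundaries inclusive
#' (1-based coordinates).  A SNP may map to multiple genes.
#'
#' @param snps data frame with `id`, `chrom`, `pos`.
#' @param gene_table data frame with `gene`, `chrom`, `start`, `end`
#'   ([read_gene_table()]).
#' @param window flanking distance in bases (default 50,000).
#' @return Named list mapping gene to a character vector of SNP ids.
#' @export
assign_snps_to_genes <- function(snps, gene_table, window = 50000L) {
  out <- lapply(seq_len(nrow(gene_table)), function(k) {
    g <- gene_table[k, ]
    hit <- snps$chrom == g$chrom & snps$pos >= g$start - window &
      snps$pos <= g$end + window
    snps$id[hit]
  })
  setNames(out, gene_table$gene)
}

#' Non-redundant pathway SNP set
#'
#' Union of the SNPs assigned to a pathway's constituent genes, deduplicated.
#' Unknown gene symbols are skipped and reported in the `skipped` attribute.
#'
#' @param pathway_genes character vector of gene symbols.
#' @param gene_snps [assign_snps_to_genes()] map.
#' @return Character vector of SNP ids (possibly empty), attribute `skipped`.
#' @export
pathway_snp_set <- function(pathway_genes, gene_snps) {
  known <- pathway_genes %in% names(gene_snps)
  snps <- unique(unlist(gene_snps[pathway_genes[known]], use.names = FALSE))
  structure(if (is.null(snps)) character(0) else snps,
            skipped = pathway_genes[!known])
}

#' Cross-validated collective-inference score for one pathway
#'
#' Cross-validated AUC of the collective model (mean-field fitting)
#' restricted to the pathway's SNP set, together with the couplings-off
#' (non-interacting) AUC.  When the effective set exceeds `max_model_snps`,
#' in-fold p-value filtering retains the `max_model_snps` most associated
#' SNPs of each training fold (selection never sees the test fold).
#'
#' @param gm a [genotype_matrix()].
#' @param snp_set SNP ids ([pathway_snp_set()]).
#' @param cv_config a [cv_config()]; its `ridge` and fold settings are used.
#' @param max_model_snps model-size cap (default 2000).
#' @param pathway_id label carried into the result.
#' @return One-row data frame of class `pathway_score`: `pathway_id`,
#'   `n_snps`, `auc_interacting`, `ci_lo`, `ci_hi`, `auc_noninteracting`,
#'   `ni_ci_lo`, `ni_ci_hi`, `flag`.
#' @export
score_pathway <- function(gm, snp_set, cv_config, max_model_snps = 2000L,
                          pathway_id = NA_character_) {
  snp_set <- intersect(snp_set, gm$snps$id)
  if (!length(snp_set)) {
    return(data.frame(pathway_id = pathway_id, n_snps = 0,
                      auc_interacting = 0.5, ci_lo = NA, ci_hi = NA,
                      auc_noninteracting = 0.5, ni_ci_lo = NA, ni_ci_hi = NA,
                      flag = "empty SNP set", stringsAsFactors = FALSE))
  }
  gm_p <- gm[, snp_set]
  n <- nrow(gm_p$genotypes)
  fold <- assign_folds(gm_p$phenotypes, cv_config$k_folds, cv_config$seed)
  scores <- matrix(NA_real_, n, 2L)
  m_used <- numeric(cv_config$k_folds)
  for (k in seq_len(cv_config$k_folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    gm_tr <- gm_p[tr, ]
    sel <- seq_along(snp_set)
    if (length(snp_set) > max_model_snps) {
      p <- scan_pvalues(gm_tr$genotypes, gm_tr$phenotypes)
      sel <- sort(head(order(p, gm_tr$snps$pos), max_model_snps))
    }
    m_used[k] <- length(sel)
    gm_tr_s <- gm_tr[, sel]
    G_te <- gm_p$genotypes[te, sel, drop = FALSE]
    mf <- fit_dda(gm_tr_s, method = "mf", ridge = cv_config$ridge)
    ni <- fit_dda(gm_tr_s, method = "mf", interactions = FALSE)
    scores[te, 1L] <- bayes_risk(mf, G_te)
    scores[te, 2L] <- bayes_risk(ni, G_te)
  }
  a_int <- auc_mw(scores[, 1L], gm_p$phenotypes)
  a_ni <- auc_mw(scores[, 2L], gm_p$phenotypes)
  out <- data.frame(pathway_id = pathway_id, n_snps = mean(m_used),
                    auc_interacting = a_int$auc, ci_lo = a_int$ci[1L],
                    ci_hi = a_int$ci[2L],
                    auc_noninteracting = a_ni$auc, ni_ci_lo = a_ni$ci[1L],
                    ni_ci_hi = a_ni$ci[2L], flag = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("pathway_score", "data.frame")
  out
}
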