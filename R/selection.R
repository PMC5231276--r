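# ---- proxy-SNP panel construction ------------------------------------------

#' Pairwise LD r-squared matrix
#'
#' Composite LD: the squared Pearson correlation of genotype count vectors,
#' computed pairwise-complete over non-missing individuals.  Zero-variance
#' SNPs yield `NA` for their pairs; the diagonal is 1.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_subset SNP ids or column indices (default all).
#' @return Symmetric matrix of r-squared values in `[0, 1]`.
#' @export
compute_r2 <- function(gm, snp_subset = NULL) {
  G <- gm$genotypes
  if (!is.null(snp_subset)) {
    if (is.character(snp_subset)) snp_subset <- match(snp_subset, gm$snps$id)
    G <- G[, snp_subset, drop = FALSE]
  }
  suppressWarnings(r <- cor(G, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 1
  r2
}

#' Region-stratified SNP selection by association rank
#'
#' Within each region, picks the SNPs with the smallest independent-SNP
#' p-values up to the region's quota; ties are broken by position, then id.
#' A quota exceeding a region's SNP count takes all of them with a warning.
#'
#' @param assoc a [genomewide_scan()] result (must carry `snp_id`, `chrom`,
#'   `pos`, `p_value`).
#' @param quotas data frame with columns `region`, `chrom`, `start`, `end`
#'   (1-based inclusive bounds), `count`.
#' @return Data frame of class `snp_selection`: `proxy_id`, `provenance`.
#' @export
select_stratified <- function(assoc, quotas) {
  picks <- lapply(seq_len(nrow(quotas)), function(k) {
    q <- quotas[k, ]
    in_region <- assoc$chrom == q$chrom & assoc$pos >= q$start &
      assoc$pos <= q$end
    cand <- assoc[in_region, , drop = FALSE]
    if (nrow(cand) < q$count)
      warning(sprintf("region %s has %d SNPs for a quota of %d; taking all",
                      q$region, nrow(cand), q$count))
    cand <- cand[order(cand$p_value, cand$pos, cand$snp_id), , drop = FALSE]
    head(cand$snp_id, q$count)
  })
  sel <- data.frame(
    proxy_id = unlist(picks),
    provenance = rep(paste0("region:", quotas$region),
                     lengths(picks)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(sel$proxy_id))
    sel <- sel[!duplicated(sel$proxy_id), , drop = FALSE]
  class(sel) <- c("snp_selection", "data.frame")
  sel
}

#' LD-cluster-reduced SNP selection
#'
#' Clusters candidate SNPs on the distance `d = -log(r2)` (r-squared of 0 or
#' `NA` capped at `d = 30`) with k-medoids (PAM) — the reproducible
#' interpretation of k-means on an LD distance, which is not Euclidean —
#' and keeps, from each cluster, the member with the smallest p-value
#' (ties: position, then id).
#'
#' @param candidates data frame with `snp_id`, `p_value`, `pos`.
#' @param r2 LD matrix over the candidates ([compute_r2()]).
#' @param k number of clusters / selected proxies (`<=` candidate count).
#' @param seed integer seed (PAM's build phase is deterministic; the seed
#'   guards any sampling-based fallback).
#' @return Data frame of class `snp_selection`: `proxy_id`, `provenance`
#'   (cluster label), one row per cluster.
#' @export
cluster_reduce <- function(candidates, r2, k, seed = 1L) {
  n <- nrow(candidates)
  if (k > n) stop("k exceeds the number of candidates")
  d <- -log(pmax(r2, exp(-30)))
  d[is.na(d)] <- 30
  diag(d) <- 0
  set.seed(seed)
  cl <- if (k == n) seq_len(n)          # trivial partition: one SNP each
  else cluster::pam(stats::as.dist(d), k = k, diss = TRUE,
                    cluster.only = TRUE)
  reps <- vapply(seq_len(k), function(g) {
    idx <- which(cl == g)
    cand <- candidates[idx, , drop = FALSE]
    cand <- cand[order(cand$p_value, cand$pos, cand$snp_id), , drop = FALSE]
    cand$snp_id[1L]
  }, character(1))
  sel <- data.frame(proxy_id = reps,
                    provenance = paste0("cluster:", seq_len(k)),
                    stringsAsFactors = FALSE)
  attr(sel, "clusters") <- cl
  class(sel) <- c("snp_selection", "data.frame")
  sel
}
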