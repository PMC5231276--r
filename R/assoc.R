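#' Independent-SNP genotypic association test
#'
#' Likelihood-ratio (G-test) comparison of separate versus pooled 3-category
#' genotype multinomials for one SNP — the non-interacting special case of the
#' collective model, in which each group's genotype distribution factorizes
#' over SNPs.  The statistic is `2 * (l_case + l_control - l_pooled)` with
#' missing entries dropped per SNP; zero cells contribute 0 (`0 * log 0 := 0`).
#' Degrees of freedom are the number of genotype levels observed in the pooled
#' sample minus one, capped at 2 (the genotypic model's additive part).
#'
#' @param gm a [genotype_matrix()].
#' @param snp_index column index of the SNP to test.
#' @return A one-row data frame: `snp_id`, `statistic`, `df`, `p_value`,
#'   `flag` (`NA_character_` or the reason the result is undefined).
#' @export
genotypic_test <- function(gm, snp_index) {
  g <- gm$genotypes[, snp_index]
  res <- genotypic_test_counts(
    tabulate(g[gm$phenotypes == 2L] + 1L, nbins = 3L),
    tabulate(g[gm$phenotypes == 1L] + 1L, nbins = 3L)
  )
  data.frame(snp_id = gm$snps$id[snp_index], statistic = res$statistic,
             df = res$df, p_value = res$p_value, flag = res$flag,
             stringsAsFactors = FALSE)
}

# core 2x3-table multinomial LR on genotype level counts (levels 0,1,2)
genotypic_test_counts <- function(n_case, n_control) {
  n1 <- sum(n_case); n0 <- sum(n_control)
  if (n1 == 0L || n0 == 0L) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                flag = "empty phenotype group"))
  }
  pooled <- n_case + n_control
  n <- n1 + n0
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  # 2 [ sum n_ya log n_ya - sum n_y. log n_y. - sum n_.a log n_.a + n log n ]
  stat <- 2 * (sum(xlx(n_case)) + sum(xlx(n_control)) -
               xlx(n1) - xlx(n0) - sum(xlx(pooled)) + xlx(n))
  stat <- max(stat, 0)
  df <- min(sum(pooled > 0L) - 1L, 2L)
  if (df <= 0L) {
    return(list(statistic = 0, df = 0L, p_value = 1, flag = NA_character_))
  }
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), flag = NA_character_)
}

# lean per-SNP p-value scan used inside cross-validation folds (no data
# frames; identical statistics to genomewide_scan)
scan_pvalues <- function(G, phenotypes) {
  case <- phenotypes == 2L
  ctrl <- phenotypes == 1L
  vapply(seq_len(ncol(G)), function(k) {
    g <- G[, k]
    genotypic_test_counts(tabulate(g[case] + 1L, nbins = 3L),
                          tabulate(g[ctrl] + 1L, nbins = 3L))$p_value
  }, numeric(1))
}

#' Genome-wide independent-SNP scan
#'
#' Applies [genotypic_test()] to every SNP.  Monomorphic SNPs yield statistic
#' 0, p-value 1 and 0 degrees of freedom.
#'
#' @param gm a [genotype_matrix()].
#' @return Data frame with one row per SNP, input order: `snp_id`, `chrom`,
#'   `pos`, `statistic`, `df`, `p_value`, `flag`.
#' @export
genomewide_scan <- function(gm) {
  case <- gm$phenotypes == 2L
  ctrl <- gm$phenotypes == 1L
  out <- lapply(seq_len(ncol(gm$genotypes)), function(k) {
    g <- gm$genotypes[, k]
    genotypic_test_counts(tabulate(g[case] + 1L, nbins = 3L),
                          tabulate(g[ctrl] + 1L, nbins = 3L))
  })
  data.frame(snp_id = gm$snps$id, chrom = gm$snps$chrom, pos = gm$snps$pos,
             statistic = vapply(out, `[[`, numeric(1), "statistic"),
             df = vapply(out, `[[`, integer(1), "df"),
             p_value = vapply(out, `[[`, numeric(1), "p_value"),
             flag = vapply(out, `[[`, character(1), "flag"),
             stringsAsFactors = FALSE)
}
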