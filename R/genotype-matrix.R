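#' Case/control genotype matrix
#'
#' The universal input container: an `n x m` matrix of genotype counts in
#' `{0, 1, 2}` (`NA` = missing call), a phenotype vector coded as in PLINK
#' (1 = control, 2 = case), and per-SNP metadata (id, chromosome, 1-based
#' GRCh37 position, alleles).
#'
#' @param genotypes integer matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2}` or `NA`.
#' @param phenotypes integer vector of length `nrow(genotypes)` with values
#'   1 (control) or 2 (case); `NA` allowed.
#' @param snps data frame with columns `id`, `chrom`, `pos`, `a1`, `a2`
#'   (one row per SNP column). A minimal frame is synthesized when omitted.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, phenotypes, snps = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(snps)) {
    snps <- data.frame(
      id = if (!is.null(colnames(genotypes))) colnames(genotypes)
           else sprintf("snp%04d", seq_len(ncol(genotypes))),
      chrom = "chr6",
      pos = 31000000L + 5000L * (seq_len(ncol(genotypes)) - 1L),
      a1 = "A", a2 = "G",
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(snps) == ncol(genotypes),
            length(phenotypes) == nrow(genotypes))
  bad <- which(!(genotypes %in% c(0L, 1L, 2L, NA)), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(genotypes))
    stop(sprintf("genotype level outside {0,1,2,NA} at row %d, col %d",
                 rc[1L], rc[2L]))
  }
  phenotypes <- as.integer(phenotypes)
  if (any(!(phenotypes %in% c(1L, 2L, NA))))
    stop("phenotypes must be coded 1 (control), 2 (case) or NA")
  if (anyDuplicated(snps$id))
    stop("duplicate SNP ids in metadata")
  colnames(genotypes) <- snps$id
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 snps = snps),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals (%d case / %d control), %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotypes == 2L, na.rm = TRUE),
              sum(x$phenotypes == 1L, na.rm = TRUE), ncol(x$genotypes)))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing rate %.3f; positions %s:%s-%s\n", miss,
              x$snps$chrom[1L], format(min(x$snps$pos), big.mark = ","),
              format(max(x$snps$pos), big.mark = ",")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i row (individual) index, missing for all.
#' @param j column (SNP) index or character vector of SNP ids.
#' @param ... unused.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$genotypes))
  if (missing(j)) j <- seq_len(ncol(x$genotypes))
  if (is.character(j)) j <- match(j, x$snps$id)
  genotype_matrix(x$genotypes[i, j, drop = FALSE], x$phenotypes[i],
                  x$snps[j, , drop = FALSE])
}

case_rows <- function(gm) which(gm$phenotypes == 2L)
control_rows <- function(gm) which(gm$phenotypes == 1L)

#' Enumerate the unordered SNP pairs of a selection
#'
#' @param m number of SNPs.
#' @return Two-column integer matrix of all `m*(m-1)/2` pairs `(i, j)`, `i < j`,
#'   ordered by `i` then `j`.
#' @export
snp_pairs <- function(m) {
  if (m < 2L) return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  i <- rep.int(seq_len(m - 1L), (m - 1L):1L)
  j <- sequence((m - 1L):1L) + i
  cbind(i = i, j = j)
}
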