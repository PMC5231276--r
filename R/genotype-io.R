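# ---- genotype readers/writers ----------------------------------------------
#
# Three dialects: package TSV (individuals x SNPs plus a phenotype column),
# PLINK transposed text (.tped/.tfam), and PLINK binary (.bed/.bim/.fam,
# SNP-major).  Phenotypes follow PLINK: 1 = control, 2 = case, 0/-9 missing.
# On read, counts are recoded to minor-allele counts, the minor allele being
# determined from the pooled sample (ties keep the stored A1); flipping which
# allele is A1 in the input therefore only relabels levels 0 <-> 2.

#' Write a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix (extensions appended per dialect).
#' @param dialect `"tsv"` (`<prefix>.tsv` + `<prefix>.snps.tsv`), `"tped"`
#'   (`.tped`/`.tfam`) or `"bed"` (`.bed`/`.bim`/`.fam`).  Allele-coded
#'   dialects emit `a1` for each counted allele copy, so the round trip is
#'   lossless whenever the coded allele is the minor one.
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(gm, prefix, dialect = c("tsv", "tped", "bed")) {
  dialect <- match.arg(dialect)
  G <- gm$genotypes
  n <- nrow(G); m <- ncol(G)
  iid <- sprintf("ind%04d", seq_len(n))
  if (dialect == "tsv") {
    df <- data.frame(iid = iid, phenotype = gm$phenotypes, G,
                     check.names = FALSE)
    write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(gm$snps, paste0(prefix, ".snps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else if (dialect == "tped") {
    con <- file(paste0(prefix, ".tped"), "w")
    on.exit(close(con))
    for (k in seq_len(m)) {
      al <- character(2L * n)
      g <- G[, k]
      a1 <- gm$snps$a1[k]; a2 <- gm$snps$a2[k]
      al[2 * seq_len(n) - 1] <- ifelse(is.na(g), "0",
                                       ifelse(g >= 1L, a1, a2))
      al[2 * seq_len(n)] <- ifelse(is.na(g), "0",
                                   ifelse(g == 2L, a1, a2))
      cat(gm$snps$chrom[k], gm$snps$id[k], "0", gm$snps$pos[k], al, "\n",
          file = con, sep = " ")
    }
    fam <- data.frame(fid = iid, iid = iid, pat = 0L, mat = 0L, sex = 0L,
                      phen = ifelse(is.na(gm$phenotypes), -9L,
                                    gm$phenotypes))
    write.table(fam, paste0(prefix, ".tfam"), sep = " ", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    fam <- data.frame(fid = iid, iid = iid, pat = 0L, mat = 0L, sex = 0L,
                      phen = ifelse(is.na(gm$phenotypes), -9L, gm$phenotypes))
    write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    bim <- data.frame(chrom = gm$snps$chrom, id = gm$snps$id, cm = 0L,
                      pos = gm$snps$pos, a1 = gm$snps$a1, a2 = gm$snps$a2)
    write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    # 2-bit codes, A1-count g: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
    code <- matrix(3L, n, m)
    code[G == 2L] <- 0L
    code[G == 1L] <- 2L
    code[is.na(G)] <- 1L
    nb <- ceiling(n / 4)
    for (k in seq_len(m)) {
      bytes <- integer(nb)
      for (r in seq_len(n)) {
        byte <- (r - 1L) %/% 4L + 1L
        shift <- 2L * ((r - 1L) %% 4L)
        bytes[byte] <- bytes[byte] + code[r, k] * 2L^shift
      }
      writeBin(as.raw(bytes), con)
    }
  }
  invisible(prefix)
}

#' Read a genotype matrix
#'
#' @param prefix path prefix as used by [write_genotypes()].
#' @param dialect `"tsv"`, `"tped"` or `"bed"`.
#' @return A [genotype_matrix()] with minor-allele genotype counts (the minor
#'   allele is determined from the pooled sample; when the stored A1 turns
#'   out to be the major allele, counts are complemented `0 <-> 2` and the
#'   allele columns swapped).
#' @export
read_genotypes <- function(prefix, dialect = c("tsv", "tped", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t",
                     check.names = FALSE)
    snps <- read.table(paste0(prefix, ".snps.tsv"), header = TRUE,
                       sep = "\t", colClasses = c(pos = "integer"),
                       stringsAsFactors = FALSE)
    G <- as.matrix(df[, -(1:2), drop = FALSE])
    phen <- df$phenotype
    if (any(!(phen %in% c(1L, 2L, NA))))
      stop("phenotype column must be 1 (control), 2 (case) or NA")
    return(genotype_matrix(G, phen, snps))
  }
  if (dialect == "tped") {
    fam <- read.table(paste0(prefix, ".tfam"), header = FALSE,
                      stringsAsFactors = FALSE)
    phen <- parse_plink_phen(fam[[6L]])
    lines <- readLines(paste0(prefix, ".tped"))
    n <- nrow(fam)
    m <- length(lines)
    G <- matrix(NA_integer_, n, m)
    snps <- data.frame(id = character(m), chrom = character(m),
                       pos = integer(m), a1 = character(m), a2 = character(m),
                       stringsAsFactors = FALSE)
    for (k in seq_len(m)) {
      f <- strsplit(trimws(lines[k]), "[ \t]+")[[1L]]
      if (length(f) != 4L + 2L * n)
        stop(sprintf(".tped line %d: expected %d fields, got %d",
                     k, 4L + 2L * n, length(f)))
      snps$chrom[k] <- f[1L]; snps$id[k] <- f[2L]
      snps$pos[k] <- as.integer(f[4L])
      al <- f[-(1:4)]
      obs <- setdiff(unique(al), "0")
      if (length(obs) > 2L)
        stop(sprintf(".tped line %d: more than two alleles", k))
      a1 <- if (length(obs)) obs[1L] else "A"
      a2 <- if (length(obs) >= 2L) obs[2L] else a1
      snps$a1[k] <- a1; snps$a2[k] <- a2
      first <- al[2 * seq_len(n) - 1]; second <- al[2 * seq_len(n)]
      miss <- first == "0" | second == "0"
      g <- (first == a1) + (second == a1)
      g[miss] <- NA_integer_
      G[, k] <- g
    }
    return(recode_minor(genotype_matrix(G, phen, snps)))
  }
  # bed
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE)
  phen <- parse_plink_phen(fam[[6L]])
  snps <- data.frame(id = as.character(bim[[2L]]),
                     chrom = as.character(bim[[1L]]),
                     pos = as.integer(bim[[4L]]),
                     a1 = as.character(bim[[5L]]), a2 = as.character(bim[[6L]]),
                     stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + ceiling(n / 4) * m + 1L)
  magic <- as.integer(raw[1:3])
  if (length(raw) < 3L || magic[1L] != 0x6c || magic[2L] != 0x1b)
    stop(".bed magic bytes wrong at offset 0: expected 0x6c 0x1b")
  if (magic[3L] != 0x01)
    stop(".bed mode byte at offset 2 is not 0x01 (SNP-major)")
  nb <- ceiling(n / 4)
  if (length(raw) != 3L + nb * m)
    stop(sprintf(".bed payload: expected %d bytes, found %d",
                 3L + nb * m, length(raw)))
  G <- matrix(NA_integer_, n, m)
  lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)  # A1 counts
  body <- as.integer(raw[-(1:3)])
  for (k in seq_len(m)) {
    bytes <- body[(k - 1L) * nb + seq_len(nb)]
    codes <- integer(4L * nb)
    for (s in 0:3) codes[4L * seq_len(nb) - 3L + s] <- (bytes %/% 4L^s) %% 4L
    G[, k] <- lut[codes[seq_len(n)] + 1L]
  }
  recode_minor(genotype_matrix(G, phen, snps))
}

parse_plink_phen <- function(x) {
  x <- as.integer(x)
  bad <- !(x %in% c(1L, 2L, 0L, -9L, NA))
  if (any(bad))
    stop(sprintf("phenotype value %d not in {1, 2, 0, -9}", x[bad][1L]))
  x[x %in% c(0L, -9L)] <- NA_integer_
  x
}

# flip SNPs whose coded (A1) allele is the pooled major allele
recode_minor <- function(gm) {
  freq <- colMeans(gm$genotypes, na.rm = TRUE) / 2
  flip <- which(!is.na(freq) & freq > 0.5)
  if (length(flip)) {
    gm$genotypes[, flip] <- 2L - gm$genotypes[, flip]
    a1 <- gm$snps$a1[flip]
    gm$snps$a1[flip] <- gm$snps$a2[flip]
    gm$snps$a2[flip] <- a1
  }
  gm
}

#' Quality-control filter on missingness and minor-allele frequency
#'
#' Removes SNPs whose missing-call rate exceeds `max_missing_rate` or whose
#' pooled minor-allele frequency is strictly below `min_maf` (a SNP exactly
#' at the MAF threshold is retained).  Monomorphic SNPs (MAF 0) are removed
#' whenever `min_maf > 0`.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_rate maximum tolerated per-SNP missing rate in `[0, 1]`.
#' @param min_maf minimum pooled minor-allele frequency in `[0, 1]`.
#' @return The filtered `genotype_matrix` with attribute `qc_report`, a data
#'   frame of removed SNPs (`id`, `reason`, `value`).  If every SNP is
#'   removed an empty matrix is returned with a warning, not an error.
#' @export
qc_filter <- function(gm, max_missing_rate = 0.05, min_maf = 0.01) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  miss <- colMeans(is.na(gm$genotypes))
  freq <- colMeans(gm$genotypes, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  drop_miss <- miss > max_missing_rate
  drop_maf <- !drop_miss & maf < min_maf
  report <- rbind(
    data.frame(id = gm$snps$id[drop_miss], reason = "missing_rate",
               value = miss[drop_miss], stringsAsFactors = FALSE),
    data.frame(id = gm$snps$id[drop_maf], reason = "maf",
               value = maf[drop_maf], stringsAsFactors = FALSE))
  keep <- which(!(drop_miss | drop_maf))
  if (!length(keep))
    warning("all SNPs removed by QC filters; returning empty matrix")
  out <- gm[, keep]
  attr(out, "qc_report") <- report
  out
}
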