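# ---- segmentations, LD groups, pathways, gene tables -----------------------

#' Read chromatin-state segmentations
#'
#' Reads one BED4 file per reference epigenome (`chrom start end state`,
#' 0-based half-open intervals as in BED) into `GRanges` objects carrying a
#' `state` metadata column.  Intervals within one epigenome must not overlap
#' (segmentations partition the genome); gaps are allowed and treated as
#' uncovered by downstream consumers.
#'
#' @param paths named character vector of BED file paths (names become
#'   epigenome ids), or a single directory containing `*.bed` files.
#' @return Named list of `GRanges`, class `segmentation_set`.
#' @export
read_segmentation <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.bed$", full.names = TRUE)
    paths <- setNames(files, sub("\\.bed$", "", basename(files)))
  }
  if (is.null(names(paths))) names(paths) <- sub("\\.bed$", "", basename(paths))
  segs <- lapply(paths, function(p) {
    gr <- rtracklayer::import(p, format = "BED")
    if (is.null(gr$name)) stop("BED file lacks the state (name) column: ", p)
    gr$state <- gr$name
    if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
      stop("overlapping intervals within one epigenome: ", p)
    gr
  })
  structure(segs, class = "segmentation_set")
}

#' Write chromatin-state segmentations as BED4
#'
#' @param segs a `segmentation_set` (named list of `GRanges` with a `state`
#'   column).
#' @param dir output directory; one `<epigenome>.bed` per element.
#' @return `dir`, invisibly.
#' @export
write_segmentation <- function(segs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(segs)) {
    gr <- segs[[nm]]
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     state = gr$state)
    write.table(df, file.path(dir, paste0(nm, ".bed")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read LD-proxy groups
#'
#' TSV with columns `proxy_id`, `snp_id`, `pos`, `r2`: for each proxy SNP,
#' the known SNPs in LD with it (`r2` above the study cutoff), the proxy
#' itself included with `r2 = 1`.
#'
#' @param path TSV path.
#' @param r2_cutoff members at or below this are rejected (default 0.5).
#' @return Named list (by proxy id) of `list(proxy_id, members)`, class
#'   `ld_groups`; `members` is a data frame `snp_id`, `pos`, `r2`.
#' @export
read_ld_groups <- function(path, r2_cutoff = 0.5) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("proxy_id", "snp_id", "pos", "r2") %in% names(df)))
  if (any(df$r2 <= r2_cutoff) || any(df$r2 > 1))
    stop(sprintf("member r2 outside (%g, 1]", r2_cutoff))
  split_df <- split(df[c("snp_id", "pos", "r2")], df$proxy_id)
  groups <- lapply(names(split_df), function(pid) {
    members <- split_df[[pid]]
    rownames(members) <- NULL
    if (!any(members$snp_id == pid & members$r2 == 1))
      stop("proxy ", pid, " is not its own member with r2 = 1")
    list(proxy_id = pid, members = members)
  })
  structure(setNames(groups, names(split_df)), class = "ld_groups")
}

#' Write LD-proxy groups as TSV
#'
#' @param groups an `ld_groups` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ld_groups <- function(groups, path) {
  df <- do.call(rbind, lapply(groups, function(g)
    data.frame(proxy_id = g$proxy_id, g$members, stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT pathway file
#'
#' One pathway per line: name, description, then gene symbols (tab-separated);
#' duplicate genes within a pathway are deduplicated.
#'
#' @param path GMT path.
#' @return Named list mapping pathway name to a character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1L]][1L], character(1),
    USE.NAMES = FALSE)
  out
}

#' Read a gene coordinate table
#'
#' TSV with columns `gene`, `chrom`, `start`, `end` giving each gene's coding
#' region (1-based inclusive coordinates).
#'
#' @param path TSV path.
#' @return Data frame `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(df)))
  df
}
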