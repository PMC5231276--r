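# ---- spatially resolved interaction maps -----------------------------------

#' Spatial grid of effective active-pair counts
#'
#' Divides `region` into `bin`-sized half-open bins anchored at the region
#' start and accumulates, for every significant proxy pair `(P, Q)`, each
#' active LD member pair: a member `u` of `LD(P)` active in `e_a` and `v` of
#' `LD(Q)` active in `e_b` contributes `1 / (|LD(P)| * |LD(Q)|)` to the bin
#' pair indexed by the two members' positions.  With `symmetrize = TRUE`
#' (default) half of each contribution lands in each of the mirror cells so
#' the matrix is symmetric while its total still equals
#' [pair_effective_count()] restricted to the region.  Members outside the
#' region are dropped and counted in the `dropped` attribute.
#'
#' @inheritParams pair_effective_count
#' @param region list or vector `(chrom, start, end)`; `start`/`end` are
#'   1-based positions bounding the mapped window.
#' @param bin bin width in bases (default 20,000).
#' @param symmetrize mirror contributions across the diagonal.
#' @return Object of class `spatial_grid`: `values` (bins x bins matrix),
#'   `region`, `bin`, `breaks`, attribute `dropped`.
#' @export
spatial_map <- function(sig_pairs, ld_groups, segs, e_a, e_b, region,
                        bin = 20000L, symmetrize = TRUE, chrom = NULL) {
  start <- as.numeric(region[["start"]]); end <- as.numeric(region[["end"]])
  if (is.null(chrom)) chrom <- as.character(region[["chrom"]])
  nb <- ceiling((end - start) / bin)
  vals <- matrix(0, nb, nb)
  dropped <- 0L
  bin_of <- function(pos) floor((pos - start) / bin) + 1
  member_info <- function(proxy, epi, pos_fallback) {
    grp <- ld_groups[[proxy]]
    pos <- if (is.null(grp)) pos_fallback else grp$members$pos
    act <- positions_active(pos, segs[[epi]], chrom)
    list(pos = pos[act], size = length(pos))
  }
  for (r in seq_len(nrow(sig_pairs))) {
    u <- member_info(sig_pairs$snp_i[r], e_a, sig_pairs$pos_i[r])
    v <- member_info(sig_pairs$snp_j[r], e_b, sig_pairs$pos_j[r])
    if (!length(u$pos) || !length(v$pos)) next
    w <- 1 / (u$size * v$size)
    bu <- bin_of(u$pos); bv <- bin_of(v$pos)
    keep_u <- bu >= 1 & bu <= nb; keep_v <- bv >= 1 & bv <= nb
    dropped <- dropped + sum(!keep_u) + sum(!keep_v)
    for (a in bu[keep_u]) for (b in bv[keep_v]) {
      if (symmetrize) {
        vals[a, b] <- vals[a, b] + w / 2
        vals[b, a] <- vals[b, a] + w / 2
      } else vals[a, b] <- vals[a, b] + w
    }
  }
  structure(list(values = vals, region = region, bin = bin,
                 breaks = start + bin * (0:nb)),
            class = "spatial_grid", dropped = dropped)
}

#' Spatially resolved enrichment p-values
#'
#' Compares one epigenome combination's spatial grid (typically at a coarser
#' bin, e.g. 100 kb) with the grid summed over all combinations: per bin
#' pair, an upper-tail binomial test of the observed effective count against
#' `Binomial(ceiling(total), q)` where `q` is the combination's overall share
#' of the total.  Bin pairs whose expected count is below 1 are reported
#' untested (`NA`).
#'
#' @param grid `spatial_grid` for the combination of interest.
#' @param total_grid `spatial_grid` of the same geometry summed over all
#'   epigenome combinations.
#' @return `spatial_grid` whose `values` are p-values (`NA` = untested).
#' @export
spatial_enrichment <- function(grid, total_grid) {
  stopifnot(identical(dim(grid$values), dim(total_grid$values)),
            identical(grid$bin, total_grid$bin))
  tot <- sum(total_grid$values)
  if (tot == 0) {
    out <- grid
    out$values[] <- NA_real_
    return(out)
  }
  q <- sum(grid$values) / tot
  n <- ceiling(total_grid$values)
  obs <- ceiling(grid$values)
  p <- matrix(NA_real_, nrow(n), ncol(n))
  testable <- n * q >= 1
  p[testable & obs == 0] <- 1
  idx <- which(testable & obs > 0)
  p[idx] <- pbinom(obs[idx] - 1, n[idx], q, lower.tail = FALSE)
  out <- grid
  out$values <- p
  out
}
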