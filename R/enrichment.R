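# ---- chromatin-state reduction and cell-type enrichment --------------------

# 15-state chromatin vocabulary (ChromHMM core model).  "ZNF/Rpts" is a
# single segmentation state; its two name parts are accepted as synonyms so
# either token classifies as active.
ACTIVE_STATES <- c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk",
                   "Enh", "EnhG", "ZNF", "Rpts", "ZNF/Rpts")
INACTIVE_STATES <- c("Het", "TssBiv", "BivFlnk", "EnhBiv",
                     "ReprPC", "ReprPCWk", "Quies")

#' Classify a chromatin-state label as active or inactive
#'
#' Reduces the 15-state vocabulary: transcribed (TssA, TssAFlnk, TxFlnk, Tx,
#' TxWk), enhancer (Enh, EnhG) and zinc-finger/repeat (ZNF/Rpts) states are
#' *active*; heterochromatin, bivalent, Polycomb-repressed and quiescent
#' states (Het, TssBiv, BivFlnk, EnhBiv, ReprPC, ReprPCWk, Quies) are
#' *inactive*.  Unknown labels are an error naming the label.
#'
#' @param state_label character vector of state labels.
#' @return Logical vector, `TRUE` for active.
#' @export
classify_active <- function(state_label) {
  known <- state_label %in% c(ACTIVE_STATES, INACTIVE_STATES)
  if (!all(known))
    stop("unknown chromatin state label: ", state_label[!known][1L])
  state_label %in% ACTIVE_STATES
}

# is each 1-based position inside an active interval of `gr`? Positions are
# converted to the BED half-open convention via the GRanges 1-based closed
# representation; uncovered positions count inactive (strict mode errors).
positions_active <- function(pos, gr, chrom, strict = FALSE) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::findOverlaps(q, gr, select = "first")
  if (anyNA(hit)) {
    if (strict) stop("SNP position not covered by the segmentation")
    warning(sum(is.na(hit)), " SNP position(s) uncovered; counted inactive")
  }
  act <- classify_active(gr$state)
  out <- logical(length(pos))
  out[!is.na(hit)] <- act[hit[!is.na(hit)]]
  out
}

#' LD-group activity profile
#'
#' For every (proxy, epigenome) pair, the mean frequency of epigenetically
#' active states over the proxy's LD group: the fraction of LD members whose
#' position lies in an active interval.  Also computes each epigenome's
#' genome-wide background `b`, the active fraction of the segmentation by
#' length.
#'
#' @param ld_groups an `ld_groups` object ([read_ld_groups()] /
#'   [simulate_ld_groups()]).
#' @param segs a `segmentation_set`.
#' @param chrom chromosome name the positions live on (default the first
#'   seqname of the first segmentation).
#' @param strict error on uncovered member positions instead of counting them
#'   inactive.
#' @return List of class `activity_profile`: `f` (proxies x epigenomes matrix
#'   of LD-group mean active frequencies) and `b` (named vector of background
#'   active fractions).
#' @export
activity_profile <- function(ld_groups, segs, chrom = NULL, strict = FALSE) {
  if (is.null(chrom))
    chrom <- as.character(GenomicRanges::seqnames(segs[[1L]])[1L])
  # one interval query per epigenome over the pooled member positions
  sizes <- vapply(ld_groups, function(g) nrow(g$members), integer(1))
  all_pos <- unlist(lapply(ld_groups, function(g) g$members$pos),
                    use.names = FALSE)
  grp_idx <- rep(seq_along(ld_groups), sizes)
  f <- matrix(NA_real_, length(ld_groups), length(segs),
              dimnames = list(names(ld_groups), names(segs)))
  for (e in names(segs)) {
    act <- positions_active(all_pos, segs[[e]], chrom, strict)
    f[, e] <- as.vector(rowsum(as.numeric(act), grp_idx)) / sizes
  }
  b <- vapply(segs, function(gr) {
    w <- GenomicRanges::width(gr)
    sum(w[classify_active(gr$state)]) / sum(w)
  }, numeric(1))
  structure(list(f = f, b = b), class = "activity_profile")
}

#' Single-SNP enrichment of active states in one epigenome
#'
#' Upper-tail binomial test of the observed number of active proxies against
#' the epigenome's genome-wide background: the observed count is the sum of
#' LD-group active frequencies over the proxy panel, rounded up to an
#' integer, compared against `Binomial(m, b)`.
#'
#' @param profile an [activity_profile()].
#' @param epigenome epigenome id (column of `profile$f`).
#' @param m total number of proxy SNPs (defaults to the panel size).
#' @return Upper-tail p-value.
#' @export
single_snp_enrichment <- function(profile, epigenome, m = nrow(profile$f)) {
  stopifnot(m >= 1)
  observed <- ceiling(sum(profile$f[, epigenome]))
  b <- profile$b[[epigenome]]
  if (b == 0 && observed > 0) {
    warning("background active fraction is 0 with active observations")
    return(.Machine$double.xmin)
  }
  pbinom(observed - 1L, m, b, lower.tail = FALSE)
}

#' Effective number of active SNP pairs in an ordered epigenome combination
#'
#' For each significant proxy pair `(P, Q)` the contribution is the number of
#' LD member pairs `(u, v)` with `u` in `LD(P)` active in `E_a` and `v` in
#' `LD(Q)` active in `E_b`, divided by `|LD(P)| * |LD(Q)|`; contributions are
#' summed over the proxy pairs.  The assignment is ordered: the pair's first
#' SNP is evaluated in `E_a` and the second in `E_b`.  A proxy without an LD
#' group is treated as a singleton group of itself.
#'
#' @param sig_pairs data frame with columns `snp_i`, `snp_j` (proxy ids), as
#'   returned by [significant_pairs()].
#' @param ld_groups an `ld_groups` object; proxies absent from it need a
#'   `pos` column in `sig_pairs` (`pos_i`, `pos_j`) to act as singletons.
#' @param segs a `segmentation_set`.
#' @param e_a,e_b epigenome ids.
#' @param chrom chromosome of the positions.
#' @return Effective count (numeric scalar in `[0, nrow(sig_pairs)]`).
#' @export
pair_effective_count <- function(sig_pairs, ld_groups, segs, e_a, e_b,
                                 chrom = NULL) {
  if (is.null(chrom))
    chrom <- as.character(GenomicRanges::seqnames(segs[[1L]])[1L])
  frac_active <- function(proxy, epi, pos_fallback) {
    grp <- ld_groups[[proxy]]
    if (is.null(grp)) {
      if (is.null(pos_fallback)) stop("proxy ", proxy, " has no LD group ",
                                      "and no fallback position")
      pos <- pos_fallback
    } else pos <- grp$members$pos
    mean(positions_active(pos, segs[[epi]], chrom))
  }
  total <- 0
  for (r in seq_len(nrow(sig_pairs))) {
    fa <- frac_active(sig_pairs$snp_i[r], e_a, sig_pairs$pos_i[r])
    fb <- frac_active(sig_pairs$snp_j[r], e_b, sig_pairs$pos_j[r])
    total <- total + fa * fb
  }
  total
}

#' Binomial enrichment test for one epigenome combination
#'
#' Compares the effective number of active pairs with the background value
#' given by the product of the two epigenomes' active-state fractions and the
#' total number of significant pairs: upper-tail
#' `P[Binomial(n_sig_pairs, b_a * b_b) >= ceiling(effective_count)]`.
#'
#' @param effective_count from [pair_effective_count()].
#' @param n_sig_pairs total number of significant SNP pairs (>= 1).
#' @param b_a,b_b background active fractions of the two epigenomes.
#' @return List of class `pair_enrichment`: `effective_count`, `n_sig_pairs`,
#'   `background_prob`, `p_value`.
#' @export
pair_enrichment <- function(effective_count, n_sig_pairs, b_a, b_b) {
  stopifnot(n_sig_pairs >= 1, effective_count >= 0,
            effective_count <= n_sig_pairs + 1e-9)
  observed <- ceiling(effective_count)
  p <- if (observed == 0) 1 else
    pbinom(observed - 1L, n_sig_pairs, b_a * b_b, lower.tail = FALSE)
  structure(list(effective_count = effective_count,
                 n_sig_pairs = as.integer(n_sig_pairs),
                 background_prob = b_a * b_b, p_value = p),
            class = "pair_enrichment")
}

#' Enrichment landscape over all ordered epigenome combinations
#'
#' [pair_effective_count()] and [pair_enrichment()] for every ordered pair of
#' epigenomes.  The LD-group activity fractions are computed once per
#' epigenome ([activity_profile()]), after which each combination's effective
#' count is a sum of products of the two fractions — identical to calling
#' [pair_effective_count()] per combination, but with one interval query per
#' epigenome instead of one per (pair, combination).  Every proxy named in
#' `sig_pairs` must have an LD group.
#'
#' @inheritParams pair_effective_count
#' @return Data frame: `e_a`, `e_b`, `effective_count`, `background_prob`,
#'   `p_value`, ordered by `p_value`.
#' @export
enrichment_landscape <- function(sig_pairs, ld_groups, segs, chrom = NULL) {
  prof <- activity_profile(ld_groups, segs, chrom)
  i_idx <- match(sig_pairs$snp_i, rownames(prof$f))
  j_idx <- match(sig_pairs$snp_j, rownames(prof$f))
  if (anyNA(i_idx) || anyNA(j_idx))
    stop("every proxy in sig_pairs needs an LD group")
  combos <- expand.grid(e_a = names(segs), e_b = names(segs),
                        stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(k) {
    ec <- sum(prof$f[i_idx, combos$e_a[k]] * prof$f[j_idx, combos$e_b[k]])
    pe <- pair_enrichment(ec, nrow(sig_pairs),
                          prof$b[[combos$e_a[k]]], prof$b[[combos$e_b[k]]])
    data.frame(e_a = combos$e_a[k], e_b = combos$e_b[k],
               effective_count = ec, background_prob = pe$background_prob,
               p_value = pe$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value), ]
}
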