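# ---- synthetic chromatin-state segmentations and LD-proxy groups -----------
#
# The generator tiles the chromosome around each SNP with a "core" segment
# containing the SNP and an adjacent "shadow" segment carrying the opposite
# activity.  LD members placed in the core share the proxy's activity in
# every epigenome; members placed in the shadow disagree in every epigenome.
# With the default 5-kb SNP spacing core and shadow tile the region exactly:
# core [pos - d/4, pos + d/4), shadow [pos + d/4, pos + 3d/4).

sample_state <- function(n, active) {
  act <- setdiff(ACTIVE_STATES, "ZNF/Rpts")   # canonical single tokens
  ifelse(active, sample(act, n, replace = TRUE),
         sample(INACTIVE_STATES, n, replace = TRUE))
}

#' Simulate chromatin-state segmentations across reference epigenomes
#'
#' Each SNP's core segment is active with probability `base_active_prob` in
#' every epigenome, independently, except for SNPs belonging to planted pairs:
#' in the designated epigenome combination `(e_a, e_b)` the first SNP of each
#' planted pair is active in `e_a` and the second in `e_b` with probability
#' `boost_prob`.  States are drawn from the 15-label vocabulary so the
#' active/inactive reduction is exercised.  Output is deterministic given
#' `seed`.
#'
#' @param snp_positions sorted 1-based SNP positions (regular spacing
#'   assumed, default layout 5 kb).
#' @param n_epigenomes number of epigenomes (ids `E001`, `E002`, ...).
#' @param base_active_prob per-(SNP, epigenome) active probability.
#' @param planted optional list `(e_a, e_b, pairs, boost_prob)`: `pairs` is a
#'   2-column matrix of SNP indices; `e_a`/`e_b` are epigenome indices or ids.
#' @param seed integer seed.
#' @param chrom chromosome name for the BED output.
#' @return A `segmentation_set` (named list of `GRanges` with `state`).
#' @export
simulate_epigenomes <- function(snp_positions, n_epigenomes,
                                base_active_prob, planted = NULL,
                                seed = 1L, chrom = "chr6") {
  stopifnot(base_active_prob >= 0, base_active_prob <= 1)
  ids <- sprintf("E%03d", seq_len(n_epigenomes))
  m <- length(snp_positions)
  d <- if (m > 1L) min(diff(sort(snp_positions))) else 5000L
  pos <- sort(snp_positions)
  if (!is.null(planted)) {
    to_idx <- function(e) if (is.character(e)) match(e, ids) else as.integer(e)
    ea <- to_idx(planted$e_a); eb <- to_idx(planted$e_b)
    if (anyNA(c(ea, eb)) || any(c(ea, eb) < 1L) || any(c(ea, eb) > n_epigenomes))
      stop("planted epigenome index out of range")
    boost <- planted$boost_prob
    stopifnot(boost >= 0, boost <= 1)
    ppairs <- matrix(as.integer(planted$pairs), ncol = 2L)
  }
  set.seed(seed)
  segs <- setNames(vector("list", n_epigenomes), ids)
  for (e in seq_len(n_epigenomes)) {
    p_active <- rep(base_active_prob, m)
    if (!is.null(planted)) {
      if (e == ea) p_active[ppairs[, 1L]] <- boost
      if (e == eb) p_active[ppairs[, 2L]] <- boost
    }
    core_active <- runif(m) < p_active
    start1 <- c(rbind(pos - d / 4, pos + d / 4))        # 1-based starts
    end1 <- c(rbind(pos + d / 4 - 1, pos + 3 * d / 4 - 1))
    states <- c(rbind(sample_state(m, core_active),
                      sample_state(m, !core_active)))
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start1, end1))
    gr$state <- states
    segs[[e]] <- gr
  }
  structure(segs, class = "segmentation_set")
}

#' Simulate LD-proxy groups with controlled activity concordance
#'
#' Every proxy receives a group of `group_size` LDed SNPs including itself.
#' Each additional member is *concordant* with probability
#' `activity_concordance`: concordant members are placed inside the proxy's
#' core segment (sharing its chromatin state in every epigenome of a
#' segmentation generated by [simulate_epigenomes()] on the same positions),
#' discordant members inside the adjacent shadow segment (opposite state).
#' Member `r2` values are drawn uniformly from (0.5, 1].
#'
#' @param proxies data frame with columns `id` and `pos` (e.g. a
#'   [genotype_matrix()]'s `snps`).
#' @param group_size LD group size including the proxy (>= 1).
#' @param activity_concordance probability a member shares the proxy's
#'   activity.
#' @param seed integer seed.
#' @param spacing SNP spacing in bases (must match the segmentation layout).
#' @return An `ld_groups` object.
#' @export
simulate_ld_groups <- function(proxies, group_size, activity_concordance = 1,
                               seed = 1L, spacing = 5000L) {
  stopifnot(group_size >= 1, activity_concordance >= 0,
            activity_concordance <= 1)
  set.seed(seed)
  d <- spacing
  groups <- lapply(seq_len(nrow(proxies)), function(k) {
    pid <- proxies$id[k]; pos <- proxies$pos[k]
    members <- data.frame(snp_id = pid, pos = pos, r2 = 1,
                          stringsAsFactors = FALSE)
    if (group_size > 1L) {
      extra <- group_size - 1L
      conc <- runif(extra) < activity_concordance
      # concordant: inside the core; discordant: inside the shadow
      mpos <- ifelse(conc,
                     pos + sample(seq(-d / 4 + 1, d / 4 - 2), extra,
                                  replace = TRUE),
                     pos + sample(seq(d / 4 + 1, 3 * d / 4 - 2), extra,
                                  replace = TRUE))
      members <- rbind(members, data.frame(
        snp_id = sprintf("%s_ld%03d", pid, seq_len(extra)),
        pos = as.integer(mpos),
        r2 = runif(extra, 0.5 + 1e-6, 1),
        stringsAsFactors = FALSE))
    }
    list(proxy_id = pid, members = members)
  })
  structure(setNames(groups, proxies$id), class = "ld_groups")
}
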