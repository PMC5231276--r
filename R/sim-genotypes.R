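#' Specify a synthetic case/control genotype simulation
#'
#' Defines a pairwise exponential-family ("Potts-like") genotype distribution
#' separately for the case and the control group.  Each SNP carries a 2-vector
#' field `h = (h(1), h(2))` (level 0 is the baseline), and selected SNP pairs
#' carry a 2x2 coupling matrix `J[a, b]`, `a, b` in `{1, 2}`.  Differences in
#' couplings between the two groups are the planted epistatic signal: they
#' produce differences in allele-frequency correlations (differential LD)
#' between case and control samples while marginals can be kept identical.
#'
#' @param n_case,n_control number of case / control individuals (>= 1).
#' @param m_snps number of SNPs (>= 1).
#' @param fields_case,fields_control `m_snps x 2` matrix of field parameters
#'   (recycled from a single 2-vector, or 0).
#' @param couplings_case,couplings_control list of couplings built with
#'   [coupling()].
#' @param missing_rate probability that any genotype call is set missing,
#'   uniformly at random.
#' @param gibbs_sweeps burn-in sweeps of the Gibbs sampler (>= 50 whenever any
#'   coupling is nonzero; ignored for coupling-free specs, which are sampled
#'   exactly).
#' @param seed integer seed; fully determines the output.
#' @return An object of class `sim_spec`.
#' @seealso [simulate_genotypes()]
#' @export
sim_spec <- function(n_case, n_control, m_snps,
                     fields_case = 0, fields_control = 0,
                     couplings_case = list(), couplings_control = list(),
                     missing_rate = 0, gibbs_sweeps = 100L, seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1, m_snps >= 1,
            missing_rate >= 0, missing_rate <= 1)
  expand_fields <- function(f) {
    if (is.null(dim(f))) {
      f <- matrix(rep_len(as.numeric(f), 2L), m_snps, 2L, byrow = TRUE)
    }
    stopifnot(nrow(f) == m_snps, ncol(f) == 2L)
    f
  }
  fc <- expand_fields(fields_case)
  fk <- expand_fields(fields_control)
  check_coup <- function(cl) {
    for (cp in cl) {
      stopifnot(inherits(cp, "snp_coupling"))
      if (cp$i >= cp$j || cp$j > m_snps)
        stop("coupling indices must satisfy i < j <= m_snps")
    }
    cl
  }
  if (!all(is.finite(fc)) || !all(is.finite(fk)))
    stop("non-finite field parameters")
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 m_snps = as.integer(m_snps),
                 fields_case = fc, fields_control = fk,
                 couplings_case = check_coup(couplings_case),
                 couplings_control = check_coup(couplings_control),
                 missing_rate = missing_rate,
                 gibbs_sweeps = as.integer(gibbs_sweeps),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Coupling between two SNPs
#'
#' @param i,j SNP indices, `i < j`.
#' @param J 2x2 numeric matrix `J[a, b]` over levels `{1, 2} x {1, 2}`, or a
#'   single number placed at `J[1, 1]`.
#' @return An object of class `snp_coupling`.
#' @export
coupling <- function(i, j, J) {
  if (length(J) == 1L) J <- matrix(c(J, 0, 0, 0), 2L, 2L)
  J <- matrix(as.numeric(J), 2L, 2L)
  if (!all(is.finite(J))) stop("non-finite coupling parameters")
  if (i >= j) stop("coupling requires i < j")
  structure(list(i = as.integer(i), j = as.integer(j), J = J),
            class = "snp_coupling")
}

# collect a group's couplings onto a shared pair list -> P x 4 matrix with
# column order (1,1),(1,2),(2,1),(2,2)
coupling_matrix <- function(couplings, pairs) {
  Jm <- matrix(0, nrow(pairs), 4L)
  if (length(couplings)) {
    key <- paste(pairs[, 1L], pairs[, 2L])
    for (cp in couplings) {
      p <- match(paste(cp$i, cp$j), key)
      Jm[p, ] <- as.vector(t(cp$J))
    }
  }
  Jm
}

sim_pairs <- function(spec) {
  keys <- unique(do.call(rbind, lapply(c(spec$couplings_case,
                                         spec$couplings_control),
                                       function(cp) c(cp$i, cp$j))))
  if (is.null(keys)) return(matrix(integer(0), 0L, 2L,
                                   dimnames = list(NULL, c("i", "j"))))
  keys <- keys[order(keys[, 1L], keys[, 2L]), , drop = FALSE]
  dimnames(keys) <- list(NULL, c("i", "j"))
  keys
}

#' Draw case/control genotypes from a pairwise genotype model
#'
#' Samples each individual as an independent Gibbs chain (systematic scan over
#' SNPs, `gibbs_sweeps` burn-in, one retained state), case rows from the
#' case-parameterized distribution and control rows from the control one.
#' Specs without couplings are sampled exactly from the per-SNP Boltzmann
#' marginals `P(g = a) = exp(h(a)) / (1 + exp(h(1)) + exp(h(2)))`.
#'
#' SNP positions are laid out on a single synthetic chromosome at 5-kb spacing
#' starting at 31,000,000 so that downstream spatial-grid code paths
#' (31-33 Mb) are exercised without real coordinates.
#'
#' @param spec a [sim_spec()].
#' @return A list with elements `gm` (a [genotype_matrix()]; controls first,
#'   phenotype 1, then cases, phenotype 2) and `truth` (list with
#'   `planted_pairs`, the index pairs whose coupling differs between groups).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  pairs <- sim_pairs(spec)
  Jc <- coupling_matrix(spec$couplings_case, pairs)
  Jk <- coupling_matrix(spec$couplings_control, pairs)
  any_coupling <- nrow(pairs) > 0L && (any(Jc != 0) || any(Jk != 0))
  if (any_coupling && spec$gibbs_sweeps < 50L)
    stop("gibbs_sweeps must be >= 50 when any coupling is nonzero")
  m <- spec$m_snps
  set.seed(spec$seed)
  draw_group <- function(n, H, Jm) {
    # exact draw from the field-only marginals (also the chain init)
    w1 <- exp(H[, 1L]); w2 <- exp(H[, 2L])
    Z <- 1 + w1 + w2
    U0 <- matrix(runif(n * m), n, m)
    G <- matrix(0L, n, m)
    for (i in seq_len(m)) {
      u <- U0[, i] * Z[i]
      G[, i] <- ifelse(u < 1, 0L, ifelse(u < 1 + w1[i], 1L, 2L))
    }
    if (any_coupling) {
      theta <- c(as.vector(t(H)), as.vector(t(Jm)))
      U <- matrix(runif(n * spec$gibbs_sweeps * m), n, spec$gibbs_sweeps * m)
      G <- gibbs_sample_cpp(n, m, theta, pairs[, 1L] - 1L, pairs[, 2L] - 1L,
                            G, U, spec$gibbs_sweeps)
    }
    G
  }
  Gk <- draw_group(spec$n_control, spec$fields_control, Jk)
  Gc <- draw_group(spec$n_case, spec$fields_case, Jc)
  G <- rbind(Gk, Gc)
  if (spec$missing_rate > 0) {
    drop <- runif(length(G)) < spec$missing_rate
    G[drop] <- NA_integer_
  }
  phen <- c(rep(1L, spec$n_control), rep(2L, spec$n_case))
  gm <- genotype_matrix(G, phen)
  differ <- rowSums(Jc != Jk) > 0
  truth <- list(planted_pairs = pairs[differ, , drop = FALSE],
                planted_active_combo = NULL)
  list(gm = gm, truth = truth)
}
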