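#' Natural-abundance correction matrix for a carbon skeleton
#'
#' Lower-triangular basis mapping a true (tracer-only) mass-isotopomer
#' distribution to the observed one: column j (0-based mass M+j) is the
#' binomial distribution of extra mass contributed by the `n_carbons - j`
#' remaining 12C positions each carrying a 13C at natural abundance `q`.
#' Each column sums to 1. Covers the carbon skeleton only (derivatization
#' atoms are out of scope).
#'
#' @param n_carbons number of carbons (>= 1).
#' @param q natural 13C abundance (default 0.0107), in `[0, 0.5)`.
#' @return (n_carbons+1) x (n_carbons+1) matrix, observed = M %*% true.
#' @export
natural_abundance_matrix <- function(n_carbons, q = 0.0107) {
  stopifnot(n_carbons >= 1, q >= 0, q < 0.5)
  n <- n_carbons
  M <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    extra <- stats::dbinom(0:(n - j), n - j, q)
    M[(j + 1):(n + 1), j + 1] <- extra
  }
  M
}

#' Natural-abundance correction of an observed MID
#'
#' Solves `matrix %*% x = observed` by non-negative least squares, clips
#' (already-nonnegative by construction) and renormalizes to sum 1, and
#' reports the fit residual. Rejects the ill-conditioned regime q >= 0.5
#' through [natural_abundance_matrix()].
#'
#' @param observed intensity vector M+0..M+n (any scale; normalized
#'   internally).
#' @param M correction matrix from [natural_abundance_matrix()].
#' @return list: mid (corrected, sums to 1), residual (L2, on the normalized
#'   scale), raw (pre-normalization NNLS solution).
#' @export
correct_mid <- function(observed, M) {
  stopifnot(length(observed) == nrow(M))
  if (any(observed < 0)) stop("observed intensities must be non-negative")
  obs <- observed / sum(observed)
  sol <- pracma::lsqnonneg(M, obs)
  x <- sol$x
  res <- sqrt(sum((M %*% x - obs)^2))
  list(mid = x / sum(x), residual = res, raw = x)
}

#' Percent of a metabolite pool carrying at least one 13C
#'
#' `100 * (1 - M+0)` of a natural-abundance-corrected MID: the percentage of
#' molecules with one or more tracer-derived 13C atoms.
#'
#' @param mid corrected MID (fractions summing to 1).
#' @param corrected assert that the MID has been corrected; set `FALSE` only
#'   deliberately (rejected otherwise).
#' @return percent in `[0, 100]`.
#' @export
percent_labeled <- function(mid, corrected = TRUE) {
  if (!corrected) stop("refusing an uncorrected MID (set corrected = TRUE only after correction)")
  if (abs(sum(mid) - 1) > 1e-6) stop("MID must be normalized to sum 1")
  100 * (1 - mid[1])
}

#' Simulate a raw (observed) mass-isotopomer distribution
#'
#' Each molecule labels each tracer-accessible carbon independently with
#' probability `p` (binomial transfer model); every remaining 12C position
#' then carries a natural-abundance 13C with probability `q`. Returns the
#' normalized observed intensity vector over M+0..M+n.
#'
#' @param n_carbons carbon count (>= 1).
#' @param p per-carbon tracer labeling probability.
#' @param q natural 13C abundance.
#' @param n_molecules molecules sampled.
#' @param seed RNG seed.
#' @return list: mid (length n_carbons+1, sums to 1), n_molecules,
#'   truth = list(p, q, percent_labeled_expected).
#' @export
simulate_mid <- function(n_carbons, p, q = 0.0107, n_molecules = 1e5,
                         seed = 1L) {
  stopifnot(n_carbons >= 1, p >= 0, p <= 1, q >= 0, q <= 1)
  set.seed(seed)
  k_lab <- stats::rbinom(n_molecules, n_carbons, p)
  k_nat <- stats::rbinom(n_molecules, n_carbons - k_lab, q)
  mass <- k_lab + k_nat
  mid <- tabulate(mass + 1, nbins = n_carbons + 1) / n_molecules
  list(mid = mid, n_molecules = n_molecules,
       truth = list(p = p, q = q,
                    percent_labeled_expected = 100 * (1 - (1 - p)^n_carbons)))
}
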