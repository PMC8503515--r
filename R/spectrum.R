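# Principal scores and ancestral information: the core inference.
#
# Both statistics are linear in the genotype vector of one individual and
# depend only on the reference-population MAFs of the panel SNPs, so no
# eigendecomposition, no reference genotypes and no other study individuals
# enter the computation.

#' Loading vectors for principal scores and ancestral information
#'
#' For each reference population k with specific SNP set G_k and expected
#' allele counts mu_km = 2 f_km, two loading vectors are formed, both zero
#' outside G_k:
#' \describe{
#'   \item{b_k (principal-score loading)}{proportional to mu_k, i.e. MAF-
#'     weighted. With the default `"score-one"` normalization,
#'     b_k = mu_k / sum(mu_km^2), so a population-k member's expected score
#'     is exactly 1. The `"unit-norm"` variant b_k = mu_k / sqrt(sum(mu^2))
#'     is the asymptotic right singular vector of the reference genotype
#'     matrix and is exposed for users who want raw PCA-projection scale.}
#'   \item{d_k (ancestral-information loading)}{equal weights
#'     1 / sum(mu_km) on G_k, making X d_k the ratio of observed to expected
#'     population-k-specific allele count — the best linear unbiased
#'     estimator (BLUE) of the ancestral proportion for rare alleles.}
#' }
#'
#' @param panel a `snp_panel`; all MAFs must be positive.
#' @param loading_norm `"score-one"` (default) or `"unit-norm"`; affects
#'   principal scores only.
#' @return List of class `"asa_loadings"`: SNP ids and population factor,
#'   `mu`, matrices `b` and `d` (M x K), cached `sum_mu` and `sum_mu2`.
#' @export
make_loadings <- function(panel, loading_norm = c("score-one", "unit-norm")) {
  loading_norm <- match.arg(loading_norm)
  pops <- panel_pops(panel)
  sizes <- panel_sizes(panel)
  if (any(sizes == 0L)) stop("panel has a population with no SNPs")
  if (any(panel$maf <= 0)) stop("panel MAFs must be positive")
  mu <- 2 * panel$maf
  popf <- factor(panel$pop, levels = pops)
  M <- nrow(panel)
  K <- length(pops)
  ind <- matrix(0, M, K, dimnames = list(panel$id, pops))
  ind[cbind(seq_len(M), as.integer(popf))] <- 1
  sum_mu <- colSums(ind * mu)
  sum_mu2 <- colSums(ind * mu^2)
  bden <- if (loading_norm == "score-one") sum_mu2 else sqrt(sum_mu2)
  b <- (ind * mu) %*% diag(1 / bden, K)
  d <- ind %*% diag(1 / sum_mu, K)
  dimnames(b) <- dimnames(d) <- list(panel$id, pops)
  structure(list(snp_id = panel$id, pop = popf, pops = pops, mu = mu,
                 b = b, d = d, sum_mu = sum_mu, sum_mu2 = sum_mu2,
                 loading_norm = loading_norm),
            class = "asa_loadings")
}

# Validate genotype/panel column alignment and return genotypes with NA -> 0,
# in double storage, ready for matrix products.
align_genotypes <- function(genotypes, loadings) {
  if (is.null(dim(genotypes)))
    genotypes <- matrix(genotypes, nrow = 1,
                        dimnames = list(NULL, names(genotypes)))
  if (ncol(genotypes) != length(loadings$snp_id))
    stop("genotype columns do not match the panel (", ncol(genotypes),
         " vs ", length(loadings$snp_id), " SNPs)")
  if (!is.null(colnames(genotypes)) &&
      !identical(colnames(genotypes), loadings$snp_id))
    stop("genotype columns are misaligned with the panel SNP order")
  X <- genotypes
  X[is.na(X)] <- 0L
  storage.mode(X) <- "double"
  X
}

# Project genotype rows onto loading columns, one individual at a time, so
# an individual's result is bit-for-bit independent of the rest of the batch
# (a whole-matrix product may accumulate differently at different batch
# sizes).
row_project <- function(X, W) {
  out <- matrix(0, nrow(X), ncol(W),
                dimnames = list(rownames(X), colnames(W)))
  for (n in seq_len(nrow(X)))
    out[n, ] <- crossprod(X[n, ], W)
  out
}

#' Principal scores by projection onto reference principal directions
#'
#' a_nk = sum_m X(n,m) b_k(m): the projection of individual n's genotype
#' vector onto the MAF-weighted loading of population k. Reference-population
#' members converge to a score of 1 for their own population and exactly 0
#' for the others; admixed individuals get one nonzero score per
#' contributing population. Scores of one individual are unaffected by which
#' other individuals are in the batch.
#'
#' @param genotypes N x M allele-count matrix aligned to the panel (a single
#'   individual may be given as a named vector).
#' @param loadings an `asa_loadings` object.
#' @return N x K matrix of scores.
#' @export
principal_scores <- function(genotypes, loadings) {
  row_project(align_genotypes(genotypes, loadings), loadings$b)
}

#' Ancestral information (BLUE of the ancestral proportion)
#'
#' p_hat_nk = (observed count of population-k-specific minor alleles in
#' individual n) / (sum of their expected counts 2 f_km in population k) —
#' identically X d_k. Values are not constrained to sum to one across
#' populations and may legitimately exceed one when the study sample carries
#' the reference population's specific alleles at higher frequency than the
#' reference itself; they are never clipped.
#'
#' @inheritParams principal_scores
#' @return N x K matrix of ancestral information values.
#' @export
ancestral_information <- function(genotypes, loadings) {
  row_project(align_genotypes(genotypes, loadings), loadings$d)
}

#' Maximum likelihood ancestral proportion under the rare-allele model
#'
#' Solves, per individual and population, the score equation of the binomial
#' 0/1 likelihood prod_m (p mu_m)^X (1 - p mu_m)^(1-X):
#' p * sum_m mu_m (1 - X_m) / (1 - p mu_m) - sum_m X_m = 0,
#' by bracketed root finding on [0, (1 - 1e-9) / max(mu_m)] to absolute
#' tolerance 1e-10. The likelihood is defined for X in {0, 1}, so diploid
#' counts of 2 are truncated to 1 (with a warning); missing calls count as 0
#' copies. If an individual carries no population-k allele the MLE is
#' exactly 0; if the score equation has no sign change in the bracket the
#' upper bracket end is returned and flagged as a boundary solution.
#'
#' @inheritParams principal_scores
#' @param pops populations to estimate for; default all panel populations.
#' @return N x K matrix of MLEs with a logical attribute `"boundary"` of the
#'   same shape marking boundary solutions.
#' @export
mle_ancestral_information <- function(genotypes, loadings,
                                      pops = loadings$pops) {
  X <- align_genotypes(genotypes, loadings)
  if (any(X > 1)) {
    warning("genotype counts of 2 truncated to 1 for the 0/1 likelihood")
    X[X > 1] <- 1
  }
  eps <- 1e-9
  est <- matrix(0, nrow(X), length(pops),
                dimnames = list(rownames(genotypes), pops))
  boundary <- matrix(FALSE, nrow(X), length(pops),
                     dimnames = dimnames(est))
  for (k in pops) {
    in_k <- loadings$pop == k
    mu_k <- loadings$mu[in_k]
    upper <- (1 - eps) / max(mu_k)
    Xk <- X[, in_k, drop = FALSE]
    for (n in seq_len(nrow(Xk))) {
      x <- Xk[n, ]
      s <- sum(x)
      if (s == 0) next                      # likelihood decreasing in p
      mu0 <- mu_k[x == 0]
      g <- function(p) p * sum(mu0 / (1 - p * mu0)) - s
      if (g(upper) <= 0) {                  # no interior root
        est[n, k] <- upper
        boundary[n, k] <- TRUE
      } else {
        est[n, k] <- stats::uniroot(g, c(0, upper), tol = 1e-10)$root
      }
    }
  }
  attr(est, "boundary") <- boundary
  est
}

#' Fit an ancestral spectrum
#'
#' The main entry point: given study genotypes aligned to a panel of
#' population-specific SNPs, computes per-individual principal scores,
#' ancestral information (the BLUE of the ancestral proportion), optional
#' maximum likelihood estimates, total information, per-population specific
#' allele counts and genotype call rates. Only the panel MAFs enter the
#' loadings, so results for an individual do not depend on the rest of the
#' batch and are comparable across studies analysed with the same panel.
#'
#' @param genotypes N x M allele-count matrix (0/1/2, `NA` missing), columns
#'   aligned to `panel`.
#' @param panel a `snp_panel`.
#' @param mle if `TRUE`, also compute maximum likelihood estimates.
#' @param loading_norm normalization of the principal-score loading; see
#'   [make_loadings()].
#' @return Object of class `"ancestral_spectrum"` with components `scores`,
#'   `info`, `mle` (or `NULL`), `boundary`, `total_info`, `allele_counts`,
#'   `call_rate`, `pops`, `panel_sizes`, `loadings`.
#' @seealso [coef.ancestral_spectrum()], [summary.ancestral_spectrum()],
#'   [plot.ancestral_spectrum()], [write_results()]
#' @examples
#' panel <- simulate_panel(n_snps = c(A = 200, B = 200), seed = 1)
#' design <- admixture_design(p = c(A = 0.7, B = 0.3), n = 5)
#' X <- simulate_genotypes(panel, design, seed = 2)
#' fit <- ancestral_spectrum(X, panel)
#' coef(fit)
#' @export
ancestral_spectrum <- function(genotypes, panel, mle = FALSE,
                               loading_norm = c("score-one", "unit-norm")) {
  loadings <- make_loadings(panel, match.arg(loading_norm))
  X <- align_genotypes(genotypes, loadings)
  if (is.null(rownames(X)))
    rownames(X) <- paste0("ind", seq_len(nrow(X)))
  scores <- row_project(X, loadings$b)
  info <- row_project(X, loadings$d)
  counts <- info %*% diag(loadings$sum_mu, length(loadings$pops))
  dimnames(counts) <- dimnames(info)
  mle_est <- NULL
  boundary <- NULL
  if (mle) {
    mle_est <- mle_ancestral_information(X, loadings)
    boundary <- attr(mle_est, "boundary")
    attr(mle_est, "boundary") <- NULL
  }
  call_rate <- if (is.null(dim(genotypes))) mean(!is.na(genotypes)) else
    rowMeans(!is.na(genotypes))
  structure(list(scores = scores, info = info, mle = mle_est,
                 boundary = boundary, total_info = rowSums(info),
                 allele_counts = counts, call_rate = call_rate,
                 pops = loadings$pops, panel_sizes = panel_sizes(panel),
                 loadings = loadings, call = match.call()),
            class = "ancestral_spectrum")
}
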