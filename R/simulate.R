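# Synthetic panels and genotypes under the binomial rare-allele admixture
# model. Every estimator in the package is validated by parameter recovery
# against these generators.

#' Simulate a population-specific SNP panel
#'
#' Draws reference MAFs per population either uniformly on a window or from
#' explicit per-population MAF vectors, and lays the SNPs out on synthetic
#' coordinates (one chromosome per population, consecutive positions).
#'
#' @param n_snps named integer vector: SNPs per population (names are the
#'   population labels). Ignored for populations given explicit MAFs.
#' @param maf either `c(low, high)` with 0 < low <= high <= 0.5 for uniform
#'   draws (default the low-frequency window `c(0.01, 0.05)`), or a named
#'   list of explicit per-population MAF vectors.
#' @param seed integer seed; the panel is a deterministic function of the
#'   arguments and the seed.
#' @return A [snp_panel()].
#' @export
simulate_panel <- function(n_snps, maf = c(0.01, 0.05), seed = NULL) {
  if (is.null(names(n_snps))) stop("n_snps must be named by population")
  if (any(n_snps < 1)) stop("each population needs at least one SNP")
  pops <- names(n_snps)
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- function(k) {
    if (is.list(maf)) {
      f <- maf[[k]]
      if (is.null(f)) stop("explicit MAFs missing for population ", k)
      f
    } else {
      if (!(length(maf) == 2L && maf[1] > 0 && maf[1] <= maf[2] &&
            maf[2] <= 0.5))
        stop("maf window must satisfy 0 < low <= high <= 0.5")
      stats::runif(n_snps[[k]], maf[1], maf[2])
    }
  }
  fs <- lapply(pops, draw)
  if (any(unlist(fs) <= 0) || any(unlist(fs) > 0.5))
    stop("explicit MAFs must lie in (0, 0.5]")
  m <- vapply(fs, length, integer(1))
  snp_panel(
    chrom = rep(paste0("chr", seq_along(pops)), m),
    pos = unlist(lapply(m, seq_len)),
    id = unlist(mapply(function(k, mk) sprintf("%s_snp%05d", k, seq_len(mk)),
                       pops, m, SIMPLIFY = FALSE)),
    minor = "A", other = "C",
    pop = rep(pops, m), maf = unlist(fs)
  )
}

#' Build an admixture design
#'
#' A design is the matrix of true ancestral proportions handed to the
#' genotype simulator and recovered by the estimators in tests.
#'
#' @param p named numeric vector of ancestral proportions (one per
#'   population, >= 0), shared by all individuals; or an N x K matrix for
#'   per-individual proportions.
#' @param n number of individuals (ignored when `p` is a matrix).
#' @param label optional bookkeeping population label for the individuals.
#' @return N x K numeric matrix with population columns, sample rownames and
#'   attribute `"label"`.
#' @export
admixture_design <- function(p, n = 1L, label = NULL) {
  if (is.matrix(p)) design <- p else {
    if (is.null(names(p))) stop("p must be named by population")
    design <- matrix(rep(p, each = n), nrow = n,
                     dimnames = list(NULL, names(p)))
  }
  if (any(design < 0)) stop("ancestral proportions must be >= 0")
  if (is.null(rownames(design)))
    rownames(design) <- sprintf("ind%04d", seq_len(nrow(design)))
  attr(design, "label") <- label
  design
}

#' Simulate genotypes under the binomial admixture model
#'
#' For individual n with ancestral proportions p_nk and a SNP m specific to
#' population k with reference MAF f_km, each of the two allele copies is
#' carried independently with probability p_nk * f_km (a haplotype descends
#' from population k with probability p_nk and then carries the allele with
#' probability f_km), so the genotype is Binomial(2, p_nk * f_km). SNPs and
#' individuals are independent. A pure population-k member (p_nk = 1) is
#' Binomial(2, f_km) at its own SNPs and exactly 0 everywhere else;
#' individuals never carry alleles of populations with p_nk = 0.
#'
#' @param panel a [snp_panel()].
#' @param design an [admixture_design()] whose columns cover the panel's
#'   populations.
#' @param seed integer seed; output is deterministic given panel, design and
#'   seed.
#' @return N x M integer matrix aligned to the panel's SNP order, with the
#'   design kept as attribute `"design"`.
#' @export
simulate_genotypes <- function(panel, design, seed = NULL) {
  pops <- panel_pops(panel)
  miss <- setdiff(pops, colnames(design))
  if (length(miss))
    stop("design lacks proportions for population(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  N <- nrow(design)
  X <- matrix(0L, N, nrow(panel),
              dimnames = list(rownames(design), panel$id))
  for (k in pops) {
    pk <- design[, k]
    if (all(pk == 0)) next          # law is a point mass at zero genotypes
    cols <- which(panel$pop == k)
    prob <- outer(pk, panel$maf[cols])
    if (any(prob > 1)) stop("p_nk * f_km > 1: impossible allele probability")
    X[, cols] <- matrix(stats::rbinom(length(prob), 2L, prob),
                        nrow = N)
  }
  attr(X, "design") <- design
  X
}

#' Simulate a drifted or bottlenecked descendant population
#'
#' Emulates, at the expectation level, two phenomena seen when a study
#' population is matched against a reference panel: allele-frequency drift
#' (per-SNP frequencies scaled by a constant) and bottleneck loss of
#' specific alleles (only a random fraction of the panel's sites remain
#' polymorphic; the rest are fixed absent). Genotypes at a retained site of
#' population k are Binomial(2, scale * f_km); non-retained sites are 0. The
#' expected ancestral information of such a cohort, measured against the
#' unmodified reference MAFs, is scale times the retained share of
#' sum(mu_km) — approximately `scale * retain`.
#'
#' @param panel a [snp_panel()].
#' @param n number of individuals.
#' @param scale frequency scaling factor(s) >= 0, scalar or named per
#'   population; `scale * f` must stay <= 0.5.
#' @param retain fraction of sites retained, in (0, 1]; scalar or named.
#' @param seed integer seed.
#' @return N x M integer matrix with attributes `"retained"` (logical per
#'   panel SNP) and `"expected_info"` (named per-population conditional
#'   expectation of the ancestral information given the retained subset).
#' @export
simulate_drifted_population <- function(panel, n, scale = 1, retain = 1,
                                        seed = NULL) {
  pops <- panel_pops(panel)
  scale <- per_pop(scale, pops, "scale")
  retain <- per_pop(retain, pops, "retain")
  if (any(retain <= 0) || any(retain > 1))
    stop("retain fractions must lie in (0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  keep <- logical(nrow(panel))
  for (k in pops) {
    cols <- which(panel$pop == k)
    m_keep <- max(1L, round(retain[[k]] * length(cols)))
    keep[cols[sample.int(length(cols), m_keep)]] <- TRUE
  }
  f <- ifelse(keep, panel$maf * scale[as.character(panel$pop)], 0)
  if (any(f > 0.5)) stop("scaled frequency exceeds 0.5")
  X <- matrix(stats::rbinom(n * sum(keep), 2L, rep(f[keep], each = n)),
              nrow = n)
  out <- matrix(0L, n, nrow(panel),
                dimnames = list(sprintf("ind%04d", seq_len(n)), panel$id))
  out[, keep] <- X
  mu <- 2 * panel$maf
  expected <- vapply(pops, function(k) {
    in_k <- panel$pop == k
    scale[[k]] * sum(mu[in_k & keep]) / sum(mu[in_k])
  }, numeric(1))
  attr(out, "retained") <- keep
  attr(out, "expected_info") <- expected
  out
}
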