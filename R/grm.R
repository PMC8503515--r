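# GRM based on population-specific SNPs (GRM-PS), its expectation and
# closed-form eigenstructure. These are diagnostic/validation quantities:
# the inference path (principal scores, ancestral information) never
# eigendecomposes anything.

#' Genetic relationship matrix from population-specific SNPs
#'
#' Computes Z = (1/M) X X' from an allele-count matrix aligned to a panel of
#' population-specific SNPs. When the rows are individuals drawn purely from
#' distinct reference populations, the supports of their nonzero genotypes
#' are disjoint across populations, so cross-population entries are exactly
#' zero and Z is block-diagonal. Missing genotypes contribute zero copies
#' (the overwhelmingly likely call for rare alleles).
#'
#' @param genotypes N x M matrix of minor-allele counts (0/1/2, `NA`
#'   allowed), columns aligned to a `snp_panel`.
#' @return N x N symmetric matrix of class `"grm_ps"` with attribute `"M"`,
#'   the SNP-count normalizer.
#' @export
build_grm_ps <- function(genotypes) {
  M <- ncol(genotypes)
  if (is.null(M) || M == 0L) stop("genotype matrix has no SNP columns")
  X <- genotypes
  X[is.na(X)] <- 0L
  storage.mode(X) <- "double"
  Z <- tcrossprod(X) / M
  attr(Z, "M") <- M
  class(Z) <- c("grm_ps", class(Z))
  Z
}

#' Expected GRM-PS parameters
#'
#' Under the rare-allele model a population-k member carries each
#' population-k-specific allele copy with probability f_km, giving genotype
#' mean mu_km = 2 f_km and variance sigma^2_km = 2 f_km (1 - 2 f_km). The
#' expected GRM-PS is block-diagonal with compound-symmetric blocks: the
#' diagonal of block k is z_k = (1/M) sum_{m in G_k} 2 f_km and the
#' off-diagonal is z_kk = (1/M) sum_{m in G_k} 4 f_km^2.
#'
#' @param panel a `snp_panel`.
#' @param pop_sizes named vector of block sizes N_k covering the panel's
#'   populations.
#' @return Data frame of class `"egrm_params"` with columns `pop`, `n`,
#'   `m_k`, `z`, `z_kk`; attribute `"M"` holds the total panel size.
#' @export
egrm_params <- function(panel, pop_sizes) {
  if (nrow(panel) == 0L) stop("panel is empty")
  pops <- panel_pops(panel)
  n <- per_pop(pop_sizes, pops, "pop_sizes")
  M <- nrow(panel)
  mu <- 2 * panel$maf
  z <- vapply(pops, function(k) sum(mu[panel$pop == k]) / M, numeric(1))
  z_kk <- vapply(pops, function(k) sum(mu[panel$pop == k]^2) / M, numeric(1))
  out <- data.frame(pop = pops, n = as.integer(n), m_k = panel_sizes(panel),
                    z = z, z_kk = z_kk, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "M") <- M
  class(out) <- c("egrm_params", "data.frame")
  out
}

#' Closed-form eigenvalues of the expected GRM-PS
#'
#' Each compound-symmetric block k of the expected GRM-PS has one
#' population-informative eigenvalue lambda_k = z_k + (N_k - 1) z_kk with
#' eigenvector 1/sqrt(N_k) inside the block, and an (N_k - 1)-fold repeated
#' eigenvalue z_k - z_kk = (1/M) sum sigma^2_km that reflects only the
#' intra-population genotype variance and carries no structure information.
#'
#' @param params an `egrm_params` object.
#' @return Data frame with columns `pop`, `lambda`, `repeated_value`,
#'   `multiplicity`.
#' @export
egrm_eigen <- function(params) {
  data.frame(pop = params$pop,
             lambda = params$z + (params$n - 1) * params$z_kk,
             repeated_value = params$z - params$z_kk,
             multiplicity = params$n - 1L,
             stringsAsFactors = FALSE)
}

#' Build the expected GRM-PS matrix
#'
#' Materialises the block-diagonal expectation: block k is N_k x N_k with
#' z_k on the diagonal and z_kk elsewhere; cross-population entries are
#' exactly zero.
#'
#' @param params an `egrm_params` object.
#' @return N x N matrix, N = sum of block sizes, with block-wise sample
#'   indices as dimnames.
#' @export
build_egrm <- function(params) {
  N <- sum(params$n)
  Z <- matrix(0, N, N)
  at <- 0L
  for (i in seq_len(nrow(params))) {
    nk <- params$n[i]
    idx <- at + seq_len(nk)
    Z[idx, idx] <- params$z_kk[i]
    Z[cbind(idx, idx)] <- params$z[i]
    at <- at + nk
  }
  labs <- rep(params$pop, params$n)
  dimnames(Z) <- list(labs, labs)
  Z
}

#' Write a GRM to a tab-separated file
#'
#' Square matrix with sample ids as header row and leading column.
#'
#' @param grm square numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(SAMPLE = rownames(grm), grm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
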