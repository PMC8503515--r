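# Panel construction: per-population MAFs and population-specific SNP selection.

#' Construct a population-specific SNP panel object
#'
#' A SNP panel records, for each SNP, its genomic coordinate, the minor and
#' other allele characters, the single reference population in which the SNP
#' is polymorphic, and its minor allele frequency (MAF) in that population.
#' Panels drive all downstream computation: the loading vectors, principal
#' scores and ancestral information depend only on the panel MAFs, never on
#' the genotypes of the reference individuals themselves.
#'
#' @param chrom chromosome names (character or coercible).
#' @param pos 1-based positions (integer).
#' @param id SNP identifiers, unique.
#' @param minor,other single-character allele labels; `minor` is the allele
#'   whose copies are counted in genotype matrices.
#' @param pop the reference population each SNP is specific to.
#' @param maf minor allele frequency of the SNP in its specific population,
#'   in (0, 0.5].
#' @return A data frame of class `"snp_panel"` with one row per SNP, ordered
#'   by population, then chromosome, then position.
#' @export
snp_panel <- function(chrom, pos, id, minor, other, pop, maf) {
  panel <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos), id = as.character(id),
    minor = as.character(minor), other = as.character(other),
    pop = as.character(pop), maf = as.numeric(maf),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(panel$id))
    stop("panel SNP ids must be unique")
  if (any(!is.finite(panel$maf)) || any(panel$maf <= 0) || any(panel$maf > 0.5))
    stop("panel MAFs must lie in (0, 0.5]")
  panel <- panel[order(panel$pop, panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Populations represented in a panel
#'
#' @param panel a `snp_panel`.
#' @return Character vector of population labels, in panel order.
#' @export
panel_pops <- function(panel) unique(panel$pop)

#' Per-population SNP counts of a panel
#'
#' @param panel a `snp_panel`.
#' @return Named integer vector M_k, plus the total as attribute is not
#'   needed: `sum()` of the result gives M.
#' @export
panel_sizes <- function(panel) {
  tab <- table(factor(panel$pop, levels = panel_pops(panel)))
  stats::setNames(as.integer(tab), names(tab))
}

# Reference (non-target) population labels of an assignment table.
reference_pops <- function(assignment) {
  setdiff(unique(assignment$pop), "target")
}

check_assignment <- function(assignment, genotypes = NULL) {
  if (!all(c("sample", "pop") %in% names(assignment)))
    stop("assignment must have columns 'sample' and 'pop'")
  if (anyDuplicated(assignment$sample))
    stop("assignment sample ids must be unique")
  if (!is.null(genotypes)) {
    miss <- setdiff(assignment$sample, rownames(genotypes))
    if (length(miss))
      stop("samples in assignment absent from genotypes: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  invisible(assignment)
}

#' Per-population minor allele frequencies
#'
#' Computes, for every SNP, the frequency of the minor allele in each
#' reference population. The minor allele is designated once, globally, on
#' the pooled reference sample: if the counted allele has pooled frequency
#' above 0.5 the orientation is flipped (counts become `2 - count`) and the
#' allele labels are swapped; at a pooled frequency of exactly 0.5 the
#' lexicographically smaller allele character is taken as minor. Missing
#' genotypes are excluded from both numerator and denominator. A population
#' with no non-missing call at a SNP gets frequency `NA` and the SNP becomes
#' ineligible for panel selection.
#'
#' @param genotypes N x M integer matrix of allele counts (0/1/2, `NA` for
#'   missing), with sample ids as rownames and SNP ids as colnames. Counts
#'   refer to allele `a1` of `alleles`.
#' @param assignment data frame with columns `sample` and `pop`; `pop` is a
#'   reference population label or `"target"`. Target samples are ignored
#'   here: frequencies are reference-population quantities.
#' @param alleles optional data frame with columns `id`, `a1`, `a2` and
#'   optionally `chrom`, `pos`, giving the counted allele (`a1`) and the
#'   other allele per SNP. Defaults to `"A"`/`"C"` placeholders.
#' @return A data frame of class `"maf_table"`: columns `id`, `chrom`,
#'   `pos`, `minor`, `other`, then one frequency column per reference
#'   population. Attribute `"pops"` names the frequency columns.
#' @export
compute_maf <- function(genotypes, assignment, alleles = NULL) {
  check_assignment(assignment, genotypes)
  pops <- sort(reference_pops(assignment))
  if (!length(pops)) stop("no reference populations in assignment")
  ref <- assignment[assignment$pop != "target", , drop = FALSE]
  G <- genotypes[ref$sample, , drop = FALSE]
  if (!all(G %in% c(0L, 1L, 2L) | is.na(G)))
    stop("genotypes must be 0, 1, 2 or NA")

  snp_ids <- colnames(G)
  if (is.null(alleles)) {
    alleles <- data.frame(id = snp_ids, a1 = "A", a2 = "C",
                          chrom = NA_character_, pos = NA_integer_,
                          stringsAsFactors = FALSE)
  }
  alleles <- alleles[match(snp_ids, alleles$id), , drop = FALSE]
  if (anyNA(alleles$id)) stop("alleles table does not cover all SNPs")
  if (is.null(alleles$chrom)) alleles$chrom <- NA_character_
  if (is.null(alleles$pos)) alleles$pos <- NA_integer_

  obs <- !is.na(G)
  # pooled frequency of the counted allele across all reference samples
  pooled_copies <- colSums(G, na.rm = TRUE)
  pooled_n <- 2 * colSums(obs)
  pooled <- ifelse(pooled_n > 0, pooled_copies / pooled_n, NA_real_)

  flip <- !is.na(pooled) &
    (pooled > 0.5 | (pooled == 0.5 & alleles$a2 < alleles$a1))
  if (any(flip)) {
    G[, flip] <- 2L - G[, flip]
    tmp <- alleles$a1[flip]
    alleles$a1[flip] <- alleles$a2[flip]
    alleles$a2[flip] <- tmp
  }

  popf <- factor(ref$pop, levels = pops)
  # per-population copies / (2 * non-missing samples)
  copies <- rowsum(ifelse(obs, G, 0L), popf)        # K x M
  nonmiss <- rowsum(obs + 0L, popf)                 # K x M
  freq <- t(ifelse(nonmiss > 0, copies / (2 * nonmiss), NA_real_))
  colnames(freq) <- pops

  out <- data.frame(id = snp_ids, chrom = alleles$chrom, pos = alleles$pos,
                    minor = alleles$a1, other = alleles$a2,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(freq))
  rownames(out) <- NULL
  attr(out, "pops") <- pops
  class(out) <- c("maf_table", "data.frame")
  out
}

# Normalise a per-population parameter (scalar or named vector) to a named
# vector over `pops`.
per_pop <- function(x, pops, what) {
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x))) {
    if (length(x) == 1L) return(stats::setNames(rep(x, length(pops)), pops))
    stop(what, " must be a scalar or named per population")
  }
  miss <- setdiff(pops, names(x))
  if (length(miss)) stop(what, " missing for population(s): ",
                         paste(miss, collapse = ", "))
  x[pops]
}

#' Select SNPs specific to exactly one reference population
#'
#' A SNP is eligible for population k when its MAF is positive in k, exactly
#' zero in every other reference population, inside the closed MAF window of
#' k, and defined (non-missing) in all populations. From each population's
#' eligible set, `panel_size` SNPs are drawn uniformly without replacement
#' under the given seed, making panel construction fully reproducible.
#'
#' @param mafs a `maf_table` from [compute_maf()].
#' @param maf_window numeric `c(low, high)` applied to every population, or a
#'   named list/matrix-like of per-population windows. Closed on both ends.
#' @param panel_size number of SNPs to draw per population; scalar or named.
#' @param seed integer seed for the subsampling draw.
#' @return A [snp_panel()], ordered by population then coordinate.
#' @export
select_specific_snps <- function(mafs, maf_window = c(0.01, 0.05),
                                 panel_size, seed = 1L) {
  pops <- attr(mafs, "pops")
  if (is.null(pops)) stop("mafs must be a maf_table from compute_maf()")
  freq <- as.matrix(mafs[, pops, drop = FALSE])

  if (is.numeric(maf_window) && length(maf_window) == 2L) {
    win <- stats::setNames(rep(list(maf_window), length(pops)), pops)
  } else {
    win <- maf_window[pops]
    if (any(vapply(win, is.null, logical(1))))
      stop("maf_window missing for some population")
  }
  size <- per_pop(panel_size, pops, "panel_size")

  defined <- !apply(freq, 1L, anyNA)
  npoly <- rowSums(freq > 0, na.rm = TRUE)

  set.seed(as.integer(seed))
  picks <- vector("list", length(pops))
  names(picks) <- pops
  for (k in pops) {
    w <- win[[k]]
    eligible <- which(defined & npoly == 1L & freq[, k] > 0 &
                        freq[, k] >= w[1] & freq[, k] <= w[2])
    if (length(eligible) < size[[k]])
      stop(sprintf("population %s: %d eligible SNPs, panel size %d requested",
                   k, length(eligible), size[[k]]))
    picks[[k]] <- sort(eligible[sample.int(length(eligible), size[[k]])])
  }

  rows <- do.call(rbind, lapply(pops, function(k) {
    i <- picks[[k]]
    data.frame(chrom = mafs$chrom[i], pos = mafs$pos[i], id = mafs$id[i],
               minor = mafs$minor[i], other = mafs$other[i],
               pop = k, maf = freq[i, k], stringsAsFactors = FALSE)
  }))
  snp_panel(rows$chrom, rows$pos, rows$id, rows$minor, rows$other,
            rows$pop, rows$maf)
}

#' Tabulate a panel by population and MAF stratum
#'
#' Counts panel SNPs per population in cumulative MAF strata (> 0.5%, > 1%,
#' > 5%, > 10%), mirroring the usual summary of population-specific variant
#' catalogues. Singletons (exactly one allele copy in the reference
#' population) are only identifiable from a MAF when the per-population
#' sample size is known, so the singleton column is `NA` unless `pop_sizes`
#' is supplied.
#'
#' @param panel a `snp_panel` (may be empty).
#' @param pop_sizes optional named vector of reference sample sizes N_k.
#' @return Data frame with one row per population plus a `Total` row;
#'   columns `pop`, `n_snps`, `singleton`, `maf_gt_0.5pct`, `maf_gt_1pct`,
#'   `maf_gt_5pct`, `maf_gt_10pct`.
#' @export
tabulate_panel <- function(panel, pop_sizes = NULL) {
  pops <- panel_pops(panel)
  one_pop <- function(k) {
    f <- panel$maf[panel$pop == k]
    singleton <- NA_integer_
    if (!is.null(pop_sizes) && k %in% names(pop_sizes))
      singleton <- sum(abs(f * 2 * pop_sizes[[k]] - 1) < 1e-9)
    data.frame(pop = k, n_snps = length(f), singleton = singleton,
               maf_gt_0.5pct = sum(f > 0.005), maf_gt_1pct = sum(f > 0.01),
               maf_gt_5pct = sum(f > 0.05), maf_gt_10pct = sum(f > 0.10),
               stringsAsFactors = FALSE)
  }
  rows <- if (length(pops)) do.call(rbind, lapply(pops, one_pop)) else
    data.frame(pop = character(0), n_snps = integer(0),
               singleton = integer(0), maf_gt_0.5pct = integer(0),
               maf_gt_1pct = integer(0), maf_gt_5pct = integer(0),
               maf_gt_10pct = integer(0), stringsAsFactors = FALSE)
  total <- data.frame(pop = "Total", n_snps = sum(rows$n_snps),
                      singleton = if (nrow(rows) == 0 ||
                                      all(!is.na(rows$singleton)))
                                    sum(rows$singleton) else NA_integer_,
                      maf_gt_0.5pct = sum(rows$maf_gt_0.5pct),
                      maf_gt_1pct = sum(rows$maf_gt_1pct),
                      maf_gt_5pct = sum(rows$maf_gt_5pct),
                      maf_gt_10pct = sum(rows$maf_gt_10pct),
                      stringsAsFactors = FALSE)
  out <- rbind(rows, total)
  rownames(out) <- NULL
  out
}
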