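# File formats: VCF input (via vcfR) and the package's tab-separated panel,
# assignment and results tables.

count_gt_allele <- function(gt, allele_code) {
  # gt: character matrix of GT strings ("0/1", "1|1", "./.", NA).
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  miss <- is.na(gt) | a1 == "." | a2 == "." | a2 == ""
  cnt <- (a1 == allele_code) + (a2 == allele_code)
  cnt[miss] <- NA_integer_
  cnt
}

#' Read genotypes from a VCF file
#'
#' Reads hard-called GT fields and returns minor-allele counts. Only
#' biallelic single-nucleotide records are used; multiallelic or
#' multicharacter-allele records are skipped and counted. With a `panel`,
#' records are matched by CHROM + POS + unordered allele pair (never by ID,
#' which drifts across call sets): if the panel's minor allele is the VCF
#' ALT the count is the ALT dosage, if it is the REF the count is
#' `2 - dosage`, and a record whose alleles do not match the panel's pair is
#' skipped and counted as a mismatch. Strand flips are never guessed;
#' palindromic (A/T, C/G) panel sites are reported in a warning so the user
#' can audit them. Panel SNPs absent from the VCF yield all-missing columns,
#' listed in attribute `"missing_snps"`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param panel optional [snp_panel()]. Without it, all biallelic SNPs are
#'   returned as ALT-allele counts with an `"alleles"` attribute (columns
#'   `id`, `a1` = ALT (the counted allele), `a2` = REF, `chrom`, `pos`)
#'   suitable for [compute_maf()].
#' @param samples optional character vector restricting the sample columns.
#' @return N x M integer matrix (samples x SNPs, `NA` = missing) with
#'   bookkeeping attributes `"n_skipped"` (non-biallelic records),
#'   `"n_mismatch"` (allele-pair mismatches at panel positions) and, with a
#'   panel, `"missing_snps"`.
#' @export
read_vcf <- function(path, panel = NULL, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1)
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s))
      stop("samples absent from VCF: ", paste(missing_s, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }

  if (is.null(panel)) {
    keep <- which(biallelic)
    if (!length(keep)) stop("no biallelic SNP records in ", path)
    ids <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"], "_",
                  ref[keep], "_", alt[keep])
    X <- t(count_gt_allele(gt[keep, , drop = FALSE], "1"))
    colnames(X) <- ids
    attr(X, "alleles") <- data.frame(
      id = ids, a1 = alt[keep], a2 = ref[keep],
      chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
      stringsAsFactors = FALSE)
    attr(X, "n_skipped") <- n_skipped
    attr(X, "n_mismatch") <- 0L
    return(X)
  }

  pal <- (panel$minor == "A" & panel$other == "T") |
         (panel$minor == "T" & panel$other == "A") |
         (panel$minor == "C" & panel$other == "G") |
         (panel$minor == "G" & panel$other == "C")
  if (any(pal))
    warning(sum(pal), " palindromic (A/T or C/G) panel site(s) matched ",
            "literally; strand flips are not corrected: ",
            paste(utils::head(panel$id[pal], 5), collapse = ", "))

  key <- paste(fix[, "CHROM"], fix[, "POS"])
  pkey <- paste(panel$chrom, panel$pos)
  hit <- match(pkey, key)             # first record at each panel position
  X <- matrix(NA_integer_, ncol(gt), nrow(panel),
              dimnames = list(colnames(gt), panel$id))
  n_mismatch <- 0L
  found <- logical(nrow(panel))
  for (i in which(!is.na(hit))) {
    r <- hit[i]
    if (!biallelic[r]) next
    pair_vcf <- sort(c(ref[r], alt[r]))
    pair_panel <- sort(c(panel$minor[i], panel$other[i]))
    if (!identical(pair_vcf, pair_panel)) {
      n_mismatch <- n_mismatch + 1L
      next
    }
    code <- if (panel$minor[i] == alt[r]) "1" else "0"
    X[, i] <- count_gt_allele(gt[r, ], code)
    found[i] <- TRUE
  }
  if (!any(found)) stop("no panel SNPs found in ", path)
  missing_snps <- panel$id[!found]
  if (length(missing_snps))
    message(length(missing_snps), " panel SNP(s) absent from VCF (reported ",
            "in attr 'missing_snps'); their columns are all-missing")
  attr(X, "n_skipped") <- n_skipped
  attr(X, "n_mismatch") <- n_mismatch
  attr(X, "missing_snps") <- missing_snps
  X
}

#' Write / read a SNP panel file
#'
#' Tab-separated with header `CHROM POS ID MINOR OTHER POP MAF`, positions
#' 1-based, rows sorted by population then coordinate. MAFs are written with
#' 17 significant digits so that `read_panel(write_panel(x))` reproduces the
#' panel exactly.
#'
#' @param panel a [snp_panel()].
#' @param path file path.
#' @return `path` invisibly for the writer; a `snp_panel` for the reader.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(CHROM = panel$chrom, POS = panel$pos, ID = panel$id,
                    MINOR = panel$minor, OTHER = panel$other,
                    POP = panel$pop,
                    MAF = sprintf("%.17g", panel$maf),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  head_line <- readLines(path, n = 1L)
  expected <- c("CHROM", "POS", "ID", "MINOR", "OTHER", "POP", "MAF")
  if (!identical(strsplit(head_line, "\t")[[1]], expected))
    stop("malformed panel header at line 1 of ", path,
         " (expected: ", paste(expected, collapse = " "), ")")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character", "character",
                                         "character", "numeric"),
                          stringsAsFactors = FALSE)
  snp_panel(df$CHROM, df$POS, df$ID, df$MINOR, df$OTHER, df$POP, df$MAF)
}

#' Write / read a sample-to-population assignment file
#'
#' Two tab-separated columns, `SAMPLE` and `POP`.
#'
#' @param assignment data frame with columns `sample`, `pop`.
#' @param path file path.
#' @return `path` invisibly for the writer; a data frame for the reader.
#' @export
write_assignment <- function(assignment, path) {
  check_assignment(assignment)
  utils::write.table(
    data.frame(SAMPLE = assignment$sample, POP = assignment$pop),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  head_line <- readLines(path, n = 1L)
  if (!identical(strsplit(head_line, "\t")[[1]], c("SAMPLE", "POP")))
    stop("malformed assignment header at line 1 of ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  data.frame(sample = df$SAMPLE, pop = df$POP, stringsAsFactors = FALSE)
}

#' Write / read a results table
#'
#' Tab-separated, one row per individual in input order; see
#' [as.data.frame.ancestral_spectrum()] for the column layout.
#'
#' @param fit an `ancestral_spectrum` fit (or an already flattened data
#'   frame).
#' @param path file path.
#' @return `path` invisibly for the writer; a data frame for the reader.
#' @export
write_results <- function(fit, path) {
  df <- if (is.data.frame(fit)) fit else as.data.frame(fit)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  head_line <- readLines(path, n = 1L)
  if (!startsWith(head_line, "SAMPLE\t"))
    stop("malformed results header at line 1 of ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
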