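# Shared fixture builders: everything is generated in code.

# A maf_table built directly from a per-population frequency matrix
# (rows = SNPs, columns = populations).
make_maf_table <- function(freq, chrom = "1", pos = seq_len(nrow(freq)),
                           minor = "A", other = "C") {
  pops <- colnames(freq)
  stopifnot(!is.null(pops))
  out <- data.frame(id = sprintf("snp%03d", seq_len(nrow(freq))),
                    chrom = chrom, pos = pos, minor = minor, other = other,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(freq))
  attr(out, "pops") <- pops
  class(out) <- c("maf_table", "data.frame")
  out
}

# A two-SNP, one-population panel with given MAFs.
tiny_panel <- function(maf = c(0.1, 0.2), pop = "POP1") {
  snp_panel(chrom = "1", pos = seq_along(maf),
            id = paste0("s", seq_along(maf)),
            minor = "A", other = "C", pop = pop, maf = maf)
}

# Write a minimal VCF from a matrix of ALT-allele counts (NA = missing call).
write_test_vcf <- function(path, chrom, pos, ref, alt, counts,
                           extra_lines = character(0)) {
  samples <- rownames(counts)
  gt_of <- function(x) {
    out <- c("0/0", "0/1", "1/1")[x + 1L]
    out[is.na(x)] <- "./."
    out
  }
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt_of(counts[, i])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body, extra_lines), path)
  path
}
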