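# fixture builders shared across test files

# genotype_dataset from per-sample dosage specs:
# dosages = named list sample_id -> named integer vector rs_id -> dosage
# (0/1/2, NA = missing); markers absent from the vector are fully missing
dataset_from_dosages <- function(dosages, breed = "TestBreed") {
  reg <- poll_registry()
  ids <- names(dosages)
  geno <- matrix(NA_character_, length(ids), nrow(reg),
                 dimnames = list(ids, reg$rs_id))
  for (s in ids) {
    d <- dosages[[s]]
    for (m in names(d)) {
      if (is.na(d[[m]])) next
      row <- reg[reg$rs_id == m, ]
      poll <- row$poll_allele
      other <- if (row$allele1 == poll) row$allele2 else row$allele1
      gt <- switch(as.character(d[[m]]),
                   "0" = c(other, other),
                   "1" = c(other, poll),
                   "2" = c(poll, poll))
      geno[s, m] <- paste(sort(gt), collapse = "/")
    }
  }
  samples <- data.frame(sample_id = ids,
                        breed = rep_len(breed, length(ids)),
                        sex = rep_len("unknown", length(ids)),
                        stringsAsFactors = FALSE)
  genotype_dataset(samples, geno, provenance = "fixture")
}

# dosage vector covering every informative marker with the diplotype's
# complete-LD expectation
ld_dosages <- function(pc, pf) {
  reg <- poll_registry()
  d <- ifelse(reg$linked_mutation == "P_C", pc, pf)
  stats::setNames(as.integer(d), reg$rs_id)
}

# independent exhaustive rule table for the OPT panel, written directly
# from the published rule statements (not via pf_consensus/call_sample):
# at least 3 of 4 P_F SNPs called, at most one differing or missing,
# P_C SNP mandatory, trans arrangement (<= 2 poll alleles total)
opt_oracle <- function(pc, pf) {
  if (is.na(pc)) return("NO_RESULT")
  called <- pf[!is.na(pf)]
  n_missing <- 4L - length(called)
  if (length(called) < 3L) return("NO_RESULT")
  # majority dosage; with >= 3 called and budget 1, a definitive call
  # requires at least (length(called) - (1 - n_missing)) identical values
  tab <- table(called)
  modal_n <- max(tab)
  n_diff <- length(called) - modal_n
  if (sum(tab == modal_n) > 1L) return("NO_RESULT")    # tied vote
  if (n_missing + n_diff > 1L) return("NO_RESULT")
  pf_dosage <- as.integer(names(tab)[which.max(tab)])
  if (pc + pf_dosage > 2L) return("NO_RESULT")
  key <- paste0(pc, pf_dosage)
  out <- c("00" = "HH", "10" = "HPC", "01" = "HPF",
           "20" = "PCPC", "11" = "PCPF", "02" = "PFPF")[key]
  if (is.na(out)) "NO_RESULT" else unname(out)
}

# write a small VCF fixture; gt_rows = named list rs_id -> character vector
# of GT fields (one per sample); markers omitted have no record
write_vcf_fixture <- function(path, sample_ids, gt_rows,
                              registry = poll_registry()) {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_ids), collapse = "\t"))
  for (m in names(gt_rows)) {
    row <- registry[registry$rs_id == m, ]
    lines <- c(lines, paste(c(row$chrom, row$pos, m, row$allele1,
                              row$allele2, ".", "PASS", ".", "GT",
                              gt_rows[[m]]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
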