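test_that("wide genotype tables parse genotypes, metadata and missing tokens", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "geno.tsv")
  writeLines(c(
    paste("sample_id", "breed", "rs383143898", "rs801127025", "rs799403053",
          "rs210350155", "rs797088784", sep = "\t"),
    paste("S1", "Brahman", "TT", "CC", "TT", "CC", "GG", sep = "\t"),
    paste("S2", "Angus", "C/T", "--", "T C", "CA", "NN", sep = "\t")
  ), path)
  ds <- read_genotype_table(path)
  expect_equal(ds$samples$sample_id, c("S1", "S2"))
  expect_equal(ds$samples$breed, c("Brahman", "Angus"))
  expect_equal(unname(ds$geno["S1", "rs383143898"]), "T/T")
  expect_equal(sum(!is.na(ds$geno["S1", ])), 5L)       # 5 called markers
  # all dialect spellings normalize to sorted "X/Y"
  expect_equal(unname(ds$geno["S2", "rs383143898"]), "C/T")
  expect_equal(unname(ds$geno["S2", "rs799403053"]), "C/T")
  # missing tokens and absent columns become NA
  expect_true(is.na(ds$geno["S2", "rs801127025"]))
  expect_true(is.na(ds$geno["S2", "rs797088784"]))
  expect_true(all(is.na(ds$geno[, "rs799187101"])))
})

test_that("table reader rejects duplicate samples and warns on unknown columns", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("sample_id\trs383143898", "S1\tTT", "S1\tCC"), dup)
  expect_error(read_genotype_table(dup), "duplicate sample_id: S1")

  unk <- file.path(dir, "unk.tsv")
  writeLines(c("sample_id\trs383143898\trs999999999", "S1\tTT\tAA"), unk)
  expect_warning(ds <- read_genotype_table(unk), "rs999999999")
  expect_false("rs999999999" %in% colnames(ds$geno))
})

test_that("alias maps translate indel and strand-variant allele symbols", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "alias.tsv")
  writeLines(c("sample_id\trs383143898\trs801127025",
               "S1\tID\tDD"), path)
  ds <- read_genotype_table(
    path,
    alias_map = list(rs383143898 = c(I = "T", D = "C"),
                     rs801127025 = c(I = "T", D = "C"))
  )
  expect_equal(unname(ds$geno["S1", "rs383143898"]), "C/T")
  expect_equal(unname(ds$geno["S1", "rs801127025"]), "C/C")
  # without the alias map the unknown symbols are an error, not silence
  expect_error(read_genotype_table(path), "alias_map")
})

test_that("VCF reader decodes GT fields, missing calls and absent records", {
  dir <- withr::local_tempdir()
  path <- write_vcf_fixture(
    file.path(dir, "panel.vcf"),
    sample_ids = c("S1", "S2"),
    gt_rows = list(
      rs383143898 = c("1/1", "0/1"),   # ALT = T = poll allele
      rs210350155 = c("0/0", "./."),
      rs799403053 = c("0|1", ".")
    )
  )
  ds <- read_vcf(path)
  expect_equal(unname(ds$geno["S1", "rs383143898"]), "T/T")
  expect_equal(unname(ds$geno["S2", "rs383143898"]), "C/T")
  expect_equal(unname(ds$geno["S1", "rs210350155"]), "C/C")
  expect_true(is.na(ds$geno["S2", "rs210350155"]))
  expect_true(is.na(ds$geno["S2", "rs799403053"]))
  # marker with no VCF record: missing for every sample
  expect_true(all(is.na(ds$geno[, "rs797088784"])))
})

test_that("VCF reader rejects multi-allelic records and mismatched alleles", {
  dir <- withr::local_tempdir()
  reg <- poll_registry()
  multi <- file.path(dir, "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t2429319\trs383143898\tC\tT,G\t.\tPASS\t.\tGT\t1/2"
  ), multi)
  expect_error(read_vcf(multi), "multi-allelic")

  bad <- file.path(dir, "bad.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t2429319\trs383143898\tA\tG\t.\tPASS\t.\tGT\t0/1"
  ), bad)
  expect_error(read_vcf(bad), "rs383143898")
})

test_that("VCF and tabular readers agree on equivalent content", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(clean_sim_config(n_samples = 40, seed = 11))
  tsv <- file.path(dir, "sim.tsv")
  vcf <- file.path(dir, "sim.vcf")
  write_genotype_table(sim$dataset, tsv)
  write_vcf(sim$dataset, vcf)
  from_tsv <- read_genotype_table(tsv)
  from_vcf <- read_vcf(vcf)
  expect_equal(from_vcf$geno, from_tsv$geno)
  expect_equal(from_tsv$geno, sim$dataset$geno)
  # and the calls downstream are identical
  expect_equal(call_dataset(from_vcf, "OPT")$diplotype,
               call_dataset(from_tsv, "OPT")$diplotype)
})

test_that("phenotype reader canonicalizes status tokens case-insensitively", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pheno.csv")
  writeLines(c("sample_id,head_status",
               "S1,poll", "S2,SCUR", "S3,Horned", "S4,hornless"), path)
  expect_warning(ph <- read_phenotypes(path), "hornless")
  expect_equal(ph$head_status, c("Poll", "Scur", "Horn", "unknown"))

  onecol <- file.path(dir, "bad.csv")
  writeLines(c("sample_id", "S1"), onecol)
  expect_error(read_phenotypes(onecol), "head_status")
})

test_that("call reports round-trip through TSV", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_samples = 60, error_rate = 0.2,
                    recomb_prob = 0, seed = 3)
  sim <- simulate_dataset(cfg)
  calls <- call_dataset(sim$dataset, "OPT")
  expect_true(any(calls$diplotype == "NO_RESULT"))  # error rate forces some
  path <- file.path(dir, "calls.tsv")
  write_calls(calls, path)
  back <- read_calls(path)
  expect_equal(back$diplotype, calls$diplotype)
  expect_equal(back$reasons, calls$reasons)
  expect_equal(back$pf_dosages, calls$pf_dosages)
  expect_equal(back$pc_dosage, calls$pc_dosage)
  # NO_RESULT rows carry a non-empty reason
  nr <- back$diplotype == "NO_RESULT"
  expect_true(all(nchar(back$reasons[nr]) > 0))
  expect_true(all(back$reasons[!nr] == ""))

  empty <- call_dataset(
    genotype_dataset(data.frame(sample_id = character(0)),
                     matrix(NA_character_, 0, 10,
                            dimnames = list(NULL, poll_registry()$rs_id))),
    "OPT")
  write_calls(empty, path)
  expect_equal(nrow(read_calls(path)), 0L)
  expect_equal(length(readLines(path)), 1L)  # header only
})
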