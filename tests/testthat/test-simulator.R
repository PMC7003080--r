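test_that("config validation rejects malformed specifications", {
  expect_error(sim_config(breed_profiles = list(
    B = list(hap_freqs = c(H = 0.5, P_C = 0.5, P_F = 0.2)))),
    "sum to 1")
  expect_error(sim_config(breed_profiles = list(
    B = list(hap_freqs = c(A = 1, B = 0, C = 0)))),
    "named H, P_C, P_F")
  expect_error(sim_config(error_rate = 1.5), "\\[0,1\\]")
  expect_error(sim_config(penetrance = list(HH = c(Horn = 0.5, Scur = 0,
                                                   Poll = 0))),
               "distribution")
})

test_that("haplotype draws follow Hardy-Weinberg and are seed-deterministic", {
  cfg <- clean_sim_config(n_samples = 20000, seed = 101)
  t1 <- simulate_haplotypes(cfg)
  t2 <- simulate_haplotypes(cfg)
  expect_identical(t1, t2)
  t3 <- simulate_haplotypes(cfg, seed = 102)
  expect_false(identical(t1, t3))

  # closed-form Hardy-Weinberg class proportions for H=.6 PC=.3 PF=.1
  expected <- c(HH = 0.36, HPC = 0.36, HPF = 0.12,
                PCPC = 0.09, PCPF = 0.06, PFPF = 0.01)
  obs <- table(t1$true_diplotype)[names(expected)] / nrow(t1)
  for (cl in names(expected)) {
    se <- sqrt(expected[cl] * (1 - expected[cl]) / nrow(t1))
    expect_lt(abs(obs[[cl]] - expected[cl]), 4 * se + 1e-9,
              label = paste("class", cl))
  }

  # degenerate frequencies
  all_h <- simulate_haplotypes(clean_sim_config(
    n_samples = 50, hap_freqs = c(H = 1, P_C = 0, P_F = 0), seed = 1))
  expect_true(all(all_h$true_diplotype == "HH"))
})

test_that("complete-LD genotype emission matches the haplotype model", {
  truth <- data.frame(
    sample_id = c("A", "B", "C"),
    breed = "X",
    hap1 = c("H", "P_F", "P_C+P_F"),
    hap2 = c("P_C", "P_F", "H"),
    stringsAsFactors = FALSE
  )
  truth$true_diplotype <- haplotype_pair_class(truth$hap1, truth$hap2)
  expect_equal(truth$true_diplotype, c("HPC", "PFPF", "PCPF"))
  ds <- haplotypes_to_genotypes(truth)
  reg <- poll_registry()
  # H/P_C: heterozygous at the Celtic marker, dosage 0 at all P_F markers
  expect_equal(unname(ds$geno["A", "rs383143898"]), "C/T")
  pf_markers <- reg$rs_id[reg$linked_mutation == "P_F"]
  expect_true(all(vapply(pf_markers, function(m)
    allele_dosage(ds$geno["A", m], m), integer(1)) == 0L))
  # P_F/P_F: dosage 2 at all four OPT P_F markers
  opt <- poll_panel("OPT")
  expect_true(all(vapply(opt$pf_markers, function(m)
    allele_dosage(ds$geno["B", m], m), integer(1)) == 2L))
  # cis recombinant over H: carries one poll allele everywhere, so the
  # trans-assuming engine calls PCPF
  call_c <- call_sample(
    pc_dosage(ds$geno["C", opt$pc_marker], opt),
    vapply(opt$pf_markers, function(m)
      allele_dosage(ds$geno["C", m], m), integer(1)),
    opt)
  expect_equal(call_c$diplotype, "PCPF")
})

test_that("noise channels respect their degenerate settings", {
  cfg <- clean_sim_config(n_samples = 100, seed = 2)
  sim <- simulate_dataset(cfg)
  base <- sim$dataset

  # error rate 0 / artifact off / full call rates: unchanged
  expect_identical(apply_genotyping_error(base, cfg, seed = 1)$geno,
                   base$geno)
  expect_identical(apply_probe_artifact(base, cfg, seed = 1)$geno,
                   base$geno)
  expect_identical(apply_missingness(base, cfg, seed = 1)$geno, base$geno)

  # error rate 1: every dosage changes to a different one
  cfg_err <- clean_sim_config(n_samples = 100, seed = 2, error_rate = 1)
  noisy <- apply_genotyping_error(base, cfg_err, seed = 9)
  expect_true(all(noisy$geno != base$geno))

  # call rate 0 at one marker: that marker missing for everyone
  cr <- stats::setNames(rep(1, 10), poll_registry()$rs_id)
  cr["rs210350155"] <- 0
  cfg_miss <- sim_config(
    n_samples = 100,
    breed_profiles = list(Composite = list(
      hap_freqs = c(H = 0.6, P_C = 0.3, P_F = 0.1), call_rates = cr)),
    error_rate = 0, recomb_prob = 0, seed = 2)
  gone <- apply_missingness(base, cfg_miss, seed = 9)
  expect_true(all(is.na(gone$geno[, "rs210350155"])))
  expect_true(all(!is.na(gone$geno[, "rs383143898"])))

  # artifact: freq 1 + certain dropout wipes rs800947704 and nothing else
  cfg_art <- clean_sim_config(n_samples = 100, seed = 2)
  cfg_art$artifact$interfering_allele_freq <- 1
  hit <- apply_probe_artifact(base, cfg_art, seed = 9)
  expect_true(all(is.na(hit$geno[, "rs800947704"])))
  others <- setdiff(colnames(hit$geno), "rs800947704")
  expect_identical(hit$geno[, others], base$geno[, others])
})

test_that("full simulation is reproducible and composes all stages", {
  cfg <- sim_config(n_samples = 300, seed = 7)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_dataset(sim_config(n_samples = 300, seed = 8))
  expect_false(identical(s1$dataset$geno, s3$dataset$geno))

  s0 <- simulate_dataset(sim_config(n_samples = 0, seed = 7))
  expect_equal(nrow(s0$truth), 0L)
  expect_equal(nrow(s0$dataset$samples), 0L)
  expect_equal(nrow(s0$phenotypes), 0L)
})

test_that("allele frequencies recovered from simulated genotypes match the model", {
  cfg <- clean_sim_config(n_samples = 10000,
                          hap_freqs = c(H = 0.6, P_C = 0.3, P_F = 0.1),
                          seed = 31)
  sim <- simulate_dataset(cfg)
  # poll-allele frequency at the Celtic marker estimates the P_C frequency
  pc <- pc_dosage(sim$dataset$geno[, "rs383143898"], poll_panel("OPT"))
  f_hat <- mean(pc) / 2
  se <- sqrt(0.3 * 0.7 / (2 * cfg$n_samples))
  expect_lt(abs(f_hat - 0.3), 3 * se)
  # and at a P_F marker, the P_F frequency
  pf <- allele_dosage(sim$dataset$geno[, "rs210350155"], "rs210350155")
  expect_lt(abs(mean(pf) / 2 - 0.1), 3 * sqrt(0.1 * 0.9 / (2 * cfg$n_samples)))
})

test_that("phenotypes follow the configured penetrance", {
  truth <- data.frame(sample_id = sprintf("S%04d", 1:3000), breed = "X",
                      hap1 = "H", hap2 = "P_C",
                      true_diplotype = "HPC", stringsAsFactors = FALSE)
  cfg <- clean_sim_config(n_samples = 3000, seed = 13)
  ph <- simulate_phenotypes(truth, cfg, seed = 13)
  p_scur <- mean(ph$head_status == "Scur")
  expect_lt(abs(p_scur - 0.599), 3 * sqrt(0.599 * 0.401 / 3000))
  expect_equal(sum(ph$head_status == "Horn"), 0L)

  # degenerate penetrance
  cfg2 <- clean_sim_config(n_samples = 10, seed = 1,
                           penetrance = list(HPC = c(Horn = 0, Scur = 0,
                                                     Poll = 1)))
  ph2 <- simulate_phenotypes(truth[1:10, ], cfg2, seed = 1)
  expect_true(all(ph2$head_status == "Poll"))

  # missing class in the penetrance map is a config error
  truth$true_diplotype[1] <- "PFPF"
  expect_error(simulate_phenotypes(truth, cfg2, seed = 1), "PFPF")
})

test_that("sim configs round-trip through JSON", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(
    n_samples = 123,
    breed_profiles = list(
      Brahman = list(hap_freqs = c(H = 0.7, P_C = 0.25, P_F = 0.05),
                     call_rates = 0.98, weight = 2),
      Angus = list(hap_freqs = c(H = 0.2, P_C = 0.8, P_F = 0),
                   call_rates = 1, weight = 1)
    ),
    error_rate = 0.001,
    artifact = list(interfering_allele_freq = 0.07,
                    dropout_prob_given_G = 0.9, miscall_prob_given_G = 0.1),
    recomb_prob = 0.002,
    penetrance = penetrance_preset("breedplan"),
    seed = 99
  )
  path <- file.path(dir, "sim.json")
  sim_config_to_json(cfg, path)
  cfg2 <- sim_config_from_json(path)
  expect_equal(cfg2$n_samples, cfg$n_samples)
  expect_equal(cfg2$breed_profiles$Brahman$hap_freqs,
               cfg$breed_profiles$Brahman$hap_freqs)
  expect_equal(cfg2$breed_profiles$Angus$weight, 1)
  expect_equal(cfg2$error_rate, cfg$error_rate)
  expect_equal(cfg2$artifact, cfg$artifact)
  expect_equal(cfg2$penetrance, cfg$penetrance)
  # identical data under the round-tripped config
  expect_identical(simulate_dataset(cfg)$dataset$geno,
                   simulate_dataset(cfg2)$dataset$geno)
})
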