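#' Penetrance presets for head phenotype given diplotype
#'
#' Probability of each head status (Horn, Scur, Poll) per diplotype class:
#' \describe{
#'   \item{validation}{the idealized pattern seen in the accurately
#'     phenotyped validation herds: HH fully horned, HPC 59.9% scurred /
#'     40.1% polled, HPF and all P-homozygote/compound classes fully
#'     polled.}
#'   \item{breedplan}{the noisier field-recorded pattern, including the few
#'     percent of HH animals misrecorded as scurred or polled. The PCPF row
#'     is normalized to sum to one (Poll 0.9926).}
#' }
#'
#' @param name "validation" or "breedplan".
#' @return Named list: diplotype class -> numeric c(Horn, Scur, Poll)
#'   summing to 1.
#' @export
penetrance_preset <- function(name = c("validation", "breedplan")) {
  name <- match.arg(name)
  row <- function(h, s, p) c(Horn = h, Scur = s, Poll = p)
  if (name == "validation") {
    list(HH = row(1, 0, 0),
         HPC = row(0, 0.599, 0.401),
         HPF = row(0, 0, 1),
         PCPC = row(0, 0, 1),
         PCPF = row(0, 0, 1),
         PFPF = row(0, 0, 1))
  } else {
    list(HH = row(0.948, 0.031, 0.021),
         HPC = row(0.135, 0.157, 0.708),
         HPF = row(0.025, 0.058, 0.917),
         PCPC = row(0.0075, 0.0025, 0.99),
         PCPF = row(0.0037, 0.0037, 0.9926),
         PFPF = row(0, 0, 1))
  }
}

#' Build a simulation configuration
#'
#' Full generative specification for the synthetic multi-breed population:
#' per-breed POLLED haplotype frequencies and per-marker call rates,
#' background genotyping error, the probe-interference artifact at
#' rs800947704, the P_C--P_F cis-recombination probability, and phenotype
#' penetrance.
#'
#' Defaults emulate the study conditions: a composite beef population with
#' haplotype frequencies H = 0.6, P_C = 0.3, P_F = 0.1; per-marker call
#' rates equal to the published mean call rates; background per-genotype
#' error 1e-4 (the expected < 0.01\% assay failure range); artifact off
#' (enable it for Brahman-like breeds; carrier frequency 0.0743 of the
#' interfering G allele with certain dropout reproduces the ~14\% marker
#' loss seen there); recombination 0.002 (~0.2\%, the approximate genetic
#' distance between the two mutations).
#'
#' @param n_samples Number of animals.
#' @param breed_profiles Named list, one per breed:
#'   \code{list(hap_freqs = c(H=, P_C=, P_F=), call_rates = <named vector
#'   rs_id -> rate in [0,1], or a single rate>, weight = sampling weight)}.
#' @param error_rate Per-genotype miscall probability in [0,1].
#' @param artifact List with \code{interfering_allele_freq} (frequency of
#'   the latent G allele 3 bp upstream of rs800947704),
#'   \code{dropout_prob_given_G}, \code{miscall_prob_given_G}.
#' @param recomb_prob Probability a transmitted P_C or P_F gamete is
#'   replaced by a cis P_C+P_F recombinant.
#' @param penetrance Penetrance map (see \code{\link{penetrance_preset}}).
#' @param seed Integer RNG seed.
#' @param registry Marker registry.
#' @return Validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 1000L,
                       breed_profiles = NULL,
                       error_rate = 1e-4,
                       artifact = list(interfering_allele_freq = 0,
                                       dropout_prob_given_G = 1,
                                       miscall_prob_given_G = 0),
                       recomb_prob = 0.002,
                       penetrance = penetrance_preset("validation"),
                       seed = 1L,
                       registry = poll_registry()) {
  if (is.null(breed_profiles)) {
    breed_profiles <- list(
      Composite = list(
        hap_freqs = c(H = 0.6, P_C = 0.3, P_F = 0.1),
        call_rates = stats::setNames(registry$mean_call_rate / 100,
                                     registry$rs_id),
        weight = 1
      )
    )
  }
  for (b in names(breed_profiles)) {
    prof <- breed_profiles[[b]]
    f <- prof$hap_freqs
    if (is.null(names(f)) || !setequal(names(f), c("H", "P_C", "P_F"))) {
      stop("breed '", b, "': hap_freqs must be named H, P_C, P_F",
           call. = FALSE)
    }
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      stop("breed '", b, "': haplotype frequencies must be non-negative ",
           "and sum to 1", call. = FALSE)
    }
    cr <- prof$call_rates %||% 1
    if (length(cr) == 1L && is.null(names(cr))) {
      cr <- stats::setNames(rep(cr, nrow(registry)), registry$rs_id)
    }
    if (any(cr < 0 | cr > 1)) {
      stop("breed '", b, "': call rates must lie in [0,1]", call. = FALSE)
    }
    breed_profiles[[b]]$call_rates <- cr
    breed_profiles[[b]]$weight <- prof$weight %||% 1
  }
  probs <- c(error_rate, recomb_prob, artifact$interfering_allele_freq,
             artifact$dropout_prob_given_G, artifact$miscall_prob_given_G)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0,1]", call. = FALSE)
  }
  for (cl in names(penetrance)) {
    p <- penetrance[[cl]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("penetrance row '", cl, "' must be a distribution", call. = FALSE)
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 breed_profiles = breed_profiles,
                 error_rate = error_rate, artifact = artifact,
                 recomb_prob = recomb_prob, penetrance = penetrance,
                 seed = as.integer(seed), registry = registry),
            class = "sim_config")
}

#' Draw true POLLED haplotype pairs
#'
#' Each animal receives a breed (by profile weight) and two gametes drawn
#' i.i.d. from the breed's haplotype frequencies (Hardy--Weinberg
#' proportions). Each P_C or P_F gamete is independently replaced by a cis
#' P_C+P_F recombinant with probability \code{recomb_prob}; the reciprocal
#' null recombinant is indistinguishable from H at the panel markers and is
#' not modeled.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional seed; \code{NULL} uses the current RNG state (so
#'   \code{\link{simulate_dataset}} controls the stream).
#' @return data.frame truth table: \code{sample_id}, \code{breed},
#'   \code{hap1}, \code{hap2} (in {H, P_C, P_F, P_C+P_F}),
#'   \code{true_diplotype}.
#' @export
simulate_haplotypes <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_samples
  breeds <- names(config$breed_profiles)
  w <- vapply(config$breed_profiles, `[[`, numeric(1), "weight")
  breed <- if (length(breeds) == 1L) {
    rep(breeds, n)
  } else {
    sample(breeds, n, replace = TRUE, prob = w)
  }
  hap1 <- character(n); hap2 <- character(n)
  for (b in breeds) {
    idx <- which(breed == b)
    if (!length(idx)) next
    f <- config$breed_profiles[[b]]$hap_freqs
    hap1[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
    hap2[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
  }
  if (config$recomb_prob > 0) {
    for (h in c("hap1", "hap2")) {
      v <- get(h)
      carrier <- v %in% c("P_C", "P_F")
      flip <- carrier & stats::runif(n) < config$recomb_prob
      v[flip] <- "P_C+P_F"
      assign(h, v)
    }
  }
  truth <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n)),
    breed = breed, hap1 = hap1, hap2 = hap2,
    stringsAsFactors = FALSE
  )
  truth$true_diplotype <- haplotype_pair_class(hap1, hap2)
  truth
}

#' Diplotype class implied by a haplotype pair
#'
#' Classifies by mutation content: the count of haplotypes carrying P_C and
#' of those carrying P_F (a cis recombinant carries both). Pairs whose
#' content exceeds two poll mutations (a cis haplotype alongside another P
#' haplotype) are classed PCPF -- carriers of both mutations, fully polled
#' under every preset.
#'
#' @param hap1,hap2 Character vectors over {H, P_C, P_F, P_C+P_F}.
#' @return Character vector of diplotype classes.
#' @export
haplotype_pair_class <- function(hap1, hap2) {
  npc <- (hap1 %in% c("P_C", "P_C+P_F")) + (hap2 %in% c("P_C", "P_C+P_F"))
  npf <- (hap1 %in% c("P_F", "P_C+P_F")) + (hap2 %in% c("P_F", "P_C+P_F"))
  cls <- character(length(npc))
  key <- paste0(npc, npf)
  map <- c("00" = "HH", "10" = "HPC", "01" = "HPF",
           "20" = "PCPC", "11" = "PCPF", "02" = "PFPF")
  cls <- unname(map[key])
  cls[is.na(cls)] <- "PCPF"  # >2 mutations: double carrier
  cls
}

# alleles carried by one haplotype at every registry marker, under
# complete LD: H = no poll allele anywhere; P_C = poll allele at the P_C
# marker only; P_F = poll alleles at every P_F-linked marker; the cis
# recombinant = poll alleles everywhere
haplotype_alleles <- function(hap, registry) {
  other <- ifelse(registry$allele1 == registry$poll_allele,
                  registry$allele2, registry$allele1)
  carries_pc <- hap %in% c("P_C", "P_C+P_F")
  carries_pf <- hap %in% c("P_F", "P_C+P_F")
  is_poll <- (registry$linked_mutation == "P_C" & carries_pc) |
    (registry$linked_mutation == "P_F" & carries_pf)
  ifelse(is_poll, registry$poll_allele, other)
}

#' Translate true haplotypes into error-free genotypes
#'
#' Complete-LD genotype emission: every marker call follows deterministically
#' from the haplotype pair, fully called and error-free. Noise channels
#' (\code{\link{apply_genotyping_error}}, \code{\link{apply_probe_artifact}},
#' \code{\link{apply_missingness}}) are layered on afterwards.
#'
#' @param truth Truth table from \code{\link{simulate_haplotypes}}.
#' @param registry Marker registry.
#' @return A \code{\link{genotype_dataset}}.
#' @export
haplotypes_to_genotypes <- function(truth, registry = poll_registry()) {
  haps <- c("H", "P_C", "P_F", "P_C+P_F")
  allele_by_hap <- vapply(haps, haplotype_alleles, character(nrow(registry)),
                          registry = registry)
  # genotype string per (hap1, hap2) per marker, precomputed
  n <- nrow(truth)
  geno <- matrix(NA_character_, n, nrow(registry),
                 dimnames = list(truth$sample_id, registry$rs_id))
  for (j in seq_len(nrow(registry))) {
    a1 <- allele_by_hap[j, truth$hap1]
    a2 <- allele_by_hap[j, truth$hap2]
    geno[, j] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  }
  samples <- data.frame(sample_id = truth$sample_id, breed = truth$breed,
                        sex = rep("unknown", nrow(truth)),
                        stringsAsFactors = FALSE)
  genotype_dataset(samples, geno, provenance = "simulated",
                   registry = registry)
}

set_marker_dosage <- function(geno_col, dosage, marker_row) {
  poll <- marker_row$poll_allele
  other <- ifelse(marker_row$allele1 == poll, marker_row$allele2,
                  marker_row$allele1)
  gt <- c(paste(sort(c(other, other)), collapse = "/"),
          paste(sort(c(other, poll)), collapse = "/"),
          paste(sort(c(poll, poll)), collapse = "/"))
  gt[dosage + 1L]
}

#' Overlay background genotyping error
#'
#' Each called genotype is independently replaced, with probability
#' \code{error_rate}, by a uniformly chosen \emph{different} dosage at the
#' same marker.
#'
#' @param dataset A \code{\link{genotype_dataset}}.
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional seed (NULL = current RNG state).
#' @return The perturbed dataset.
#' @export
apply_genotyping_error <- function(dataset, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- config$error_rate
  if (e == 0) return(dataset)
  reg <- config$registry
  for (j in seq_len(ncol(dataset$geno))) {
    m <- colnames(dataset$geno)[j]
    row <- reg[reg$rs_id == m, ]
    calls <- dataset$geno[, j]
    idx <- which(!is.na(calls) & stats::runif(length(calls)) < e)
    if (!length(idx)) next
    cur <- allele_dosage(calls[idx], row, reg)
    new <- vapply(cur, function(d) sample(setdiff(0:2, d), 1L), integer(1))
    dataset$geno[idx, j] <- set_marker_dosage(NULL, new, row)
  }
  dataset
}

#' Overlay the probe-interference artifact at rs800947704
#'
#' Models the hybridization failure caused by a latent interfering SNP 3 bp
#' upstream of rs800947704 (g.2378742A>G): probes recognize the A allele
#' only, so samples carrying at least one G allele fail or miscall at the
#' target marker. Each sample draws a latent interfering genotype under
#' Hardy--Weinberg at \code{interfering_allele_freq}; G carriers lose their
#' rs800947704 call with \code{dropout_prob_given_G}, otherwise are
#' miscalled (dosage decremented toward 0, hiding a poll allele) with
#' \code{miscall_prob_given_G}. The interfering SNP is latent: it never
#' appears in the genotype output. Markers other than rs800947704 are
#' untouched, so an OPT panel is immune by construction.
#'
#' @inheritParams apply_genotyping_error
#' @return The perturbed dataset.
#' @export
apply_probe_artifact <- function(dataset, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  art <- config$artifact
  p <- art$interfering_allele_freq
  target <- "rs800947704"
  if (p == 0 || !target %in% colnames(dataset$geno)) return(dataset)
  n <- nrow(dataset$geno)
  carrier <- stats::runif(n) < 1 - (1 - p)^2
  u <- stats::runif(n)
  drop <- carrier & u < art$dropout_prob_given_G
  miscall <- carrier & !drop &
    stats::runif(n) < art$miscall_prob_given_G
  dataset$geno[drop, target] <- NA_character_
  idx <- which(miscall & !is.na(dataset$geno[, target]))
  if (length(idx)) {
    reg <- config$registry
    row <- reg[reg$rs_id == target, ]
    cur <- allele_dosage(dataset$geno[idx, target], row, reg)
    dataset$geno[idx, target] <- set_marker_dosage(NULL, pmax(cur - 1L, 0L),
                                                   row)
  }
  dataset
}

#' Overlay per-marker missingness
#'
#' Each genotype is independently set missing with probability
#' 1 - call_rate for its marker and the sample's breed profile.
#'
#' @inheritParams apply_genotyping_error
#' @return The thinned dataset.
#' @export
apply_missingness <- function(dataset, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (b in names(config$breed_profiles)) {
    idx <- which(dataset$samples$breed == b)
    if (!length(idx)) next
    cr <- config$breed_profiles[[b]]$call_rates
    for (m in colnames(dataset$geno)) {
      rate <- if (m %in% names(cr)) cr[[m]] else 1
      if (rate >= 1) next
      gone <- idx[stats::runif(length(idx)) >= rate]
      dataset$geno[gone, m] <- NA_character_
    }
  }
  dataset
}

#' Draw head phenotypes from penetrance
#'
#' One head status per animal, sampled from the penetrance row of its true
#' diplotype class.
#'
#' @param truth Truth table from \code{\link{simulate_haplotypes}}.
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional seed (NULL = current RNG state).
#' @return data.frame with \code{sample_id}, \code{head_status}.
#' @export
simulate_phenotypes <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing_cls <- setdiff(unique(truth$true_diplotype),
                         names(config$penetrance))
  if (length(missing_cls)) {
    stop("penetrance map lacks diplotype class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  status <- character(nrow(truth))
  for (cl in unique(truth$true_diplotype)) {
    idx <- which(truth$true_diplotype == cl)
    p <- config$penetrance[[cl]]
    status[idx] <- sample(c("Horn", "Scur", "Poll"), length(idx),
                          replace = TRUE, prob = p)
  }
  data.frame(sample_id = truth$sample_id, head_status = status,
             stringsAsFactors = FALSE)
}

#' Simulate a full genotype + phenotype dataset
#'
#' Composes the generative stages in fixed order -- haplotypes, complete-LD
#' genotypes, background error, probe artifact, missingness, phenotypes --
#' under a single seed, so runs are byte-reproducible.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{dataset} (a \code{\link{genotype_dataset}}),
#'   \code{truth}, \code{phenotypes}.
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 50, seed = 7))
#' table(sim$truth$true_diplotype)
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  truth <- simulate_haplotypes(config, seed = NULL)
  dataset <- haplotypes_to_genotypes(truth, config$registry)
  dataset <- apply_genotyping_error(dataset, config)
  dataset <- apply_probe_artifact(dataset, config)
  dataset <- apply_missingness(dataset, config)
  phenotypes <- simulate_phenotypes(truth, config)
  list(dataset = dataset, truth = truth, phenotypes = phenotypes)
}

#' A noise-free simulation configuration
#'
#' Convenience preset: complete LD, every marker fully called, no
#' genotyping error, artifact off, no recombination. On such data both
#' panels recover the simulated truth for every sample.
#'
#' @param n_samples Number of animals.
#' @param hap_freqs Haplotype frequencies, default c(H=0.6, P_C=0.3,
#'   P_F=0.1).
#' @param seed RNG seed.
#' @param error_rate,recomb_prob Noise overrides (default off).
#' @param ... Further arguments to \code{\link{sim_config}}.
#' @return A \code{\link{sim_config}}.
#' @export
clean_sim_config <- function(n_samples = 1000L,
                             hap_freqs = c(H = 0.6, P_C = 0.3, P_F = 0.1),
                             seed = 1L, error_rate = 0, recomb_prob = 0,
                             ...) {
  sim_config(
    n_samples = n_samples,
    breed_profiles = list(Composite = list(hap_freqs = hap_freqs,
                                           call_rates = 1)),
    error_rate = error_rate,
    artifact = list(interfering_allele_freq = 0,
                    dropout_prob_given_G = 1, miscall_prob_given_G = 0),
    recomb_prob = recomb_prob,
    seed = seed,
    ...
  )
}

#' Serialize a simulation config to/from JSON
#'
#' The JSON schema mirrors the \code{\link{sim_config}} arguments
#' (\code{n_samples}, \code{breed_profiles}, \code{error_rate},
#' \code{artifact}, \code{recomb_prob}, \code{penetrance} as a map of
#' class -> {Horn, Scur, Poll}, \code{seed}); the marker registry is not
#' serialized (the built-in is used on load).
#'
#' @param config A \code{\link{sim_config}}.
#' @param path JSON file path.
#' @return \code{path} / a \code{sim_config}.
#' @export
sim_config_to_json <- function(config, path) {
  x <- unclass(config)
  x$registry <- NULL
  x$penetrance <- lapply(x$penetrance, as.list)
  x$breed_profiles <- lapply(x$breed_profiles, function(p) {
    p$call_rates <- as.list(p$call_rates)
    p$hap_freqs <- as.list(p$hap_freqs)
    p
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname sim_config_to_json
#' @export
sim_config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  profiles <- lapply(x$breed_profiles, function(p) {
    list(hap_freqs = unlist(p$hap_freqs),
         call_rates = unlist(p$call_rates),
         weight = p$weight %||% 1)
  })
  sim_config(
    n_samples = x$n_samples,
    breed_profiles = profiles,
    error_rate = x$error_rate %||% 0,
    artifact = as.list(unlist(x$artifact) %||%
                         c(interfering_allele_freq = 0,
                           dropout_prob_given_G = 1,
                           miscall_prob_given_G = 0)),
    recomb_prob = x$recomb_prob %||% 0.002,
    penetrance = lapply(x$penetrance, unlist),
    seed = x$seed %||% 1L
  )
}
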