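#' Poll-allele dosage at one marker
#'
#' Counts the marker's poll-associated allele in an unphased diploid call.
#' A missing call propagates as \code{NA}.
#'
#' @param gt Genotype string "X/Y" or \code{NA}.
#' @param marker One registry row (data.frame) or a marker rs-ID resolved
#'   against \code{registry}.
#' @param registry Marker registry.
#' @return Integer dosage 0, 1, 2 or \code{NA}.
#' @export
allele_dosage <- function(gt, marker, registry = poll_registry()) {
  if (is.character(marker)) {
    marker <- registry[registry$rs_id == marker, , drop = FALSE]
    if (nrow(marker) != 1L) stop("unknown marker", call. = FALSE)
  }
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "/", fixed = TRUE)[[1]]
    bad <- setdiff(a, c(marker$allele1, marker$allele2))
    if (length(bad)) {
      stop("allele symbol(s) ", paste(bad, collapse = ","),
           " not valid for marker ", marker$rs_id,
           " (alias mapping failed upstream?)", call. = FALSE)
    }
    sum(a == marker$poll_allele)
  }, integer(1), USE.NAMES = FALSE)
}

#' Celtic-allele dosage for a sample
#'
#' The Celtic (P_C) mutation is predicted from the single marker
#' rs383143898: the dosage of its poll allele T is the predicted count of
#' P_C haplotypes.
#'
#' @param gt Genotype string at the panel's P_C marker, or \code{NA}.
#' @param panel A \code{poll_panel}.
#' @param registry Marker registry.
#' @return 0, 1, 2 or \code{NA}.
#' @export
pc_dosage <- function(gt, panel = poll_panel("OPT"),
                      registry = poll_registry()) {
  allele_dosage(gt, panel$pc_marker, registry)
}

#' Friesian-marker dosage
#'
#' Dosage of the poll allele at one Friesian-linked (P_F) marker.
#'
#' @param gt Genotype string or \code{NA}.
#' @param marker Marker rs-ID or registry row; must be P_F-linked.
#' @param registry Marker registry.
#' @return 0, 1, 2 or \code{NA}.
#' @export
pf_marker_dosage <- function(gt, marker, registry = poll_registry()) {
  if (is.character(marker)) {
    marker <- registry[registry$rs_id == marker, , drop = FALSE]
  }
  stopifnot(nrow(marker) == 1L)
  if (marker$linked_mutation != "P_F") {
    stop(marker$rs_id, " is not a Friesian-linked marker", call. = FALSE)
  }
  allele_dosage(gt, marker, registry)
}

#' Consensus Friesian dosage across the panel's P_F markers
#'
#' Under complete linkage disequilibrium every P_F marker of a sample
#' reports the same dosage; the consensus is the modal dosage among called
#' markers and any called marker off the mode is discordant. A tie for the
#' mode is refused (consensus \code{NA}, \code{ambiguous = TRUE}) and the
#' markers outside one modal class all count as discordant, which always
#' exceeds both panels' budgets -- a tied sample is never called.
#'
#' @param dosages Integer vector of per-marker dosages (0/1/2/\code{NA}),
#'   one per panel P_F marker, in panel order.
#' @param panel A \code{poll_panel} (used for its marker count).
#' @return List with \code{consensus} (0/1/2 or \code{NA}),
#'   \code{ambiguous}, \code{n_called}, \code{n_missing},
#'   \code{n_discordant}, \code{per_marker}.
#' @export
pf_consensus <- function(dosages, panel) {
  if (length(dosages) != length(panel$pf_markers)) {
    stop("expected ", length(panel$pf_markers), " P_F dosages, got ",
         length(dosages), call. = FALSE)
  }
  called <- dosages[!is.na(dosages)]
  n_called <- length(called)
  n_missing <- length(dosages) - n_called
  if (n_called == 0L) {
    return(list(consensus = NA_integer_, ambiguous = FALSE,
                n_called = 0L, n_missing = n_missing, n_discordant = 0L,
                per_marker = dosages))
  }
  tab <- tabulate(called + 1L, nbins = 3L)
  modal_count <- max(tab)
  modal <- which(tab == modal_count) - 1L
  ambiguous <- length(modal) > 1L
  list(
    consensus = if (ambiguous) NA_integer_ else as.integer(modal),
    ambiguous = ambiguous,
    n_called = n_called,
    n_missing = as.integer(n_missing),
    n_discordant = as.integer(n_called - modal_count),
    per_marker = dosages
  )
}

#' Call the poll diplotype of one sample
#'
#' The translation test proper. The Celtic dosage comes from the single P_C
#' marker; the Friesian dosage from the consensus over the panel's P_F
#' markers. A sample is a \code{NO_RESULT} when
#' \itemize{
#'   \item the P_C marker failed (\code{PC_MISSING});
#'   \item CPT-style budgets: more P_F markers are missing than
#'     \code{max_pf_missing} (\code{PF_TOO_MANY_MISSING}) or more disagree
#'     with the consensus than \code{max_pf_discordant}
#'     (\code{PF_DISCORDANT});
#'   \item OPT-style budget: missing + discordant exceed
#'     \code{combined_budget} (\code{PF_BUDGET_EXCEEDED});
#'   \item the two predictions claim more than two poll alleles in total
#'     (\code{DOSAGE_INCONSISTENT}) -- possible only through genotyping
#'     error or a cis P_C+P_F recombinant haplotype, neither of which the
#'     trans-assuming test can resolve.
#' }
#' Otherwise the (P_C, P_F) dosage pair maps onto the six diplotypes:
#' (0,0) HH, (1,0) HPC, (0,1) HPF, (2,0) PCPC, (1,1) PCPF, (0,2) PFPF.
#'
#' @param pc Celtic dosage (0/1/2 or \code{NA}).
#' @param pf_dosages Integer vector of P_F marker dosages in panel order.
#' @param panel A \code{poll_panel}.
#' @return List: \code{diplotype}, \code{reasons} (character, empty when
#'   definitive), \code{pc_dosage}, \code{pf} (the consensus evidence list).
#' @examples
#' call_sample(1, c(1, 1, 1, 1), poll_panel("OPT"))$diplotype  # "PCPF"
#' @export
call_sample <- function(pc, pf_dosages, panel) {
  ev <- pf_consensus(pf_dosages, panel)
  reasons <- character(0)
  if (is.na(pc)) reasons <- c(reasons, "PC_MISSING")
  if (!is.null(panel$combined_budget)) {
    if (ev$n_missing + ev$n_discordant > panel$combined_budget) {
      reasons <- c(reasons, "PF_BUDGET_EXCEEDED")
    }
  } else {
    if (ev$n_missing > panel$max_pf_missing) {
      reasons <- c(reasons, "PF_TOO_MANY_MISSING")
    }
    if (ev$n_discordant > panel$max_pf_discordant) {
      reasons <- c(reasons, "PF_DISCORDANT")
    }
  }
  if (!length(reasons) && (ev$ambiguous || is.na(ev$consensus))) {
    # unreachable for the built-in panels (a tie always breaches the
    # discordance budget) but guards custom panels with loose budgets
    reasons <- "PF_DISCORDANT"
  }
  if (!length(reasons) && pc + ev$consensus > 2L) {
    reasons <- "DOSAGE_INCONSISTENT"
  }
  diplotype <- if (length(reasons)) {
    "NO_RESULT"
  } else {
    dosage_pair_class(pc, ev$consensus)
  }
  list(diplotype = diplotype, reasons = reasons,
       pc_dosage = pc, pf = ev)
}

dosage_pair_class <- function(pc, pf) {
  key <- paste0(pc, pf)
  switch(key,
         "00" = "HH", "10" = "HPC", "01" = "HPF",
         "20" = "PCPC", "11" = "PCPF", "02" = "PFPF",
         stop("inconsistent dosage pair (", pc, ",", pf, ")", call. = FALSE))
}

#' Call every sample in a dataset
#'
#' @param dataset A \code{\link{genotype_dataset}}.
#' @param panel A \code{poll_panel} (or panel name).
#' @param registry Marker registry.
#' @return data.frame, one row per sample in input order: \code{sample_id},
#'   \code{breed}, \code{panel}, \code{diplotype}, \code{reasons}
#'   (semicolon-joined), \code{pc_dosage}, \code{pf_consensus},
#'   \code{pf_n_called}, \code{pf_n_missing}, \code{pf_n_discordant},
#'   \code{pf_dosages} (comma-joined per-marker dosages, "." = missing).
#' @export
call_dataset <- function(dataset, panel, registry = poll_registry()) {
  if (is.character(panel)) panel <- poll_panel(panel, registry)
  n <- nrow(dataset$samples)
  pc_gt <- dataset$geno[, panel$pc_marker]
  pc <- pc_dosage(pc_gt, panel, registry)
  pf_mat <- matrix(NA_integer_, n, length(panel$pf_markers))
  for (j in seq_along(panel$pf_markers)) {
    pf_mat[, j] <- pf_marker_dosage(dataset$geno[, panel$pf_markers[j]],
                                    panel$pf_markers[j], registry)
  }
  diplotype <- character(n); reasons <- character(n)
  pf_cons <- integer(n); n_called <- integer(n)
  n_miss <- integer(n); n_disc <- integer(n); dos_str <- character(n)
  for (i in seq_len(n)) {
    res <- call_sample(pc[i], pf_mat[i, ], panel)
    diplotype[i] <- res$diplotype
    reasons[i] <- paste(res$reasons, collapse = ";")
    pf_cons[i] <- res$pf$consensus
    n_called[i] <- res$pf$n_called
    n_miss[i] <- res$pf$n_missing
    n_disc[i] <- res$pf$n_discordant
    dos <- res$pf$per_marker
    dos_str[i] <- paste(ifelse(is.na(dos), ".", dos), collapse = ",")
  }
  data.frame(
    sample_id = as.character(dataset$samples$sample_id),
    breed = as.character(dataset$samples$breed),
    panel = rep(panel$name, n),
    diplotype = diplotype,
    reasons = reasons,
    pc_dosage = pc,
    pf_consensus = pf_cons,
    pf_n_called = n_called,
    pf_n_missing = n_miss,
    pf_n_discordant = n_disc,
    pf_dosages = dos_str,
    stringsAsFactors = FALSE
  )
}

#' Is a call definitive?
#'
#' @param diplotype Character vector of diplotype labels.
#' @return Logical: TRUE for the six diplotypes, FALSE for NO_RESULT.
#' @export
is_definitive <- function(diplotype) {
  diplotype %in% setdiff(diplotype_classes(), "NO_RESULT")
}
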