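#' Built-in registry of POLLED-locus diagnostic markers
#'
#' Returns the ten SNP/indel markers on bovine autosome 1 (BTA1) that are in
#' strong linkage disequilibrium with the Celtic (P_C) and Friesian (P_F)
#' POLLED mutations, with their ARS-UCD1.2 coordinates, allele pairs, the
#' poll-associated allele, and the mutation each marker tags. The two indel
#' markers (P_5ID at rs801127025 and P_202ID at rs383143898) are represented
#' as biallelic pseudo-SNPs with alleles C/T; insertion/deletion allele
#' symbols in input files can be remapped with an alias map at read time
#' (see \code{\link{read_genotype_table}}).
#'
#' Two markers (rs798116945, rs800767839) are near-monomorphic across both
#' taurine and indicine breeds and are flagged \code{informative = FALSE};
#' they are excluded from every built-in panel. \code{mean_call_rate} is the
#' published mean genotyping call rate (percent) and is QC metadata only --
#' it plays no role in calling.
#'
#' @return A data.frame with one row per marker, in genomic order, and
#'   columns \code{rs_id}, \code{chrom}, \code{pos}, \code{allele1},
#'   \code{allele2}, \code{poll_allele}, \code{linked_mutation},
#'   \code{informative}, \code{mean_call_rate}.
#' @seealso \code{\link{poll_panel}}, \code{\link{poll_locus_info}}
#' @examples
#' reg <- poll_registry()
#' reg[reg$linked_mutation == "P_C", ]
#' @export
poll_registry <- function() {
  reg <- data.frame(
    rs_id = c("rs801127025", "rs799187101", "rs800947704", "rs798116945",
              "rs383143898", "rs799403053", "rs210350155", "rs797088784",
              "rs800767839", "rs799920960"),
    chrom = "1",
    pos = c(2372456L, 2377687L, 2378745L, 2407338L, 2429319L,
            2486811L, 2491161L, 2578598L, 2629115L, 2748715L),
    allele1 = c("C", "G", "C", "G", "C", "T", "C", "G", "T", "C"),
    allele2 = c("T", "A", "T", "C", "T", "C", "A", "A", "A", "G"),
    poll_allele = c("T", "A", "T", "C", "T", "C", "A", "A", "A", "G"),
    linked_mutation = c("P_F", "P_F", "P_F", "P_F", "P_C",
                        "P_F", "P_F", "P_F", "P_F", "P_F"),
    informative = c(TRUE, TRUE, TRUE, FALSE, TRUE,
                    TRUE, TRUE, TRUE, FALSE, TRUE),
    mean_call_rate = c(99.47, 99.98, 96.32, 99.99, 99.92,
                       99.80, 99.23, 99.44, 99.94, 100.00),
    stringsAsFactors = FALSE
  )
  class(reg) <- c("poll_registry", "data.frame")
  reg
}

#' POLLED locus reference constants
#'
#' Documentation constants for the POLLED locus on BTA1 (ARS-UCD1.2
#' coordinates, 1-based): the span covered by the diagnostic marker panel,
#' the Friesian duplication breakpoints (g.2629113_2709240, an 80,128 bp
#' tandem duplication), the Celtic complex indel breakpoints, and the
#' positions of the rarer Mongolian (P_M) and Guarani (P_G) variants. P_M
#' and P_G are metadata only; no built-in panel detects them.
#'
#' @return A named list of coordinate vectors.
#' @export
poll_locus_info <- function() {
  list(
    assembly = "ARS-UCD1.2",
    chrom = "1",
    marker_span = c(start = 2372456L, end = 2748715L),
    celtic_variant = c(start = 2429109L, end = 2429335L),
    friesian_duplication = c(start = 2629113L, end = 2709240L,
                             length = 2709240L - 2629113L + 1L),
    mongolian_variant = c(start = 2695261L, end = 2696047L),
    guarani_variant = c(start = 2614828L, end = 2724315L)
  )
}

#' Diplotype classes reported by the poll test
#'
#' The seven possible outcomes: the six POLLED-locus diplotypes plus
#' \code{NO_RESULT} for samples where marker failures or discordance exceed
#' the panel's rule budgets.
#'
#' @return Character vector of class labels in reporting order.
#' @export
diplotype_classes <- function() {
  c("HH", "HPC", "HPF", "PCPC", "PCPF", "PFPF", "NO_RESULT")
}

#' Construct a built-in poll-test panel
#'
#' Builds the rule set for one of the two supported translation tests:
#' \describe{
#'   \item{CPT}{the 8-SNP current poll test: the single Celtic predictor
#'     rs383143898 plus all seven informative Friesian-linked markers.
#'     Tolerates up to 2 missing P_F markers and at most 1 P_F marker whose
#'     dosage disagrees with the consensus; beyond either budget the sample
#'     is a No Result.}
#'   \item{OPT}{the optimized 5-SNP test: the same Celtic predictor plus the
#'     four reliable P_F markers (rs801127025, rs799403053, rs210350155,
#'     rs797088784). Requires at least 3 of the 4 P_F markers called and at
#'     most 1 marker missing or discordant combined.}
#' }
#'
#' @param name Panel name, \code{"CPT"} or \code{"OPT"}.
#' @param registry Marker registry, by default \code{\link{poll_registry}()}.
#' @return An object of class \code{poll_panel}: a list with elements
#'   \code{name}, \code{pc_marker}, \code{pf_markers}, \code{max_pf_missing},
#'   \code{max_pf_discordant}, \code{combined_budget}, \code{min_pf_called}.
#' @examples
#' poll_panel("OPT")$pf_markers
#' @export
poll_panel <- function(name, registry = poll_registry()) {
  if (length(name) != 1L || !name %in% c("CPT", "OPT")) {
    stop("unknown panel '", paste(name, collapse = ","),
         "'; valid panels are: CPT, OPT", call. = FALSE)
  }
  pc_marker <- registry$rs_id[registry$linked_mutation == "P_C"]
  if (name == "OPT") {
    panel <- panel_spec(
      name = "OPT",
      pc_marker = pc_marker,
      pf_markers = c("rs801127025", "rs799403053", "rs210350155",
                     "rs797088784"),
      combined_budget = 1L,
      min_pf_called = 3L
    )
  } else {
    pf <- registry$rs_id[registry$informative &
                           registry$linked_mutation == "P_F"]
    panel <- panel_spec(
      name = "CPT",
      pc_marker = pc_marker,
      pf_markers = pf,
      max_pf_missing = 2L,
      max_pf_discordant = 1L,
      min_pf_called = length(pf) - 2L
    )
  }
  panel
}

#' Construct a custom panel rule set
#'
#' Lower-level constructor behind \code{\link{poll_panel}}, exposed so users
#' can define custom panels (e.g., from a JSON config via
#' \code{\link{panel_from_json}}). A panel uses either the separate CPT-style
#' budgets (\code{max_pf_missing}, \code{max_pf_discordant}) or a single
#' OPT-style \code{combined_budget} on missing + discordant together; supply
#' one or the other.
#'
#' @param name Panel label.
#' @param pc_marker rs-ID of the single Celtic (P_C) predictor marker.
#' @param pf_markers Character vector of Friesian (P_F) marker rs-IDs.
#' @param max_pf_missing Maximum tolerated missing P_F markers (CPT style).
#' @param max_pf_discordant Maximum tolerated discordant P_F markers
#'   (CPT style).
#' @param combined_budget Maximum missing + discordant together (OPT style).
#' @param min_pf_called Minimum called P_F markers required.
#' @return A \code{poll_panel} object.
#' @export
panel_spec <- function(name, pc_marker, pf_markers,
                       max_pf_missing = NULL, max_pf_discordant = NULL,
                       combined_budget = NULL,
                       min_pf_called = length(pf_markers) -
                         (combined_budget %||% max_pf_missing %||% 0L)) {
  if (is.null(combined_budget) &&
      (is.null(max_pf_missing) || is.null(max_pf_discordant))) {
    stop("supply either combined_budget or both max_pf_missing and ",
         "max_pf_discordant", call. = FALSE)
  }
  panel <- list(
    name = as.character(name),
    pc_marker = as.character(pc_marker),
    pf_markers = as.character(pf_markers),
    max_pf_missing = if (!is.null(max_pf_missing)) as.integer(max_pf_missing),
    max_pf_discordant = if (!is.null(max_pf_discordant))
      as.integer(max_pf_discordant),
    combined_budget = if (!is.null(combined_budget))
      as.integer(combined_budget),
    min_pf_called = as.integer(min_pf_called)
  )
  class(panel) <- "poll_panel"
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.poll_panel <- function(x, ...) {
  cat("Poll-test panel:", x$name, "\n")
  cat("  P_C marker :", x$pc_marker, "\n")
  cat("  P_F markers:", paste(x$pf_markers, collapse = ", "), "\n")
  if (!is.null(x$combined_budget)) {
    cat("  budget     : missing + discordant <=", x$combined_budget, "\n")
  } else {
    cat("  budgets    : missing <=", x$max_pf_missing,
        "; discordant <=", x$max_pf_discordant, "\n")
  }
  invisible(x)
}

#' All markers used by a panel
#'
#' @param panel A \code{poll_panel}.
#' @return Character vector: the P_C marker followed by the P_F markers.
#' @export
panel_markers <- function(panel) {
  c(panel$pc_marker, panel$pf_markers)
}

#' Validate a panel against a marker registry
#'
#' Checks that every panel marker exists in the registry, that the P_C slot
#' holds the Celtic-linked marker, and that all P_F markers are
#' Friesian-linked and informative. Violations are returned, not raised, so
#' user-defined panels can be checked before use.
#'
#' @param panel A \code{poll_panel}.
#' @param registry Marker registry (default built-in).
#' @return Character vector of violation messages; empty if the panel is
#'   consistent.
#' @examples
#' validate_panel(poll_panel("OPT"))
#' @export
validate_panel <- function(panel, registry = poll_registry()) {
  violations <- character(0)
  all_markers <- panel_markers(panel)
  unknown <- setdiff(all_markers, registry$rs_id)
  for (m in unknown) {
    violations <- c(violations, paste0("unknown marker: ", m))
  }
  known <- registry[match(all_markers, registry$rs_id), , drop = FALSE]
  pc_row <- registry[registry$rs_id == panel$pc_marker, , drop = FALSE]
  if (nrow(pc_row) == 1L && pc_row$linked_mutation != "P_C") {
    violations <- c(violations,
                    paste0("pc_marker not Celtic-linked: ", panel$pc_marker))
  }
  for (m in intersect(panel$pf_markers, registry$rs_id)) {
    row <- registry[registry$rs_id == m, ]
    if (row$linked_mutation != "P_F") {
      violations <- c(violations,
                      paste0("P_F marker not Friesian-linked: ", m))
    }
    if (!row$informative) {
      violations <- c(violations, paste0("non-informative marker: ", m))
    }
  }
  violations
}

#' Serialize a panel or registry to JSON
#'
#' Panels and marker registries round-trip through a plain JSON schema so
#' custom panels can be kept under version control and passed to the
#' command-line interface. The panel schema has keys \code{name},
#' \code{pc_marker}, \code{pf_markers} and whichever budget fields the panel
#' uses; the registry schema is an array of marker objects mirroring the
#' columns of \code{\link{poll_registry}}.
#'
#' @param panel A \code{poll_panel}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
panel_to_json <- function(panel, path) {
  jsonlite::write_json(unclass(panel), path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname panel_to_json
#' @export
panel_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel_spec(
    name = x$name, pc_marker = x$pc_marker, pf_markers = x$pf_markers,
    max_pf_missing = x$max_pf_missing,
    max_pf_discordant = x$max_pf_discordant,
    combined_budget = x$combined_budget,
    min_pf_called = x$min_pf_called %||%
      (length(x$pf_markers) -
         (x$combined_budget %||% x$max_pf_missing %||% 0L))
  )
}

#' @rdname panel_to_json
#' @param registry A marker registry data.frame.
#' @export
registry_to_json <- function(registry, path) {
  jsonlite::write_json(as.data.frame(registry), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname panel_to_json
#' @export
registry_from_json <- function(path) {
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- as.data.frame(reg, stringsAsFactors = FALSE)
  reg$pos <- as.integer(reg$pos)
  class(reg) <- c("poll_registry", "data.frame")
  reg
}

#' Reference diplotype counts from the development cohort
#'
#' Diplotype class counts from the 20,636-animal multi-breed Australian
#' commercial testing cohort on which the optimized panel was developed,
#' under both the current (CPT) and optimized (OPT) translations. Shipped as
#' benchmark data for the panel-comparison report structure and its
#' arithmetic identities (class gains sum to zero, panel totals agree, the
#' OPT success rate is 99.96%); the underlying per-sample genotypes are
#' proprietary and not included.
#'
#' @return A data.frame with columns \code{class}, \code{cpt}, \code{opt},
#'   \code{gain}, one row per diplotype class.
#' @export
published_cohort_counts <- function() {
  data.frame(
    class = diplotype_classes(),
    cpt = c(11113L, 3420L, 135L, 3641L, 300L, 28L, 1999L),
    opt = c(12785L, 3696L, 147L, 3651L, 311L, 37L, 9L),
    gain = c(1672L, 276L, 12L, 10L, 11L, 9L, -1990L),
    stringsAsFactors = FALSE
  )
}
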