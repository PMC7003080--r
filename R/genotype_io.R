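#' Construct a genotype dataset
#'
#' The container passed to the calling engine: per-sample metadata plus an
#' unphased genotype matrix over the registry markers. Genotype cells are
#' strings of the two called alleles joined by "/" with alleles sorted
#' (genotypes are order-insensitive: the test consumes poll-allele dosages
#' only), or \code{NA} for a missing call.
#'
#' @param samples data.frame with columns \code{sample_id}, \code{breed},
#'   \code{sex}. Breed/sex default to "unknown".
#' @param geno Character matrix, rows = samples (rownames = sample_id),
#'   columns = marker rs-IDs.
#' @param provenance Free-text source tag.
#' @param registry Marker registry the columns are validated against.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(samples, geno, provenance = "unspecified",
                             registry = poll_registry()) {
  stopifnot(is.data.frame(samples), is.matrix(geno))
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(samples$breed)) samples$breed <- rep("unknown", nrow(samples))
  if (is.null(samples$sex)) samples$sex <- rep("unknown", nrow(samples))
  samples <- samples[, c("sample_id", "breed", "sex")]
  # every registry marker gets a column (MISSING where the source had none)
  full <- matrix(NA_character_, nrow(samples), nrow(registry),
                 dimnames = list(samples$sample_id, registry$rs_id))
  keep <- intersect(colnames(geno), registry$rs_id)
  full[, keep] <- geno[, keep, drop = FALSE]
  full[] <- normalize_gt(full)
  validate_geno_alleles(full, registry)
  structure(list(samples = samples, geno = full, provenance = provenance),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x",
      ncol(x$geno), "markers (", x$provenance, ")\n")
  cat("  breeds:", paste(unique(x$samples$breed), collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(x$geno)), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)

# sort the two alleles within each genotype string; NA passes through
normalize_gt <- function(g) {
  out <- g
  idx <- which(!is.na(g))
  if (length(idx)) {
    parts <- strsplit(g[idx], "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      stop("malformed genotype string(s): ",
           paste(unique(g[idx][bad]), collapse = ", "), call. = FALSE)
    }
    out[idx] <- vapply(parts, function(p) paste(sort(p), collapse = "/"),
                       character(1))
  }
  out
}

validate_geno_alleles <- function(geno, registry) {
  for (m in colnames(geno)) {
    row <- registry[registry$rs_id == m, ]
    if (nrow(row) != 1L) next
    ok <- c(row$allele1, row$allele2)
    calls <- geno[, m]
    alleles <- unlist(strsplit(calls[!is.na(calls)], "/", fixed = TRUE))
    bad <- setdiff(unique(alleles), ok)
    if (length(bad)) {
      stop("allele symbol(s) ", paste(bad, collapse = ","), " at marker ", m,
           " not in registry alleles {", paste(ok, collapse = ","),
           "}; supply an alias_map if the source uses another encoding",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

apply_alias_map <- function(geno, alias_map) {
  if (is.null(alias_map)) return(geno)
  for (m in intersect(names(alias_map), colnames(geno))) {
    map <- alias_map[[m]]
    calls <- geno[, m]
    idx <- which(!is.na(calls))
    if (!length(idx)) next
    parts <- strsplit(calls[idx], "/", fixed = TRUE)
    geno[idx, m] <- vapply(parts, function(p) {
      hit <- p %in% names(map)
      p[hit] <- map[p[hit]]
      paste(sort(p), collapse = "/")
    }, character(1))
  }
  geno
}

#' Read panel genotypes from a VCF file
#'
#' Matches VCF records to registry markers by ID first, then by
#' (chrom, pos) with 1-based coordinates. Biallelic records only at panel
#' positions; REF/ALT must match the registry alleles (after alias mapping).
#' "./." and "." genotypes become missing calls; markers with no VCF record
#' are missing for every sample. VCF carries no breed/sex, so both are set
#' "unknown".
#'
#' @param path Path to a VCF (v4.x) file, plain or bgzipped.
#' @param registry Marker registry.
#' @param alias_map Optional named list: rs_id -> named character vector
#'   mapping source allele symbols to registry symbols (e.g., indel symbols
#'   I/D to T/C at the two indel markers, or strand complements).
#' @return A \code{\link{genotype_dataset}}.
#' @export
read_vcf <- function(path, registry = poll_registry(), alias_map = NULL) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  hit <- match(registry$rs_id, ids)
  # positional fallback for records without matching IDs
  pos_key <- paste(fix[, "CHROM"], fix[, "POS"])
  reg_key <- paste(registry$chrom, registry$pos)
  hit[is.na(hit)] <- match(reg_key[is.na(hit)], pos_key)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt)
  geno <- matrix(NA_character_, length(sample_ids), nrow(registry),
                 dimnames = list(sample_ids, registry$rs_id))
  for (i in seq_len(nrow(registry))) {
    row_idx <- hit[i]
    if (is.na(row_idx)) next
    m <- registry$rs_id[i]
    ref <- fix[row_idx, "REF"]
    alt <- fix[row_idx, "ALT"]
    if (grepl(",", alt, fixed = TRUE)) {
      stop("multi-allelic VCF record at panel marker ", m, call. = FALSE)
    }
    alleles <- c(ref, alt)
    if (!is.null(alias_map[[m]])) {
      map <- alias_map[[m]]
      alleles <- ifelse(alleles %in% names(map), map[alleles], alleles)
    }
    if (!setequal(alleles, c(registry$allele1[i], registry$allele2[i]))) {
      stop("REF/ALT (", ref, "/", alt, ") at marker ", m,
           " do not match registry alleles {", registry$allele1[i], ",",
           registry$allele2[i], "}", call. = FALSE)
    }
    calls <- gt[row_idx, ]
    geno[, m] <- decode_gt(calls, alleles)
  }
  samples <- data.frame(sample_id = sample_ids, breed = "unknown",
                        sex = "unknown", stringsAsFactors = FALSE)
  genotype_dataset(samples, geno, provenance = paste0("vcf:", path),
                   registry = registry)
}

# "0/1", "1|1", "./.", "." -> "A/B" strings or NA
decode_gt <- function(calls, alleles) {
  out <- rep(NA_character_, length(calls))
  idx <- which(!is.na(calls) & calls != "." & calls != "./." &
                 calls != ".|.")
  if (!length(idx)) return(out)
  parts <- strsplit(calls[idx], "[/|]")
  out[idx] <- vapply(parts, function(p) {
    if (length(p) != 2L || any(p == ".")) return(NA_character_)
    i <- suppressWarnings(as.integer(p)) + 1L
    if (anyNA(i) || any(i < 1L) || any(i > length(alleles))) {
      stop("unparseable GT field: ", paste(p, collapse = "/"),
           call. = FALSE)
    }
    paste(sort(alleles[i]), collapse = "/")
  }, character(1))
  out
}

#' Read panel genotypes from a wide table
#'
#' Reads a vendor-report-style wide table: one row per sample, a sample-ID
#' column, optional breed and sex columns, and one column per marker named
#' by rs-ID holding two-letter genotypes ("CT", "C/T" and "C T" all accepted).
#' Marker columns not in the registry are ignored with a warning.
#'
#' @param path Delimited text file.
#' @param registry Marker registry.
#' @param sep Field separator; default tab, use "," for CSV.
#' @param missing_tokens Cell values mapped to a missing call.
#' @param alias_map As in \code{\link{read_vcf}}.
#' @param id_col,breed_col,sex_col Column names for sample metadata.
#' @return A \code{\link{genotype_dataset}}.
#' @export
read_genotype_table <- function(path, registry = poll_registry(),
                                sep = "\t",
                                missing_tokens = c("--", "NN", "", "NA",
                                                   "./.", "." ),
                                alias_map = NULL,
                                id_col = "sample_id", breed_col = "breed",
                                sex_col = "sex") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% names(tab)) {
    stop("missing sample-ID column '", id_col, "' in ", path, call. = FALSE)
  }
  if (anyDuplicated(tab[[id_col]])) {
    dup <- unique(tab[[id_col]][duplicated(tab[[id_col]])])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  meta_cols <- c(id_col, breed_col, sex_col)
  marker_cols <- setdiff(names(tab), meta_cols)
  unknown <- setdiff(marker_cols, registry$rs_id)
  if (length(unknown)) {
    warning("ignoring non-registry column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    marker_cols <- setdiff(marker_cols, unknown)
  }
  geno <- matrix(NA_character_, nrow(tab), length(marker_cols),
                 dimnames = list(tab[[id_col]], marker_cols))
  for (m in marker_cols) {
    cells <- trimws(tab[[m]])
    cells[cells %in% missing_tokens] <- NA_character_
    geno[, m] <- parse_gt_cell(cells, m)
  }
  geno <- apply_alias_map(geno, alias_map)
  samples <- data.frame(
    sample_id = tab[[id_col]],
    breed = if (breed_col %in% names(tab)) tab[[breed_col]] else "unknown",
    sex = if (sex_col %in% names(tab)) tab[[sex_col]] else "unknown",
    stringsAsFactors = FALSE
  )
  genotype_dataset(samples, geno, provenance = paste0("table:", path),
                   registry = registry)
}

# "CT", "C/T", "C T" -> "C/T"; single letters rejected
parse_gt_cell <- function(cells, marker) {
  out <- rep(NA_character_, length(cells))
  idx <- which(!is.na(cells))
  if (!length(idx)) return(out)
  raw <- gsub("[ /|]", "", cells[idx])
  bad <- nchar(raw) != 2L
  if (any(bad)) {
    stop("unparseable genotype cell(s) at ", marker, ": ",
         paste(unique(cells[idx][bad]), collapse = ", "), call. = FALSE)
  }
  out[idx] <- paste(substr(raw, 1, 1), substr(raw, 2, 2), sep = "/")
  out
}

#' Write a genotype dataset as a wide table
#'
#' Inverse of \code{\link{read_genotype_table}}; genotypes written as
#' two-letter strings, missing calls as "--".
#'
#' @param dataset A \code{\link{genotype_dataset}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_genotype_table <- function(dataset, path) {
  geno <- gsub("/", "", dataset$geno, fixed = TRUE)
  geno[is.na(geno)] <- "--"
  out <- cbind(dataset$samples, as.data.frame(geno,
                                              stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genotype dataset as a minimal VCF
#'
#' Emits a VCF v4.2 file with one record per registry marker (REF/ALT from
#' the registry, poll allele as ALT or REF as stored) and unphased GT
#' fields. Breed/sex metadata are not representable in VCF and are dropped.
#'
#' @param dataset A \code{\link{genotype_dataset}}.
#' @param path Output path.
#' @param registry Marker registry.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(dataset, path, registry = poll_registry()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pollcall",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       dataset$samples$sample_id), collapse = "\t")), con)
  for (i in seq_len(nrow(registry))) {
    m <- registry$rs_id[i]
    ref <- registry$allele1[i]
    alt <- registry$allele2[i]
    calls <- dataset$geno[, m]
    gt <- vapply(calls, function(g) {
      if (is.na(g)) return("./.")
      a <- strsplit(g, "/", fixed = TRUE)[[1]]
      paste(sort(match(a, c(ref, alt)) - 1L), collapse = "/")
    }, character(1), USE.NAMES = FALSE)
    writeLines(paste(c(registry$chrom[i], registry$pos[i], m, ref, alt,
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read head-phenotype records
#'
#' Two-column delimited file (sample_id, head_status); status tokens are
#' case-insensitive. Tokens outside {Horn, Scur, Poll} map to "unknown" with
#' a warning.
#'
#' @param path Delimited file with a header row.
#' @param sep Field separator (default auto: comma if the header contains
#'   one, else tab).
#' @return data.frame with columns \code{sample_id}, \code{head_status}.
#' @export
read_phenotypes <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("phenotype file needs sample_id and head_status columns",
         call. = FALSE)
  }
  names(tab)[1:2] <- c("sample_id", "head_status")
  status <- canonical_status(tab$head_status)
  bad <- tab$head_status[status == "unknown" &
                           tolower(tab$head_status) != "unknown"]
  if (length(bad)) {
    warning("unrecognized head_status token(s) mapped to unknown: ",
            paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = tab$sample_id, head_status = status,
             stringsAsFactors = FALSE)
}

canonical_status <- function(x) {
  lu <- c(horn = "Horn", horned = "Horn", scur = "Scur", scurred = "Scur",
          poll = "Poll", polled = "Poll", unknown = "unknown")
  out <- lu[tolower(trimws(x))]
  out[is.na(out)] <- "unknown"
  unname(out)
}

#' Write and re-read a call report
#'
#' \code{write_calls} writes one TSV row per sample: identifiers, panel,
#' diplotype, semicolon-joined reason codes and the per-marker dosage string
#' (panel order, "." for missing). \code{read_calls} restores the
#' machine-readable subset (sample, panel, diplotype, reasons, dosages)
#' exactly, so reports round-trip.
#'
#' @param calls A call table from \code{\link{call_dataset}}.
#' @param path Output TSV path.
#' @return \code{path} (write) or a call data.frame (read), invisibly for
#'   write.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, na.strings = ".")
  for (col in c("pc_dosage", "pf_consensus", "pf_n_called", "pf_n_missing",
                "pf_n_discordant")) {
    if (col %in% names(tab)) tab[[col]] <- as.integer(tab[[col]])
  }
  tab$reasons[is.na(tab$reasons)] <- ""
  tab
}
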