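#' Round a proportion to a half-up percentage
#'
#' Percentages throughout the reports use round-half-up (so 9.68695...
#' prints as 9.69), matching the convention of the published tables rather
#' than R's banker's rounding.
#'
#' @param numerator,denominator Non-negative counts; denominator > 0.
#' @param dp Decimal places (default 2).
#' @return 100 * numerator / denominator, rounded half-up to \code{dp}.
#' @examples
#' percent(20636 - 9, 20636)  # 99.96
#' @export
percent <- function(numerator, denominator, dp = 2) {
  if (any(denominator == 0)) stop("denominator is zero", call. = FALSE)
  round_half_up(100 * numerator / denominator, dp)
}

round_half_up <- function(x, dp = 2) {
  scale <- 10^dp
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Tally diplotype classes in a call set
#'
#' @param calls Call table from \code{\link{call_dataset}}; all rows must
#'   share one panel.
#' @return List of class \code{class_counts}: \code{panel}, \code{counts}
#'   (named integer over the 7 classes), \code{total}.
#' @export
genotype_class_counts <- function(calls) {
  panels <- unique(calls$panel)
  if (length(panels) > 1L) {
    stop("mixed panels in call set: ", paste(panels, collapse = ", "),
         call. = FALSE)
  }
  classes <- diplotype_classes()
  counts <- table(factor(calls$diplotype, levels = classes))
  structure(list(panel = if (length(panels)) panels else NA_character_,
                 counts = stats::setNames(as.integer(counts), classes),
                 total = nrow(calls)),
            class = "class_counts")
}

#' @export
print.class_counts <- function(x, ...) {
  cat("Diplotype counts (", x$panel, "), n = ", x$total, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Compare the CPT and OPT translations on one dataset
#'
#' Calls every sample under both panels and reports the class-by-class
#' counts, the per-class gain by OPT, how many previously unresolved (CPT
#' No Result) samples OPT recovers, and the headline success rates.
#'
#' @param dataset A \code{\link{genotype_dataset}} covering the CPT marker
#'   superset.
#' @param registry Marker registry.
#' @return List of class \code{panel_comparison}: \code{cpt}, \code{opt}
#'   (both \code{class_counts}), \code{gain} (named integer, opt - cpt),
#'   \code{resolved_of_previous_no_result}, \code{changed_definitive}
#'   (samples definitive under both panels whose calls differ -- expected 0
#'   under complete LD), and \code{percentages} with \code{cpt_success},
#'   \code{opt_success} (2 dp) and \code{resolved_pct} of prior No Results
#'   (1 dp).
#' @export
compare_panels <- function(dataset, registry = poll_registry()) {
  cpt_calls <- call_dataset(dataset, poll_panel("CPT", registry), registry)
  opt_calls <- call_dataset(dataset, poll_panel("OPT", registry), registry)
  cpt <- genotype_class_counts(cpt_calls)
  opt <- genotype_class_counts(opt_calls)
  gain <- opt$counts - cpt$counts
  cpt_nr <- cpt_calls$diplotype == "NO_RESULT"
  resolved <- sum(cpt_nr & is_definitive(opt_calls$diplotype))
  changed <- sum(is_definitive(cpt_calls$diplotype) &
                   is_definitive(opt_calls$diplotype) &
                   cpt_calls$diplotype != opt_calls$diplotype)
  n <- nrow(dataset$samples)
  percentages <- list(
    cpt_success = if (n > 0) percent(sum(!cpt_nr), n, 2) else NA_real_,
    opt_success = if (n > 0)
      percent(sum(opt_calls$diplotype != "NO_RESULT"), n, 2) else NA_real_,
    resolved_pct = if (sum(cpt_nr) > 0)
      percent(resolved, sum(cpt_nr), 1) else NA_real_
  )
  structure(list(cpt = cpt, opt = opt, gain = gain,
                 resolved_of_previous_no_result = resolved,
                 changed_definitive = changed,
                 percentages = percentages,
                 cpt_calls = cpt_calls, opt_calls = opt_calls),
            class = "panel_comparison")
}

#' @export
print.panel_comparison <- function(x, ...) {
  tab <- data.frame(class = names(x$cpt$counts),
                    cpt = x$cpt$counts, opt = x$opt$counts,
                    gain = x$gain, row.names = NULL)
  print(tab)
  cat("success: CPT ", x$percentages$cpt_success, "%, OPT ",
      x$percentages$opt_success, "%\n", sep = "")
  cat("CPT No Results resolved by OPT: ",
      x$resolved_of_previous_no_result,
      if (!is.na(x$percentages$resolved_pct))
        paste0(" (", x$percentages$resolved_pct, "%)"), "\n", sep = "")
  invisible(x)
}

#' As a data.frame
#' @param x A \code{panel_comparison}.
#' @param ... Unused.
#' @export
as.data.frame.panel_comparison <- function(x, ...) {
  data.frame(class = names(x$cpt$counts), cpt = unname(x$cpt$counts),
              opt = unname(x$opt$counts), gain = unname(x$gain),
              stringsAsFactors = FALSE)
}

#' Per-marker call rates, by group
#'
#' QC summary of genotyping completeness: the fraction of samples with a
#' non-missing call at each marker, per group (breed by default) and for the
#' pooled "all" pseudo-group, as percentages rounded half-up to 2 dp.
#'
#' @param dataset A \code{\link{genotype_dataset}}.
#' @param by Column of the sample metadata to group by ("breed" or "sex"),
#'   or NULL for the pooled rate only.
#' @return data.frame with columns \code{group}, \code{rs_id}, \code{n},
#'   \code{call_rate} (percent; \code{NA} for an empty group).
#' @export
marker_call_rates <- function(dataset, by = "breed") {
  geno <- dataset$geno
  groups <- list(all = seq_len(nrow(geno)))
  if (!is.null(by)) {
    if (!by %in% names(dataset$samples)) {
      stop("no sample column '", by, "' to group by", call. = FALSE)
    }
    key <- dataset$samples[[by]]
    groups <- c(groups, split(seq_len(nrow(geno)), key))
  }
  out <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    n <- length(idx)
    rate <- if (n == 0) {
      rep(NA_real_, ncol(geno))
    } else {
      percent(colSums(!is.na(geno[idx, , drop = FALSE])), n, 2)
    }
    data.frame(group = g, rs_id = colnames(geno), n = n,
               call_rate = unname(rate), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
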