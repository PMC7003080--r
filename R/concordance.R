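#' Genotype-phenotype concordance table
#'
#' Joins diplotype calls to head-phenotype records on sample_id and
#' row-normalizes: for each definitive diplotype class, N phenotyped
#' animals and the percentage observed as Horn, Scur and Poll (half-up, 1
#' dp). NO_RESULT samples and samples without a usable phenotype are
#' excluded from the rows but counted in the attributes.
#'
#' @param calls Call table from \code{\link{call_dataset}}.
#' @param phenos Phenotype data.frame from \code{\link{read_phenotypes}}.
#' @return data.frame of class \code{concordance_table} with columns
#'   \code{class}, \code{n}, \code{horn_pct}, \code{scur_pct},
#'   \code{poll_pct} (percent columns \code{NA} when \code{n} = 0);
#'   attributes \code{n_unphenotyped} and \code{n_no_result}.
#' @export
concordance_table <- function(calls, phenos) {
  merged <- merge(calls[, c("sample_id", "diplotype")], phenos,
                  by = "sample_id", all.x = TRUE)
  merged$head_status[is.na(merged$head_status)] <- "unknown"
  n_no_result <- sum(!is_definitive(merged$diplotype))
  merged <- merged[is_definitive(merged$diplotype), , drop = FALSE]
  n_unphenotyped <- sum(merged$head_status == "unknown")
  merged <- merged[merged$head_status != "unknown", , drop = FALSE]
  classes <- setdiff(diplotype_classes(), "NO_RESULT")
  rows <- lapply(classes, function(cl) {
    sub <- merged[merged$diplotype == cl, ]
    n <- nrow(sub)
    pct <- function(status) {
      if (n == 0) NA_real_ else percent(sum(sub$head_status == status), n, 1)
    }
    data.frame(class = cl, n = n, horn_pct = pct("Horn"),
               scur_pct = pct("Scur"), poll_pct = pct("Poll"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_unphenotyped") <- n_unphenotyped
  attr(out, "n_no_result") <- n_no_result
  class(out) <- c("concordance_table", "data.frame")
  out
}

#' @export
print.concordance_table <- function(x, ...) {
  disp <- as.data.frame(x)
  for (col in c("horn_pct", "scur_pct", "poll_pct")) {
    disp[[col]] <- ifelse(is.na(x[[col]]) | x[[col]] == 0, "—",
                          formatC(x[[col]], format = "f", digits = 1))
  }
  print(disp, row.names = FALSE)
  cat("(excluded:", attr(x, "n_no_result"), "No Result,",
      attr(x, "n_unphenotyped"), "without phenotype)\n")
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table via the hypergeometric
#' distribution. With cell layout \code{[[a, b], [c, d]]} and fixed margins,
#' the one-sided p-values are hypergeometric tail sums in \code{a}; the
#' two-sided p-value sums the probabilities of all tables (same margins) no
#' more probable than the observed one, the convention used by
#' \code{stats::fisher.test}.
#'
#' @param tab 2x2 numeric matrix of non-negative counts (rows = groups,
#'   columns = outcome / not-outcome).
#' @param alternative "two.sided" (default), "greater" or "less"; sidedness
#'   refers to the association of row 1 with column 1.
#' @return The p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2, byrow = TRUE))  # 0.1
#' @export
fisher_exact_2x2 <- function(tab,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("all-zero table", call. = FALSE)
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # row-1 total
  n <- sum(tab[2, ])          # row-2 total
  k <- sum(tab[, 1])          # column-1 total
  support <- max(0L, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p <- switch(alternative,
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]),
    two.sided = {
      p_obs <- stats::dhyper(a, m, n, k)
      sum(probs[probs <= p_obs * (1 + 1e-7)])
    })
  min(1, p)
}

#' Compare poll rates between the two heterozygote classes
#'
#' Tests whether HPF animals are polled at a different rate than HPC
#' animals: builds the 2x2 table of heterozygote class (HPF, HPC) against
#' phenotype (Poll vs not-Poll, pooling Horn and Scur) and applies
#' \code{\link{fisher_exact_2x2}}. Samples without a usable phenotype are
#' dropped. Classes smaller than 30 animals are flagged: the exact test is
#' valid but the estimate is imprecise.
#'
#' @param calls Call table.
#' @param phenos Phenotype records.
#' @param alternative Passed to \code{\link{fisher_exact_2x2}};
#'   "greater" tests HPF more likely polled than HPC.
#' @return List: \code{table} (2x2 matrix), \code{prop_poll} (named,
#'   HPF/HPC), \code{n} (group sizes), \code{p_value},
#'   \code{small_groups} (names of classes with n < 30).
#' @export
het_poll_comparison <- function(calls, phenos,
                                alternative = "two.sided") {
  merged <- merge(calls[, c("sample_id", "diplotype")], phenos,
                  by = "sample_id")
  merged <- merged[merged$diplotype %in% c("HPF", "HPC") &
                     merged$head_status %in% c("Horn", "Scur", "Poll"), ]
  n <- c(HPF = sum(merged$diplotype == "HPF"),
         HPC = sum(merged$diplotype == "HPC"))
  empty <- names(n)[n == 0]
  if (length(empty)) {
    stop("no phenotyped samples in heterozygote class: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  poll <- c(HPF = sum(merged$diplotype == "HPF" &
                        merged$head_status == "Poll"),
            HPC = sum(merged$diplotype == "HPC" &
                        merged$head_status == "Poll"))
  tab <- rbind(HPF = c(Poll = poll[["HPF"]],
                       not_Poll = n[["HPF"]] - poll[["HPF"]]),
               HPC = c(Poll = poll[["HPC"]],
                       not_Poll = n[["HPC"]] - poll[["HPC"]]))
  list(table = tab,
       prop_poll = round_half_up(poll / n, 4),
       n = n,
       p_value = fisher_exact_2x2(tab, alternative),
       small_groups = names(n)[n < 30])
}
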