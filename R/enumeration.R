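# Semi-quantitative enumeration from enrichment dilution series.
#
# One enrichment tube per ten-fold dilution 10^-d, d = 0..6. A positive
# tube at dilution 10^-d is attributed 1 cfu/ml, i.e. the undiluted sample
# carries ~10^d cfu/ml, so the estimated log10 count is simply the highest
# positive exponent.

#' A per-sample enrichment dilution series
#'
#' @param sample_id Sample label.
#' @param group Grouping label (production step or retail class).
#' @param taxon Target taxon.
#' @param exponents Integer dilution exponents `d` (dilution `10^-d`),
#'   unique, between 0 and `max_exponent`.
#' @param positive Logical vector, same length: enrichment positivity.
#' @param max_exponent Largest admissible exponent (default 6: series are
#'   carried to the 10^-6 dilution).
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(sample_id, group, taxon, exponents, positive,
                            max_exponent = 6L) {
  if (!length(exponents))
    abort("a dilution series needs at least one tube", "invalid_input")
  exponents <- as.integer(exponents)
  if (any(is.na(exponents)) || anyDuplicated(exponents) ||
      any(exponents < 0L) || any(exponents > max_exponent))
    abort(sprintf("exponents must be unique integers in 0..%d", max_exponent),
          "invalid_input")
  if (length(positive) != length(exponents) || !is.logical(positive) ||
      anyNA(positive))
    abort("positive must be a logical vector matching exponents", "invalid_input")
  o <- order(exponents)
  structure(list(sample_id = sample_id, group = group, taxon = taxon,
                 exponents = exponents[o], positive = positive[o]),
            class = "dilution_series")
}

#' Estimate a log10 count from a dilution series
#'
#' The estimate is the highest dilution exponent with a positive tube
#' (1 cfu/ml attributed at dilution 10^-d implies 10^d cfu/ml undiluted).
#' An all-negative series gives `log_count = 0` with `detected = FALSE`;
#' a sample positive only in the undiluted tube gives `log_count = 0` with
#' `detected = TRUE`, so detection and count are deliberately decoupled at
#' the bottom of the scale. A non-monotone series (a negative tube below a
#' positive one) is admissible -- enrichment from a single tube per
#' dilution is noisy near the detection limit -- and is resolved in favour
#' of the highest positive exponent, with a flag.
#'
#' @param series A [dilution_series].
#' @return A list of class `count_estimate`: `sample_id`, `group`, `taxon`,
#'   `log_count`, `detected`, `flags`.
#' @examples
#' s <- dilution_series("c1", "A", "B. crudilactis", 0:6,
#'                      c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
#' estimate_log_count(s)$log_count
#' @export
estimate_log_count <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  pos <- series$exponents[series$positive]
  detected <- length(pos) > 0L
  log_count <- if (detected) max(pos) else 0L
  flags <- character(0)
  if (detected && any(!series$positive & series$exponents < max(pos)))
    flags <- "non-monotone series: negative tube below highest positive dilution"
  structure(list(sample_id = series$sample_id, group = series$group,
                 taxon = series$taxon, log_count = as.numeric(log_count),
                 detected = detected, flags = flags),
            class = "count_estimate")
}

#' Summarise count estimates by group
#'
#' Per `(group, taxon)` cell: the number and percentage of positive
#' samples, and the mean and sample standard deviation (n - 1 denominator)
#' of the log counts over all samples in the cell, non-detected samples
#' contributing 0. Percentages are rounded half-up to the nearest integer;
#' a single-sample cell reports SD 0.
#'
#' @param estimates List of `count_estimate` objects (from
#'   [estimate_log_count()]).
#' @param by Character vector of grouping fields, a subset of
#'   `c("group", "taxon")`.
#' @return A data frame of class `survey_summary` with columns `group`
#'   and/or `taxon`, `n`, `n_positive`, `percent_positive`, `mean_log`,
#'   `sd_log`.
#' @examples
#' counts <- c(4, 4, 5, 5, 0)
#' est <- lapply(seq_along(counts), function(i) {
#'   s <- dilution_series(paste0("s", i), "retail", "B. crudilactis",
#'                        0:6, 0:6 <= counts[i] & counts[i] > 0)
#'   estimate_log_count(s)
#' })
#' summarize_survey(est)
#' @export
summarize_survey <- function(estimates, by = c("group", "taxon")) {
  stopifnot(is.list(estimates), length(estimates) > 0L,
            all(vapply(estimates, inherits, TRUE, "count_estimate")))
  by <- match.arg(by, c("group", "taxon"), several.ok = TRUE)
  df <- data.frame(
    group = vapply(estimates, `[[`, "", "group"),
    taxon = vapply(estimates, `[[`, "", "taxon"),
    log_count = vapply(estimates, `[[`, 0, "log_count"),
    detected = vapply(estimates, `[[`, TRUE, "detected"),
    stringsAsFactors = FALSE
  )
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(cell) {
    n <- nrow(cell)
    res <- cell[1, by, drop = FALSE]
    res$n <- n
    res$n_positive <- sum(cell$detected)
    res$percent_positive <- round_half_up(100 * res$n_positive / n)
    res$mean_log <- mean(cell$log_count)
    res$sd_log <- if (n > 1L) stats::sd(cell$log_count) else 0
    res
  }))
  rownames(out) <- NULL
  class(out) <- c("survey_summary", "data.frame")
  out
}

#' Render survey summaries in the printed-table layout
#'
#' Formats each cell as the survey tables print them: positives as
#' `"n_positive (pct%)"` with integer percentages, counts as
#' `"mean ± sd"` with two decimals.
#'
#' @param summaries A `survey_summary` data frame.
#' @return A data frame with formatted `positives` and `mean_count`
#'   columns alongside the grouping columns.
#' @export
survey_table <- function(summaries) {
  stopifnot(inherits(summaries, "survey_summary"))
  keys <- intersect(c("group", "taxon"), names(summaries))
  out <- summaries[, keys, drop = FALSE]
  out$positives <- sprintf("%d/%d (%d%%)", summaries$n_positive, summaries$n,
                           summaries$percent_positive)
  out$mean_count <- sprintf("%.2f \u00b1 %.2f", summaries$mean_log,
                            summaries$sd_log)
  class(out) <- "data.frame"
  out
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("Semi-quantitative survey summary (log10 cfu per ml or g)\n")
  print.data.frame(x, row.names = FALSE, digits = 3, ...)
  invisible(x)
}

#' Read dilution series from CSV
#'
#' Expected columns: `sample_id`, `group`, `taxon`, and tube columns
#' `d0`..`d6` (or any `d<k>` subset) holding logicals or 0/1.
#'
#' @param path CSV file path.
#' @return A list of [dilution_series].
#' @export
read_dilution_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "taxon")
  if (!all(need %in% names(df)))
    abort(sprintf("dilution CSV must have columns: %s",
                  paste(need, collapse = ", ")), "invalid_input")
  dcols <- grep("^d[0-9]+$", names(df), value = TRUE)
  if (!length(dcols))
    abort("dilution CSV has no d<k> tube columns", "invalid_input")
  exps <- as.integer(sub("^d", "", dcols))
  lapply(seq_len(nrow(df)), function(i)
    dilution_series(df$sample_id[i], df$group[i], df$taxon[i],
                    exps, as.logical(unlist(df[i, dcols])),
                    max_exponent = max(exps, 6L)))
}

#' Write dilution series to CSV
#'
#' Inverse of [read_dilution_csv()].
#'
#' @param series List of [dilution_series] sharing one exponent layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dilution_csv <- function(series, path) {
  stopifnot(is.list(series), all(vapply(series, inherits, TRUE, "dilution_series")))
  exps <- series[[1]]$exponents
  rows <- lapply(series, function(s) {
    stopifnot(identical(s$exponents, exps))
    row <- data.frame(sample_id = s$sample_id, group = s$group,
                      taxon = s$taxon, stringsAsFactors = FALSE)
    for (j in seq_along(exps)) row[[paste0("d", exps[j])]] <- s$positive[j]
    row
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
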