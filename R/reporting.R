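#' @title Run summaries and manifests
#' @description Aggregates classification, brain-specificity, differential
#' inclusion, coding and overlap results into headline count/percentage
#' tables (half-up rounding to one decimal, the convention used throughout)
#' and a reproducible run manifest.
#' @name reporting
NULL

#' Half-up percentage to one decimal
#'
#' The rounding convention used in every reported percentage (plain
#' \code{round()} is half-even).
#'
#' @param count,denominator non-negative counts.
#' @return 100 * count / denominator, half-up rounded to one decimal
#'   (0 when the denominator is 0).
#' @export
percent_half_up <- function(count, denominator) {
  pct1(count, denominator)
}

#' Summarize a run's headline numbers
#'
#' @param classes frame from \code{\link{classify_exons}}.
#' @param brain frame from \code{\link{brain_specific}} (optional).
#' @param dpsi result of \code{\link{differential_inclusion}} (optional).
#' @param overlaps data.frame (name, n_universe, n_a, n_b, n_overlap)
#'   (optional) — rows are tested with \code{\link{overlap_test}}.
#' @param coding frame from \code{\link{class_coding_summary}} (optional).
#' @return object of class \code{microx_summary}: \code{$table} (metric,
#'   count, denominator, percent) and \code{$text} (plain-text report
#'   lines).
#' @export
summarize_run <- function(classes, brain = NULL, dpsi = NULL,
                          overlaps = NULL, coding = NULL) {
  rows <- list()
  add <- function(metric, count, denom = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, count = count, denominator = denom,
      percent = if (is.na(denom)) NA_real_ else pct1(count, denom),
      stringsAsFactors = FALSE)
  }
  expressed <- sum(classes$label %in% c("CS", "AS"))
  add("exons_total", nrow(classes))
  add("exons_expressed", expressed, nrow(classes))
  add("exons_CS", sum(classes$label == "CS"), expressed)
  add("exons_AS", sum(classes$label == "AS"), expressed)
  add("exons_not_expressed", sum(classes$label == "not-expressed"),
      nrow(classes))
  if (!is.null(brain)) {
    add("brain_specific", sum(brain$brain_specific), nrow(brain))
  }
  if (!is.null(dpsi)) {
    add("dpsi_reported", nrow(dpsi$table))
    add("dpsi_up", sum(dpsi$table$direction == "up"), nrow(dpsi$table))
    add("dpsi_down", sum(dpsi$table$direction == "down"), nrow(dpsi$table))
  }
  if (!is.null(coding)) {
    for (i in seq_len(nrow(coding))) {
      add(paste0("coding_potential_", coding$label[i]), coding$n_coding[i],
          coding$n[i])
    }
  }
  tab <- do.call(rbind, rows)
  text <- sprintf("%-28s %8s %10s %8s", "metric", "count", "denominator",
                  "percent")
  text <- c(text, sprintf("%-28s %8d %10s %8s", tab$metric, tab$count,
                          ifelse(is.na(tab$denominator), "-",
                                 tab$denominator),
                          ifelse(is.na(tab$percent), "-",
                                 sprintf("%.1f", tab$percent))))
  if (!is.null(overlaps)) {
    for (i in seq_len(nrow(overlaps))) {
      p <- overlap_test(overlaps$n_universe[i], overlaps$n_a[i],
                        overlaps$n_b[i], overlaps$n_overlap[i])
      text <- c(text, sprintf("overlap %-20s p = %.3g", overlaps$name[i], p))
    }
  }
  structure(list(table = tab, text = text), class = "microx_summary")
}

#' @export
print.microx_summary <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}

#' Write a summary to TSV + plain-text report
#' @param summary a \code{microx_summary}.
#' @param dir output directory.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(summary$table, file.path(dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(summary$text, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Build a reproducible run manifest
#'
#' Records the package version, seeds, input-file digests and per-stage row
#' counts; rerunning on identical inputs reproduces identical digests.
#'
#' @param inputs named character vector of input file paths.
#' @param seeds named vector of seeds used.
#' @param counts named vector of per-stage row counts.
#' @return named list (flat key-value), suitable for
#'   \code{\link{write_manifest}}.
#' @export
run_manifest <- function(inputs = character(0), seeds = integer(0),
                         counts = integer(0)) {
  digests <- vapply(inputs, function(p)
    as.character(tools::md5sum(p)), character(1))
  c(list(tool = "microx",
         version = as.character(utils::packageVersion("microx"))),
    setNames(as.list(digests), paste0("md5_", names(inputs))),
    setNames(as.list(seeds), paste0("seed_", names(seeds))),
    setNames(as.list(counts), paste0("n_", names(counts))))
}

#' Write a manifest as JSON
#' @param manifest list from \code{\link{run_manifest}}.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
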