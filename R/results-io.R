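#' Write analysis results to disk
#'
#' Renders an epistasis or pathway result table as CSV, JSON or a Markdown
#' table.  CSV and JSON carry the full-precision tidy table (JSON also
#' includes the thresholds used and, for epistasis results, the per-part
#' effects).  Markdown renders the classic matrix layout: one row per
#' combination, one column per trait, each cell
#' `"<label> <epsilon>"` with epsilon rounded to the trait's declared
#' `digits` (e.g. `"+SE 9.0"`, `"ADD -0.2"`).  An empty result table
#' yields a header-only file.
#'
#' @param results An `epistasis_tbl`, `pathway_tbl`, or plain data frame.
#' @param path Output file path.
#' @param format `"csv"`, `"json"` or `"markdown"` (default: from the file
#'   extension, falling back to csv).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = NULL) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               json = "json", md = "markdown",
                               markdown = "markdown", "csv")
  format <- match.arg(format, c("csv", "json", "markdown"))
  flat <- tidy_results(results)
  if (format == "csv") {
    readr::write_csv(flat, path)
  } else if (format == "json") {
    payload <- list(
      results = results_for_json(results),
      thresholds = list(k_sig = attr(results, "k_sig"),
                        abs_tol = attr(results, "abs_tol"))
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    writeLines(results_markdown(results), path)
  }
  invisible(path)
}

tidy_results <- function(results) {
  out <- as_tibble(results)
  keep <- !vapply(out, is.list, logical(1))
  out[keep]
}

results_for_json <- function(results) {
  out <- as_tibble(results)
  if ("w_parts" %in% names(out)) {
    out$w_parts <- lapply(out$w_parts, as.list)
    out$part_sems <- lapply(out$part_sems, as.list)
  }
  out
}

#' Format one epistasis cell
#'
#' @param label Class label (`"+SE"`, `"ADD"`, ...).
#' @param epsilon Interaction magnitude.
#' @param digits Decimal places for `epsilon`.
#' @return Character, e.g. `"+SE 9.0"`.
#' @keywords internal
format_epistasis_cell <- function(label, epsilon, digits = 1L) {
  mapply(function(l, e, d) paste(l, formatC(e, format = "f", digits = d)),
         label, epsilon, rep_len(digits, length(label)),
         USE.NAMES = FALSE)
}

results_markdown <- function(results) {
  if (inherits(results, "epistasis_tbl") && nrow(results) > 0) {
    ti <- attr(results, "trait_info")
    digits_of <- function(tr) {
      d <- if (!is.null(ti)) ti$digits[match(tr, ti$trait)] else NA
      ifelse(is.na(d), 1L, d)
    }
    wide <- as_tibble(results) |>
      dplyr::mutate(cell = format_epistasis_cell(
        .data$label, .data$epsilon,
        vapply(.data$trait, digits_of, numeric(1))
      )) |>
      dplyr::select("type", "combination", "genotype", "trait", "cell") |>
      tidyr::pivot_wider(names_from = "trait", values_from = "cell")
    return(markdown_table(wide))
  }
  markdown_table(tidy_results(results))
}

markdown_table <- function(df) {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE) else as.character(col)
  }), check.names = FALSE, stringsAsFactors = FALSE)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  if (nrow(df) == 0L) return(c(header, rule))
  body <- apply(df, 1L, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  c(header, rule, body)
}
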