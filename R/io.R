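#' Read and write deconvolution datasets
#'
#' `read_deconvolution()` reads a CSV or TSV trait table into a
#' [deconvolution()] object.  Two schemas are accepted: replicate-level
#' (`genotype`, `trait`, `value`; one row per replicate) or aggregated
#' (`genotype`, `trait`, `mean` and optionally `sem`, `n`).  The delimiter
#' is inferred from the file extension (`.tsv`/`.tab` = tab, else comma)
#' unless `delim` is given.  Files must be UTF-8 with a header row;
#' genotype labels are case-sensitive.  `write_deconvolution()` writes the
#' aggregated table back to CSV at full precision, so numeric columns
#' round-trip exactly.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` to infer from the extension.
#' @inheritParams deconvolution
#' @return A `deconvolution` (for `read_deconvolution()`); the input,
#'   invisibly (for `write_deconvolution()`).
#' @export
read_deconvolution <- function(path, sites, parent = NULL,
                               temperature = 298.15, trait_info = NULL,
                               delim = NULL) {
  delim <- delim %||%
    (if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ",")
  ## read as text, convert below with R's correctly rounded parser so that
  ## full-precision numeric columns round-trip bit-for-bit
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  num_cols <- intersect(names(raw), c("value", "mean", "sem", "n"))
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric `%s` at data line%s %s of %s",
                    col, if (length(bad) > 1) "s" else "",
                    paste(head(bad + 1L, 5), collapse = ", "), path))
    }
    raw[[col]] <- vals
  }
  if ("value" %in% names(raw)) {
    reps <- raw |> dplyr::count(.data$genotype, .data$trait)
    if (dplyr::n_distinct(reps$n) > 1L) {
      warn("inconsistent replicate counts across genotype-trait pairs")
    }
  }
  deconvolution(raw, sites = sites, parent = parent,
                temperature = temperature, trait_info = trait_info)
}

#' @param x A `deconvolution`.
#' @rdname read_deconvolution
#' @export
write_deconvolution <- function(x, path) {
  out <- as_tibble(x)
  for (col in c("mean", "sem")) {
    # 17 significant digits: doubles survive the text round trip bit-for-bit
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         sprintf("%.17g", out[[col]]))
  }
  readr::write_csv(out, path)
  invisible(x)
}

#' Validate a deconvolution dataset
#'
#' Report-only checks: completeness (which of the `2^n` genotypes are
#' unmeasured, per trait), SEM consistency against raw replicates
#' (`sem == sd/sqrt(n)`), and cross-trait consistency of derived kinetic
#' traits (product formation rate should equal NADPH consumption rate times
#' coupling efficiency wherever all three are measured, honouring percent
#' units).
#'
#' @param x A `deconvolution`.
#' @param rel_tol Relative tolerance for consistency checks.
#' @return A tibble with columns `check`, `status` (`"ok"`/`"warning"`) and
#'   `detail`.
#' @export
validate_deconvolution <- function(x, rel_tol = 0.05) {
  checks <- list()
  note <- function(check, status, detail) {
    checks[[length(checks) + 1L]] <<- tibble(
      check = check, status = status, detail = detail
    )
  }

  n <- length(sites(x))
  miss <- missing_genotypes(x)
  incomplete <- miss[lengths(miss$missing) > 0L, ]
  if (nrow(incomplete) == 0L) {
    note("completeness", "ok",
         sprintf("complete, %d genotypes, %d traits",
                 2^n, nrow(trait_info(x))))
  } else {
    for (i in seq_len(nrow(incomplete))) {
      note("completeness", "warning",
           sprintf("trait %s missing genotype(s): %s",
                   incomplete$trait[i],
                   paste(incomplete$missing[[i]], collapse = ", ")))
    }
  }

  reps <- replicates(x)
  if (!is.null(reps)) {
    ref <- reps |>
      dplyr::group_by(.data$genotype, .data$trait) |>
      dplyr::summarise(
        sem_ref = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
        .groups = "drop"
      ) |>
      dplyr::left_join(as_tibble(x), by = c("genotype", "trait")) |>
      dplyr::filter(abs(.data$sem - .data$sem_ref) >
                      rel_tol * pmax(abs(.data$sem_ref), 1e-12))
    if (nrow(ref) == 0L) {
      note("sem", "ok", "SEMs consistent with replicates (sd/sqrt(n))")
    } else {
      note("sem", "warning",
           sprintf("SEM inconsistent with replicates for %s / %s",
                   ref$genotype[1], ref$trait[1]))
    }
  }

  tr <- trait_names(x)
  if (all(c("ncr", "ce", "pfr") %in% tr)) {
    ti <- trait_info(x)
    ce_scale <- if (identical(ti$units[match("ce", ti$trait)], "%")) 100 else 1
    wide <- as_tibble(x) |>
      dplyr::filter(.data$trait %in% c("ncr", "ce", "pfr")) |>
      dplyr::select("genotype", "trait", "mean") |>
      tidyr::pivot_wider(names_from = "trait", values_from = "mean") |>
      dplyr::filter(!is.na(.data$ncr), !is.na(.data$ce), !is.na(.data$pfr)) |>
      dplyr::mutate(expected = .data$ncr * .data$ce / ce_scale) |>
      dplyr::filter(abs(.data$pfr - .data$expected) >
                      rel_tol * pmax(abs(.data$expected), 1e-12))
    if (nrow(wide) == 0L) {
      note("derived", "ok", "PFR consistent with NCR x CE")
    } else {
      for (g in wide$genotype) {
        note("derived", "warning",
             sprintf("PFR != NCR x CE for genotype %s", g))
      }
    }
  }

  dplyr::bind_rows(checks)
}
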