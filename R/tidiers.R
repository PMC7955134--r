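#' Tidiers for epiland result objects
#'
#' `tidy()` returns the plain tibble of results (list columns dropped);
#' `glance()` returns a one-row summary.
#'
#' @param x An `epistasis_tbl`, `pathway_tbl` or `deconvolution`.
#' @param ... Unused.
#' @return A tibble.
#' @name epiland-tidiers
NULL

#' @rdname epiland-tidiers
#' @export
tidy.epistasis_tbl <- function(x, ...) tidy_results(x)

#' @rdname epiland-tidiers
#' @export
glance.epistasis_tbl <- function(x, ...) {
  fam <- sub("^[+-]", "", x$label)
  tibble(
    n_results = nrow(x),
    n_traits = dplyr::n_distinct(x$trait),
    n_splits = dplyr::n_distinct(x$split),
    n_skipped = nrow(attr(x, "skipped") %||% tibble()),
    n_add = sum(fam == "ADD"),
    n_se = sum(fam == "SE"),
    n_me = sum(fam == "ME"),
    n_rse = sum(fam == "RSE"),
    pct_epistatic = if (nrow(x) > 0) {
      as.integer(round(100 * mean(fam != "ADD")))
    } else NA_integer_,
    k_sig = attr(x, "k_sig"),
    abs_tol = attr(x, "abs_tol")
  )
}

#' @rdname epiland-tidiers
#' @export
tidy.pathway_tbl <- function(x, ...) tidy_results(x)

#' @rdname epiland-tidiers
#' @export
glance.pathway_tbl <- function(x, ...) {
  tibble(
    n_pathways = nrow(x),
    n_accessible = attr(x, "n_accessible"),
    n_unevaluable = sum(is.na(x$verdict)),
    traits = paste(attr(x, "traits"), collapse = ", "),
    k_sig = attr(x, "k_sig"),
    abs_tol = attr(x, "abs_tol")
  )
}

#' @rdname epiland-tidiers
#' @export
tidy.deconvolution <- function(x, ...) as_tibble(x)

#' @rdname epiland-tidiers
#' @export
glance.deconvolution <- function(x, ...) {
  miss <- missing_genotypes(x)
  tibble(
    n_sites = length(sites(x)),
    n_genotypes = dplyr::n_distinct(x$genotype),
    n_traits = nrow(trait_info(x)),
    complete = all(lengths(miss$missing) == 0L),
    parent = parent_label(x),
    temperature = assay_temperature(x)
  )
}
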