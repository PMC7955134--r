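#' Build a deconvolution dataset
#'
#' A deconvolution dataset holds genotype x trait measurements for the
#' intermediate mutants between a parent (all mutations absent) and a full
#' n-site variant.  It is a tibble with one row per genotype-trait pair
#' (columns `genotype`, `trait`, `mean`, `sem`, `n`) carrying the site
#' names, parent label, assay temperature, per-trait metadata and (when
#' available) the raw replicate values as attributes.
#'
#' `data` may be replicate-level (columns `genotype`, `trait`, `value`, one
#' row per replicate) or pre-aggregated (columns `genotype`, `trait`,
#' `mean` and optionally `sem`, `n`).  Replicates are aggregated with the
#' arithmetic mean and the standard error of the mean,
#' `sem = sd(values) / sqrt(n)` (sample standard deviation, n-1
#' denominator); a single replicate gets `sem = 0`.
#'
#' @param data A data frame as described above.
#' @param sites Character vector of ordered site names.
#' @param parent Label of the parent genotype; defaults to the all-absent
#'   label (`"---"` for three sites).  The parent must be measured.
#' @param temperature Assay temperature in kelvin (used by free-energy
#'   derivations).
#' @param trait_info Optional tibble with per-trait metadata: columns among
#'   `trait`, `units`, `higher_is_better`, `kind`, `digits`.  Missing traits
#'   or columns are filled with defaults (unknown units, higher-is-better,
#'   measured, 1 digit).
#' @return A `deconvolution` tibble.
#' @examples
#' d <- deconvolution(
#'   data.frame(
#'     genotype = rep(c("--", "A-", "-B", "AB"), each = 2),
#'     trait = "activity",
#'     value = c(1, 1.2, 2, 2.2, 3, 3.1, 7, 7.3)
#'   ),
#'   sites = c("xA", "yB")
#' )
#' d
#' @export
deconvolution <- function(data, sites, parent = NULL,
                          temperature = 298.15, trait_info = NULL) {
  data <- as_tibble(data)
  if (nrow(data) == 0L) abort("no measurements: the dataset is empty")
  need <- c("genotype", "trait")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns `genotype` and `trait`")
  }
  replicates <- NULL
  if ("value" %in% names(data)) {
    if (!is.numeric(data$value)) {
      bad <- which(is.na(suppressWarnings(as.numeric(data$value))))
      abort(sprintf("non-numeric `value` in row%s %s",
                    if (length(bad) > 1) "s" else "",
                    paste(head(bad, 5), collapse = ", ")))
    }
    key <- paste(data$genotype, data$trait, sep = "\r")
    replicates <- tibble(
      genotype = data$genotype, trait = data$trait,
      replicate = stats::ave(seq_along(key), key,
                             FUN = seq_along),
      value = data$value
    )
    mean_v <- tapply(data$value, key, mean)
    sd_v <- tapply(data$value, key, sd)
    n_v <- lengths(split(data$value, key))
    ks <- strsplit(names(mean_v), "\r", fixed = TRUE)
    meas <- tibble::new_tibble(list(
      genotype = vapply(ks, `[[`, character(1), 1L),
      trait = vapply(ks, `[[`, character(1), 2L),
      mean = as.vector(mean_v),
      sem = as.vector(ifelse(n_v > 1L, sd_v / sqrt(n_v), 0)),
      n = as.integer(as.vector(n_v))
    ), nrow = length(mean_v))
  } else if ("mean" %in% names(data)) {
    if (!is.numeric(data$mean)) abort("column `mean` must be numeric")
    nr <- nrow(data)
    meas <- tibble::new_tibble(list(
      genotype = data$genotype, trait = data$trait, mean = data$mean,
      sem = if ("sem" %in% names(data)) as.numeric(data$sem) else
        rep(0, nr),
      n = if ("n" %in% names(data)) as.integer(data$n) else
        rep(NA_integer_, nr)
    ), nrow = nr)
    dup <- anyDuplicated(paste(meas$genotype, meas$trait, sep = "\r"))
    if (dup > 0L) {
      abort(sprintf("duplicate genotype-trait pair: %s / %s",
                    meas$genotype[dup], meas$trait[dup]))
    }
  } else {
    abort("`data` must have a `value` (replicate) or `mean` column")
  }

  parent <- parent %||% strrep("-", length(sites))
  bad <- unique(meas$genotype[nchar(meas$genotype) != length(sites)])
  if (length(bad) > 0L) {
    abort(sprintf("genotype label%s %s: expected width %d (one character per site)",
                  if (length(bad) > 1) "s" else "",
                  paste(sQuote(bad), collapse = ", "), length(sites)))
  }
  if (!parent %in% meas$genotype) {
    abort(sprintf("parent genotype %s is not measured", sQuote(parent)))
  }
  trait_info <- complete_trait_info(trait_info, unique(meas$trait))
  masks <- vapply(meas$genotype,
                  function(g) as.numeric(mask_from_label(g, sites)),
                  numeric(1))
  meas <- meas[order(masks, meas$trait), ]
  new_deconvolution(meas, sites = sites, parent = parent,
                    temperature = temperature, trait_info = trait_info,
                    replicates = replicates)
}

new_deconvolution <- function(meas, sites, parent, temperature,
                              trait_info, replicates = NULL,
                              provenance = NULL) {
  structure(
    as_tibble(meas),
    sites = sites, parent = parent, temperature = temperature,
    trait_info = trait_info, replicates = replicates,
    provenance = provenance,
    class = c("deconvolution", class(tibble()))
  )
}

complete_trait_info <- function(trait_info, traits) {
  nt <- length(traits)
  base <- tibble::new_tibble(list(
    trait = traits, units = rep("", nt),
    higher_is_better = rep(TRUE, nt),
    kind = rep("measured", nt), digits = rep(1L, nt)
  ), nrow = nt)
  if (is.null(trait_info)) return(base)
  trait_info <- as_tibble(trait_info)
  if (!"trait" %in% names(trait_info)) abort("trait_info needs a `trait` column")
  idx <- match(trait_info$trait, base$trait)
  hit <- !is.na(idx)
  for (col in intersect(names(trait_info),
                        c("units", "higher_is_better", "kind", "digits"))) {
    base[[col]][idx[hit]] <- trait_info[[col]][hit]
  }
  if (any(!hit)) {
    warn(sprintf("trait_info for unmeasured trait(s): %s",
                 paste(trait_info$trait[!hit], collapse = ", ")))
  }
  base
}

#' Deconvolution accessors
#'
#' Small helpers to read the metadata carried by a [deconvolution()] object:
#' the ordered site names, the parent genotype label, the assay temperature,
#' the per-trait metadata table, the raw replicate table (or `NULL`), and
#' per-trait lists of unmeasured genotypes.
#'
#' @param x A `deconvolution`.
#' @return See each helper; `missing_genotypes()` returns a tibble with
#'   columns `trait` and `missing` (list column of absent labels).
#' @name deconvolution-accessors
NULL

#' @rdname deconvolution-accessors
#' @export
sites <- function(x) attr(x, "sites")

#' @rdname deconvolution-accessors
#' @export
parent_label <- function(x) attr(x, "parent")

#' @rdname deconvolution-accessors
#' @export
assay_temperature <- function(x) attr(x, "temperature")

#' @rdname deconvolution-accessors
#' @export
trait_info <- function(x) attr(x, "trait_info")

#' @rdname deconvolution-accessors
#' @export
replicates <- function(x) attr(x, "replicates")

#' @rdname deconvolution-accessors
#' @export
trait_names <- function(x) trait_info(x)$trait

#' @rdname deconvolution-accessors
#' @export
missing_genotypes <- function(x) {
  all_g <- genotype_labels(sites(x))
  x |>
    as_tibble() |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      missing = list(setdiff(all_g, .data$genotype)), .groups = "drop"
    )
}

#' @rdname deconvolution-accessors
#' @export
is_complete <- function(x) {
  all(lengths(missing_genotypes(x)$missing) == 0L)
}

#' @export
print.deconvolution <- function(x, ...) {
  n <- length(sites(x))
  miss <- missing_genotypes(x)
  complete <- all(lengths(miss$missing) == 0L)
  cat(sprintf(
    "<deconvolution> %d site%s (%s), parent %s, %d genotype%s, %d trait%s, %s\n",
    n, if (n > 1) "s" else "", paste(sites(x), collapse = ", "),
    parent_label(x),
    length(unique(x$genotype)), if (length(unique(x$genotype)) > 1) "s" else "",
    nrow(trait_info(x)), if (nrow(trait_info(x)) > 1) "s" else "",
    if (complete) "complete" else "incomplete"
  ))
  NextMethod()
}

## Named lookup vectors used throughout the analysis modules.
trait_lookup <- function(x, trait) {
  i <- which(x$trait == trait)
  g <- x$genotype[i]
  sem <- x$sem[i]
  sem[is.na(sem)] <- 0
  list(mean = setNames(x$mean[i], g), sem = setNames(sem, g))
}

trait_orientation <- function(x, trait) {
  ti <- trait_info(x)
  hib <- ti$higher_is_better[match(trait, ti$trait)]
  ifelse(is.na(hib) | hib, 1, -1)
}
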