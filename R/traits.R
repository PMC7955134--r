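#' Regioselectivity as a transition-state free-energy difference
#'
#' Converts the fraction `p` of product flux going to the target regioisomer
#' into the relative free-energy difference of the competing transition
#' states, `ddG = R*T*ln(p / (1 - p))` in kJ/mol (R = 8.314 J/mol/K).
#' `ddG` is 0 at a 1:1 product ratio, positive when the target isomer is
#' favoured, and antisymmetric: `ddG(p) = -ddG(1 - p)`.
#' `selectivity_ddg_sem()` propagates a standard error on `p` by the delta
#' method, `sem(ddG) = R*T*sem(p) / (p*(1-p))`.
#'
#' @param p Fraction in (0, 1) of flux to the target isomer.  `p` may be
#'   measured against a single competing isomer ("pairwise" basis) or
#'   against all other products ("total" basis, the default basis used for
#'   the bundled example data); the transform is the same, the
#'   interpretation differs.
#' @param temperature Temperature in kelvin.
#' @param clamp Optional small positive number: values of `p` equal to 0 or
#'   1 are pulled to `clamp` / `1 - clamp` instead of erroring.
#' @param p_sem Standard error of `p`.
#' @return Numeric vector, kJ/mol.
#' @examples
#' selectivity_to_ddg(0.94, 298.15) # 6.82 kJ/mol
#' selectivity_to_ddg(0.5) # 0
#' @export
selectivity_to_ddg <- function(p, temperature = 298.15, clamp = NULL) {
  if (!is.null(clamp)) {
    stopifnot(clamp > 0, clamp < 0.5)
    p <- pmin(pmax(p, clamp), 1 - clamp)
  }
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    abort("selectivity at bound; ddG undefined for p in {0, 1} (set `clamp` to truncate)")
  }
  .R_kJ * temperature * log(p / (1 - p))
}

#' @rdname selectivity_to_ddg
#' @export
selectivity_ddg_sem <- function(p, p_sem, temperature = 298.15) {
  .R_kJ * temperature * p_sem / (p * (1 - p))
}

#' Derived kinetic traits
#'
#' Elementary transforms between the measured kinetic quantities of an
#' NADPH-dependent monooxygenase assay.  `compute_pfr()` gives the product
#' formation rate as NADPH consumption rate times coupling efficiency;
#' `compute_ce()` is its inverse (the fraction of consumed NADPH channelled
#' into product); `compute_ttf()` normalises total turnovers by the time to
#' NADPH depletion; `correct_ncr()` subtracts the substrate-free NADPH leak
#' rate from the raw consumption rate (negative results are kept, with a
#' warning, since a leak exceeding consumption is informative).
#'
#' @param ncr NADPH consumption rate (per minute), non-negative.
#' @param ce Coupling efficiency as a fraction in \[0, 1\].
#' @param pfr Product formation rate (per minute).
#' @param ttn Total turnover number (dimensionless).
#' @param elapsed Time to NADPH depletion, minutes, positive.
#' @param raw_rate,leak_rate Raw and substrate-free NADPH consumption
#'   rates (per minute), non-negative.
#' @return Numeric vector.
#' @examples
#' compute_pfr(100, 0.37) # 37
#' compute_ce(37, 100) # 0.37
#' compute_ttf(1580, 10) # 158
#' correct_ncr(120, 20) # 100
#' @export
compute_pfr <- function(ncr, ce) {
  if (any(ncr < 0, na.rm = TRUE)) abort("`ncr` must be non-negative")
  if (any(ce > 1, na.rm = TRUE)) {
    abort("`ce` > 1: coupling efficiency must be a fraction (divide percentages by 100)")
  }
  if (any(ce < 0, na.rm = TRUE)) abort("`ce` must be non-negative")
  ncr * ce
}

#' @rdname compute_pfr
#' @export
compute_ce <- function(pfr, ncr) {
  if (any(ncr == 0, na.rm = TRUE)) {
    abort("coupling efficiency undefined at ncr = 0")
  }
  pfr / ncr
}

#' @rdname compute_pfr
#' @export
compute_ttf <- function(ttn, elapsed) {
  if (any(elapsed <= 0, na.rm = TRUE)) {
    abort("`elapsed` must be positive")
  }
  ttn / elapsed
}

#' @rdname compute_pfr
#' @export
correct_ncr <- function(raw_rate, leak_rate) {
  if (any(raw_rate < 0, na.rm = TRUE) || any(leak_rate < 0, na.rm = TRUE)) {
    abort("rates must be non-negative")
  }
  out <- raw_rate - leak_rate
  neg <- sum(out < 0, na.rm = TRUE)
  if (neg > 0) {
    warn(sprintf("leak exceeds consumption for %d value(s); kept negative", neg))
  }
  out
}

#' Add a derived trait to a deconvolution dataset
#'
#' Computes one of the built-in derived traits for every genotype and
#' appends it to the dataset.  When raw replicates of all input traits are
#' available the derivation is applied per replicate (replicate i of each
#' input combined with replicate i of the others) and the SEM recomputed
#' from the derived replicates; otherwise it is applied to the means with a
#' delta-method SEM.
#'
#' Built-in formulas (`formula` =):
#' \describe{
#'   \item{`"ddg"`}{[selectivity_to_ddg()] of a selectivity trait.  Input
#'     values with `%` units (or a maximum above 1) are divided by 100.}
#'   \item{`"pfr"`}{[compute_pfr()] from `ncr` and `ce` inputs.}
#'   \item{`"ce"`}{[compute_ce()] from `pfr` and `ncr` inputs.}
#'   \item{`"ttf"`}{[compute_ttf()] from a `ttn` input and fixed `elapsed`.}
#'   \item{`"ncr_corrected"`}{[correct_ncr()] from raw and leak inputs.}
#' }
#'
#' @param x A [deconvolution()].
#' @param name Name of the new trait.
#' @param formula One of `"ddg"`, `"pfr"`, `"ce"`, `"ttf"`,
#'   `"ncr_corrected"`.
#' @param inputs Character vector of input trait names, in the order the
#'   formula expects (defaults: `"sel"`; `c("ncr","ce")`; `c("pfr","ncr")`;
#'   `"ttn"`; `c("ncr_raw","ncr_leak")`).
#' @param temperature Kelvin; defaults to the dataset's assay temperature.
#' @param elapsed Minutes (for `"ttf"`).
#' @param units,higher_is_better,digits Metadata for the new trait.
#' @param overwrite If the trait already exists, error unless `TRUE`.
#' @param clamp Passed to [selectivity_to_ddg()].
#' @return The dataset with the derived trait appended; its `trait_info`
#'   records `kind = "derived"` and the input traits.
#' @export
derive_trait <- function(x, name, formula = c("ddg", "pfr", "ce", "ttf",
                                              "ncr_corrected"),
                         inputs = NULL, temperature = NULL, elapsed = NULL,
                         units = NULL, higher_is_better = TRUE,
                         digits = 1L, overwrite = FALSE, clamp = NULL) {
  formula <- match.arg(formula)
  stopifnot(inherits(x, "deconvolution"))
  inputs <- inputs %||% switch(formula,
    ddg = "sel", pfr = c("ncr", "ce"), ce = c("pfr", "ncr"),
    ttf = "ttn", ncr_corrected = c("ncr_raw", "ncr_leak")
  )
  absent <- setdiff(inputs, unique(x$trait))
  if (length(absent) > 0L) {
    warn(sprintf("input trait(s) %s not in dataset; %s skipped",
                 paste(absent, collapse = ", "), name))
    return(x)
  }
  if (name %in% x$trait && !overwrite) {
    abort(sprintf("trait %s already present (use overwrite = TRUE)", sQuote(name)))
  }
  temperature <- temperature %||% assay_temperature(x)
  ti <- trait_info(x)
  pct <- function(tr) identical(ti$units[match(tr, ti$trait)], "%")

  fn <- switch(formula,
    ddg = function(v) {
      p <- if (pct(inputs[1]) || max(v[[1]], na.rm = TRUE) > 1) {
        v[[1]] / 100
      } else v[[1]]
      selectivity_to_ddg(p, temperature, clamp = clamp)
    },
    pfr = function(v) {
      ce <- if (pct(inputs[2]) || max(v[[2]], na.rm = TRUE) > 1) {
        v[[2]] / 100
      } else v[[2]]
      compute_pfr(v[[1]], ce)
    },
    ce = function(v) compute_ce(v[[1]], v[[2]]),
    ttf = function(v) {
      if (is.null(elapsed)) abort("`elapsed` is required for formula = \"ttf\"")
      compute_ttf(v[[1]], elapsed)
    },
    ncr_corrected = function(v) correct_ncr(v[[1]], v[[2]])
  )

  reps <- replicates(x)
  have_reps <- !is.null(reps) && all(inputs %in% reps$trait)
  if (have_reps) {
    wide <- reps |>
      dplyr::filter(.data$trait %in% inputs) |>
      tidyr::pivot_wider(names_from = "trait", values_from = "value") |>
      tidyr::drop_na(dplyr::all_of(inputs))
    derived_reps <- wide |>
      dplyr::mutate(trait = name,
                    value = fn(lapply(inputs, function(tr) wide[[tr]]))) |>
      dplyr::select("genotype", "trait", "replicate", "value")
    new_meas <- derived_reps |>
      dplyr::group_by(.data$genotype, .data$trait) |>
      dplyr::summarise(
        mean = mean(.data$value),
        sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
        n = dplyr::n(), .groups = "drop"
      )
    reps <- dplyr::bind_rows(reps, derived_reps)
  } else {
    wide_m <- as_tibble(x) |>
      dplyr::filter(.data$trait %in% inputs) |>
      dplyr::select("genotype", "trait", "mean") |>
      tidyr::pivot_wider(names_from = "trait", values_from = "mean") |>
      tidyr::drop_na(dplyr::all_of(inputs))
    wide_s <- as_tibble(x) |>
      dplyr::filter(.data$trait %in% inputs) |>
      dplyr::select("genotype", "trait", "sem") |>
      tidyr::pivot_wider(names_from = "trait", values_from = "sem")
    wide_s <- wide_s[match(wide_m$genotype, wide_s$genotype), ]
    vals <- lapply(inputs, function(tr) wide_m[[tr]])
    mean_out <- fn(vals)
    sem_out <- delta_method_sem(fn, vals,
                                lapply(inputs, function(tr) {
                                  dplyr::coalesce(wide_s[[tr]], 0)
                                }))
    new_meas <- tibble(genotype = wide_m$genotype, trait = name,
                       mean = mean_out, sem = sem_out,
                       n = NA_integer_)
  }

  meas <- dplyr::bind_rows(as_tibble(x), new_meas)
  info <- dplyr::bind_rows(
    ti[ti$trait != name, ],
    tibble(trait = name,
           units = units %||% switch(formula, ddg = "kJ/mol", ce = "",
                                     "1/min"),
           higher_is_better = higher_is_better, kind = "derived",
           digits = as.integer(digits),
           derived_from = paste(inputs, collapse = "+"))
  )
  new_deconvolution(meas, sites = sites(x), parent = parent_label(x),
                    temperature = assay_temperature(x), trait_info = info,
                    replicates = reps, provenance = attr(x, "provenance"))
}

## First-order (delta-method) SEM of fn(vals) under independent errors:
## numeric partial derivatives at the means.
delta_method_sem <- function(fn, vals, sems) {
  base <- fn(vals)
  var_out <- rep(0, length(base))
  for (j in seq_along(vals)) {
    h <- pmax(abs(vals[[j]]) * 1e-6, 1e-9)
    shifted <- vals
    shifted[[j]] <- vals[[j]] + h
    grad <- (fn(shifted) - base) / h
    var_out <- var_out + (grad * sems[[j]])^2
  }
  sqrt(var_out)
}
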