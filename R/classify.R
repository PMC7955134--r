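#' Classify an epistatic interaction
#'
#' Assigns one of the seven interaction classes from the part effects
#' `w_i = f(part_i) - f(parent)`, the combined effect
#' `w_combined = f(union) - f(parent)` and the deviation from additivity
#' `epsilon` (all on the trait's oriented scale, so that positive means
#' beneficial):
#'
#' * `ADD` - `|epsilon| <= max(k_sig * epsilon_sem, abs_tol)`: no
#'   resolvable interaction.
#' * `+ME` / `-ME` (magnitude epistasis) - all parts share one effect sign
#'   (all beneficial or all deleterious) and the combination over- or
#'   under-shoots additivity without reversing that sign; the label's sign
#'   is the sign of `epsilon`.
#' * `+SE` / `-SE` (sign epistasis) - the parts have opposite individual
#'   effect signs; positive or negative by the sign of `epsilon`.
#' * `+RSE` / `-RSE` (reciprocal sign epistasis) - all parts share one
#'   sign but the combined effect has the opposite sign: `+RSE` when all
#'   parts are deleterious yet the combination is beneficial, `-RSE` when
#'   all parts are beneficial yet the combination is deleterious.
#'
#' A part whose effect is within `max(k_sig * part_sem, abs_tol)` of zero
#' has no resolvable sign; it is grouped with the majority sign of the
#' resolvable parts (which preserves ME over an unstable SE call) and the
#' result is flagged `marginal`.  If no part sign is resolvable the parts
#' are grouped with the sign of the combined effect (falling back to the
#' sign of `epsilon`).  The combined effect must itself exceed its own
#' threshold to count as a sign reversal (RSE).
#'
#' @param w_parts Numeric vector of oriented part effects.
#' @param w_combined Oriented combined effect.
#' @param epsilon,epsilon_sem Deviation from additivity and its SEM.
#' @param part_sems SEMs of the part effects (recycled).
#' @param combined_sem SEM of the combined effect.
#' @param k_sig Multiplier on SEMs for all significance thresholds.
#' @param abs_tol Absolute floor for all thresholds.
#' @return A list with `label` (e.g. `"+SE"`, `"ADD"`) and `marginal`
#'   (logical: some part sign was unresolvable).
#' @examples
#' classify_epistasis(c(2, 3), w_combined = 9, epsilon = 4, epsilon_sem = 0.5)
#' classify_epistasis(c(-2, 5), w_combined = 7, epsilon = 4, epsilon_sem = 0.5)
#' classify_epistasis(c(-2, -3), w_combined = 4, epsilon = 9, epsilon_sem = 0.5)
#' @export
classify_epistasis <- function(w_parts, w_combined, epsilon, epsilon_sem,
                               part_sems = 0, combined_sem = 0,
                               k_sig = 1, abs_tol = 0) {
  part_sems <- rep_len(dplyr::coalesce(part_sems, 0), length(w_parts))
  epsilon_sem <- dplyr::coalesce(epsilon_sem, 0)
  combined_sem <- dplyr::coalesce(combined_sem, 0)

  tol_eps <- max(k_sig * epsilon_sem, abs_tol)
  thr_part <- pmax(k_sig * part_sems, abs_tol)
  marginal <- abs(w_parts) <= thr_part
  if (abs(epsilon) <= tol_eps) {
    return(list(label = "ADD", marginal = any(marginal)))
  }

  s <- sign(w_parts)
  thr_comb <- max(k_sig * combined_sem, abs_tol)
  if (all(marginal)) {
    shared <- if (abs(w_combined) > thr_comb) sign(w_combined) else sign(epsilon)
    s[] <- shared
  } else if (any(marginal)) {
    res <- s[!marginal]
    maj <- if (sum(res > 0) >= sum(res < 0)) 1 else -1
    s[marginal] <- maj
  }

  sign_char <- if (epsilon > 0) "+" else "-"
  if (length(unique(s)) > 1L) {
    return(list(label = paste0(sign_char, "SE"), marginal = any(marginal)))
  }
  shared <- s[1]
  flip <- sign(w_combined) == -shared && abs(w_combined) > thr_comb
  base <- if (flip) "RSE" else "ME"
  list(label = paste0(sign_char, base), marginal = any(marginal))
}

#' Epistasis analysis of a full deconvolution
#'
#' Runs [epistasis_epsilon()] and [classify_epistasis()] for every
#' enumerated split (see [enumerate_splits()]) on every requested trait.
#' Splits whose part, union or parent genotypes are unmeasured for a trait
#' are skipped and listed in the `skipped` attribute.  Traits whose
#' metadata declares `higher_is_better = FALSE` are classified on the
#' flipped scale, so labels always read in the direction of improvement.
#'
#' @param x A [deconvolution()].
#' @param traits Character vector of traits to analyse (default: all).
#' @param mode Split enumeration mode, see [enumerate_splits()].
#' @param k_sig,abs_tol Significance thresholds, see
#'   [classify_epistasis()].
#' @return A tibble of class `epistasis_tbl`, one row per (split, trait):
#'   `split`, `type`, `combination` (e.g. `"I-- + -II"`), `genotype` (the
#'   union), `trait`, `w_parts` and `part_sems` (list columns), `expected`,
#'   `expected_sem`, `observed`, `observed_sem`, `epsilon`, `epsilon_sem`,
#'   `label`, `significant`, `marginal`.  Attributes: `skipped` (tibble of
#'   skipped split-trait pairs with reasons), `k_sig`, `abs_tol`, `mode`,
#'   `trait_info`.
#' @examples
#' fx <- bm3_fixture()
#' res <- analyze_epistasis(fx, traits = c("ddg", "ttf"))
#' dplyr::filter(res, type == "T")
#' @export
analyze_epistasis <- function(x, traits = NULL, mode = "standard",
                              k_sig = 1, abs_tol = 0) {
  stopifnot(inherits(x, "deconvolution"))
  traits <- traits %||% trait_names(x)
  unknown <- setdiff(traits, trait_names(x))
  if (length(unknown) > 0L) {
    abort(sprintf("trait(s) not in dataset: %s", paste(unknown, collapse = ", ")))
  }
  splits <- enumerate_splits(length(sites(x)), mode = mode)

  rows <- list()
  skipped <- list()
  for (tr in traits) {
    orient <- trait_orientation(x, tr)
    lk <- trait_lookup(x, tr)
    for (i in seq_len(nrow(splits))) {
      parts <- splits$parts[[i]]
      labels <- vapply(parts, label_from_indices, character(1),
                       sites = sites(x))
      u_label <- label_from_indices(splits$union[[i]], sites(x))
      req <- c(parent_label(x), labels, u_label)
      absent <- setdiff(req, names(lk$mean))
      if (length(absent) > 0L) {
        skipped[[length(skipped) + 1L]] <- tibble(
          split = splits$split[i], trait = tr,
          reason = paste("missing genotype(s):",
                         paste(absent, collapse = ", "))
        )
        next
      }
      st <- split_stats(x, parts, tr, lk = lk)
      w_comb <- st$observed - st$f0
      cls <- classify_epistasis(
        w_parts = orient * st$w_parts,
        w_combined = orient * w_comb,
        epsilon = orient * st$epsilon,
        epsilon_sem = st$epsilon_sem,
        part_sems = sqrt(st$part_sems^2 + st$s0^2),
        combined_sem = sqrt(st$observed_sem^2 + st$s0^2),
        k_sig = k_sig, abs_tol = abs_tol
      )
      rows[[length(rows) + 1L]] <- list(
        split = splits$split[i], type = splits$type[i],
        combination = paste(labels, collapse = " + "),
        genotype = st$u_label, trait = tr, n_parts = length(parts),
        w_parts = st$w_parts, part_sems = st$part_sems,
        expected = st$expected, expected_sem = st$expected_sem,
        observed = st$observed, observed_sem = st$observed_sem,
        epsilon = st$epsilon, epsilon_sem = st$epsilon_sem,
        label = cls$label, significant = cls$label != "ADD",
        marginal = cls$marginal
      )
    }
  }
  grab <- function(field) vapply(rows, `[[`, vector(mode_of[[field]], 1L),
                                 field)
  mode_of <- list(split = "integer", type = "character",
                  combination = "character", genotype = "character",
                  trait = "character", n_parts = "integer",
                  expected = "numeric", expected_sem = "numeric",
                  observed = "numeric", observed_sem = "numeric",
                  epsilon = "numeric", epsilon_sem = "numeric",
                  label = "character", significant = "logical",
                  marginal = "logical")
  out <- if (length(rows) == 0L) {
    tibble(split = integer(), type = character(), combination = character(),
           genotype = character(), trait = character(), n_parts = integer(),
           w_parts = list(), part_sems = list(), expected = numeric(),
           expected_sem = numeric(), observed = numeric(),
           observed_sem = numeric(), epsilon = numeric(),
           epsilon_sem = numeric(), label = character(),
           significant = logical(), marginal = logical())
  } else {
    tibble(
      split = grab("split"), type = grab("type"),
      combination = grab("combination"), genotype = grab("genotype"),
      trait = grab("trait"), n_parts = grab("n_parts"),
      w_parts = lapply(rows, `[[`, "w_parts"),
      part_sems = lapply(rows, `[[`, "part_sems"),
      expected = grab("expected"), expected_sem = grab("expected_sem"),
      observed = grab("observed"), observed_sem = grab("observed_sem"),
      epsilon = grab("epsilon"), epsilon_sem = grab("epsilon_sem"),
      label = grab("label"), significant = grab("significant"),
      marginal = grab("marginal")
    )
  }
  structure(
    out,
    skipped = if (length(skipped) > 0) dplyr::bind_rows(skipped) else
      tibble(split = integer(), trait = character(), reason = character()),
    k_sig = k_sig, abs_tol = abs_tol, mode = mode,
    trait_info = trait_info(x),
    class = c("epistasis_tbl", class(tibble()))
  )
}

#' Summarise epistasis classes per trait
#'
#' Counts and integer percentages of each interaction class, class family
#' (SE/ME/RSE/ADD) and sign per trait.
#'
#' @param results An `epistasis_tbl` from [analyze_epistasis()], or any
#'   data frame with `trait` and `label` columns.
#' @return A tibble: `trait`, `label`, `family`, `sign`, `n`, `pct`
#'   (percentage of that trait's splits, rounded to integer).
#' @examples
#' summarize_epistasis(analyze_epistasis(bm3_fixture(), traits = "ddg"))
#' @export
summarize_epistasis <- function(results) {
  stopifnot(all(c("trait", "label") %in% names(results)))
  as_tibble(results) |>
    dplyr::count(.data$trait, .data$label, name = "n") |>
    dplyr::group_by(.data$trait) |>
    dplyr::mutate(
      family = sub("^[+-]", "", .data$label),
      sign = dplyr::case_when(
        startsWith(.data$label, "+") ~ "+",
        startsWith(.data$label, "-") ~ "-",
        TRUE ~ ""
      ),
      pct = as.integer(round(100 * .data$n / sum(.data$n)))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("trait", "label", "family", "sign", "n", "pct")
}

#' @export
print.epistasis_tbl <- function(x, ...) {
  sk <- attr(x, "skipped")
  cat(sprintf("<epistasis analysis> %d result%s (%d skipped), k_sig = %g, abs_tol = %g\n",
              nrow(x), if (nrow(x) != 1) "s" else "",
              if (is.null(sk)) 0L else nrow(sk),
              attr(x, "k_sig"), attr(x, "abs_tol")))
  NextMethod()
}
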