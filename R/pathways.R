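#' Enumerate stepwise mutational pathways
#'
#' A pathway is one of the `n!` orders in which the `n` mutations can be
#' introduced one at a time, giving a chain of `n + 1` genotypes from the
#' parent to the full variant in which consecutive genotypes differ by
#' exactly one added site.  Pathways are numbered 1..n! in lexicographic
#' order of the site-index permutation (for three sites, pathways 5 and 6
#' are the two that introduce the third site first).
#'
#' @param n_sites Number of mutation sites (>= 1).
#' @return A tibble with columns `pathway` (id) and `ordering` (list of
#'   site-index permutations).
#' @examples
#' enumerate_pathways(3) # 6 pathways
#' @export
enumerate_pathways <- function(n_sites) {
  stopifnot(n_sites >= 1)
  perms <- permutations_lex(n_sites)
  tibble(pathway = seq_along(perms), ordering = perms)
}

permutations_lex <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_lex(n - 1L)
    pool <- setdiff(seq_len(n), i)
    for (p in rest) {
      out[[length(out) + 1L]] <- c(i, pool[p])
    }
  }
  out
}

## Genotype labels along one ordering, parent first.
pathway_genotypes <- function(ordering, sites) {
  acc <- integer(0)
  c(strrep("-", length(sites)),
    vapply(seq_along(ordering), function(k) {
      label_from_indices(ordering[seq_len(k)], sites)
    }, character(1)))
}

#' Classify pathway accessibility
#'
#' A pathway is *favoured* when no step passes through a local minimum on
#' any considered trait: every step's oriented change must satisfy
#' `delta >= -tol`, with `tol = max(k_sig * step_sem, abs_tol)` and
#' `step_sem = sqrt(sem_from^2 + sem_to^2)`.  Steps whose decrease is
#' within tolerance (including exact ties) are permitted.  A pathway with
#' at least one blocked step is *disfavoured*; the first blocking step and
#' the traits that block it are recorded.  Under several traits a step is
#' permitted only if it is permitted on every trait, so the favoured set is
#' the intersection of the single-trait favoured sets.
#'
#' @param x A [deconvolution()].
#' @param traits Traits to require jointly (default: all traits).
#' @param k_sig,abs_tol Tolerance parameters, see Details.
#' @return A tibble of class `pathway_tbl`, one row per pathway:
#'   `pathway`, `ordering` (site names joined by " -> "), `route` (genotype
#'   chain), `verdict` (`"favoured"`/`"disfavoured"`, `NA` if
#'   unevaluable), `first_block_step`, `first_block_genotype`,
#'   `blocking_traits`.  Attributes: `steps` (per step x trait deltas,
#'   tolerances and permitted flags; see [pathway_steps()]), `traits`,
#'   `n_accessible`.
#' @examples
#' cp <- classify_pathways(bm3_fixture(), traits = c("ddg", "ttf"))
#' cp
#' glance(cp)
#' @export
classify_pathways <- function(x, traits = NULL, k_sig = 1, abs_tol = 0) {
  stopifnot(inherits(x, "deconvolution"))
  traits <- traits %||% trait_names(x)
  unknown <- setdiff(traits, trait_names(x))
  if (length(unknown) > 0L) {
    abort(sprintf("trait(s) not in dataset: %s", paste(unknown, collapse = ", ")))
  }
  pw <- enumerate_pathways(length(sites(x)))
  lks <- lapply(setNames(traits, traits), trait_lookup, x = x)
  orients <- vapply(traits, trait_orientation, numeric(1), x = x)

  rows <- list()
  step_rows <- list()
  for (i in seq_len(nrow(pw))) {
    ordering <- pw$ordering[[i]]
    genos <- pathway_genotypes(ordering, sites(x))
    evaluable <- all(vapply(traits, function(tr) {
      all(genos %in% names(lks[[tr]]$mean))
    }, logical(1)))
    if (!evaluable) {
      rows[[i]] <- tibble(
        pathway = pw$pathway[i],
        ordering = paste(sites(x)[ordering], collapse = " -> "),
        route = paste(genos, collapse = " -> "),
        verdict = NA_character_, first_block_step = NA_integer_,
        first_block_genotype = NA_character_, blocking_traits = NA_character_
      )
      next
    }
    n_steps <- length(genos) - 1L
    permitted_step <- rep(TRUE, n_steps)
    block_traits <- vector("list", n_steps)
    for (tr in traits) {
      lk <- lks[[tr]]
      from <- genos[-length(genos)]
      to <- genos[-1]
      delta <- orients[[tr]] * (lk$mean[to] - lk$mean[from])
      step_sem <- sqrt(lk$sem[from]^2 + lk$sem[to]^2)
      tol <- pmax(k_sig * step_sem, abs_tol)
      ok <- delta >= -tol
      permitted_step <- permitted_step & ok
      for (s in which(!ok)) {
        block_traits[[s]] <- c(block_traits[[s]], tr)
      }
      step_rows[[length(step_rows) + 1L]] <- tibble(
        pathway = pw$pathway[i], step = seq_len(n_steps),
        from = unname(from), to = unname(to), trait = tr,
        delta = unname(delta), tolerance = unname(tol),
        permitted = unname(ok)
      )
    }
    first_block <- if (all(permitted_step)) NA_integer_ else
      min(which(!permitted_step))
    rows[[i]] <- tibble(
      pathway = pw$pathway[i],
      ordering = paste(sites(x)[ordering], collapse = " -> "),
      route = paste(genos, collapse = " -> "),
      verdict = if (is.na(first_block)) "favoured" else "disfavoured",
      first_block_step = first_block,
      first_block_genotype = if (is.na(first_block)) NA_character_ else
        genos[first_block + 1L],
      blocking_traits = if (is.na(first_block)) NA_character_ else
        paste(block_traits[[first_block]], collapse = ", ")
    )
  }
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    steps = dplyr::bind_rows(step_rows),
    traits = traits, k_sig = k_sig, abs_tol = abs_tol,
    n_accessible = sum(out$verdict == "favoured", na.rm = TRUE),
    class = c("pathway_tbl", class(tibble()))
  )
}

#' Evaluate a single pathway
#'
#' @param ordering Integer permutation of site indices (or character vector
#'   of site names in introduction order).
#' @inheritParams classify_pathways
#' @return One-row tibble as in [classify_pathways()].
#' @export
evaluate_pathway <- function(x, ordering, traits = NULL, k_sig = 1,
                             abs_tol = 0) {
  if (is.character(ordering)) ordering <- match(ordering, sites(x))
  stopifnot(!anyNA(ordering),
            identical(sort(as.integer(ordering)), seq_along(sites(x))))
  all_p <- classify_pathways(x, traits = traits, k_sig = k_sig,
                             abs_tol = abs_tol)
  target <- paste(sites(x)[ordering], collapse = " -> ")
  row <- all_p[all_p$ordering == target, ]
  attr(row, "steps") <- dplyr::filter(attr(all_p, "steps"),
                                      .data$pathway == row$pathway)
  row
}

#' @param p A `pathway_tbl`.
#' @rdname classify_pathways
#' @export
pathway_steps <- function(p) attr(p, "steps")

#' Fitness-pathway landscape grid
#'
#' Long-format trait values along every pathway: one row per (pathway,
#' step, trait), with the genotype occupying that step and its mean and
#' SEM.  Step 0 is the shared parent, step `n` the full variant; for a
#' complete dataset the grid has `(n + 1) * n!` rows per trait.  Suitable
#' for external surface plotting or [plot_landscape()].
#'
#' @inheritParams classify_pathways
#' @return A tibble: `pathway`, `step`, `genotype`, `trait`, `value`,
#'   `sem`.
#' @export
landscape_grid <- function(x, traits = NULL) {
  stopifnot(inherits(x, "deconvolution"))
  traits <- traits %||% trait_names(x)
  pw <- enumerate_pathways(length(sites(x)))
  grid <- pw |>
    dplyr::mutate(genotype = lapply(.data$ordering, pathway_genotypes,
                                    sites = sites(x))) |>
    dplyr::select("pathway", "genotype") |>
    tidyr::unnest_longer("genotype", indices_to = "step") |>
    dplyr::mutate(step = .data$step - 1L)
  grid <- dplyr::bind_rows(lapply(traits, function(tr) {
    dplyr::mutate(grid, trait = tr)
  }))
  grid |>
    dplyr::left_join(
      as_tibble(x)[c("genotype", "trait", "mean", "sem")],
      by = c("genotype", "trait")
    ) |>
    dplyr::rename(value = "mean") |>
    dplyr::select("pathway", "step", "genotype", "trait", "value", "sem")
}

#' @export
print.pathway_tbl <- function(x, ...) {
  cat(sprintf("<pathway classification> %d/%d accessible on trait(s) %s\n",
              attr(x, "n_accessible"), nrow(x),
              paste(attr(x, "traits"), collapse = ", ")))
  NextMethod()
}
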