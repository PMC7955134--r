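#' Enumerate combination splits
#'
#' A split expresses a multi-mutant genotype as the union of two or more
#' disjoint, non-empty mutation sets, e.g. `{R47I} + {T49I, Y51I} -> III`.
#' Epistasis is measured per split: the union's observed effect against the
#' sum of the parts' effects.
#'
#' Modes:
#' \describe{
#'   \item{`"standard"`}{all unordered pairs of disjoint non-empty mutation
#'     sets (binary splits of every achievable sub-genotype) plus, for
#'     `n_sites >= 3`, the all-singles split of the full genotype.  For
#'     `n_sites = 3` this gives the canonical 6 binary + 1 tertiary rows.}
#'   \item{`"binary_only"`}{the binary pairs only.}
#'   \item{`"all_kway"`}{every set partition (into >= 2 blocks) of every
#'     achievable sub-genotype with >= 2 mutations.}
#' }
#' Splits are returned in deterministic order: by union size, then union
#' bitmask, then number of parts, then parts.
#'
#' @param n_sites Number of mutation sites (>= 2).
#' @param mode Enumeration mode, see Details.
#' @return A tibble with columns `split` (id), `type` (`"B"` binary, `"T"`
#'   tertiary, `"<k>-way"` beyond), `parts` (list of lists of site-index
#'   vectors) and `union` (list of site-index vectors).
#' @examples
#' enumerate_splits(3)            # 7 splits: 6 binary + 1 tertiary
#' nrow(enumerate_splits(4))      # 26
#' @export
enumerate_splits <- function(n_sites,
                             mode = c("standard", "binary_only", "all_kway")) {
  mode <- match.arg(mode)
  if (n_sites < 2) abort("`n_sites` must be at least 2")
  full <- 2L^n_sites - 1L

  part_list <- list()
  if (mode %in% c("standard", "binary_only")) {
    for (a in 1:(full - 1L)) {
      for (b in (a + 1L):full) {
        if (bitwAnd(a, b) == 0L) {
          part_list[[length(part_list) + 1L]] <- list(a, b)
        }
      }
    }
    if (mode == "standard" && n_sites >= 3L) {
      part_list[[length(part_list) + 1L]] <-
        as.list(bitwShiftL(1L, seq_len(n_sites) - 1L))
    }
  } else {
    for (u in 1:full) {
      if (length(indices_from_mask(u, n_sites)) < 2L) next
      parts <- set_partitions(indices_from_mask(u, n_sites))
      for (p in parts) {
        if (length(p) >= 2L) {
          part_list[[length(part_list) + 1L]] <-
            lapply(p, mask_from_indices)
        }
      }
    }
  }

  canon <- lapply(part_list, function(ps) {
    ps[order(vapply(ps, as.numeric, numeric(1)))]
  })
  unions <- vapply(canon, function(ps) Reduce(bitwOr, ps), integer(1))
  usize <- vapply(unions, function(u) length(indices_from_mask(u, n_sites)),
                  integer(1))
  nparts <- lengths(canon)
  key <- vapply(canon, function(ps) {
    paste(vapply(ps, as.character, character(1)), collapse = "|")
  }, character(1))
  ord <- order(usize, unions, nparts, key)
  canon <- canon[ord][!duplicated(key[ord])]
  unions <- vapply(canon, function(ps) Reduce(bitwOr, ps), integer(1))
  nparts <- lengths(canon)

  tibble(
    split = seq_along(canon),
    type = dplyr::case_when(nparts == 2L ~ "B", nparts == 3L ~ "T",
                            TRUE ~ paste0(nparts, "-way")),
    parts = lapply(canon, function(ps) {
      lapply(ps, indices_from_mask, n = n_sites)
    }),
    union = lapply(unions, indices_from_mask, n = n_sites)
  )
}

## All set partitions of a vector (restricted growth strings).
set_partitions <- function(v) {
  n <- length(v)
  if (n == 0L) return(list())
  out <- list()
  recurse <- function(i, assign, k) {
    if (i > n) {
      blocks <- split(v, assign[seq_len(n)])
      out[[length(out) + 1L]] <<- unname(blocks)
      return(invisible())
    }
    for (b in seq_len(k + 1L)) {
      assign[i] <- b
      recurse(i + 1L, assign, max(k, b))
    }
  }
  recurse(1L, integer(n), 0L)
  out
}

#' Additive expectation of a mutation combination
#'
#' Under additivity the trait value of the combined genotype is the parent
#' value plus the sum of each part's effect relative to the parent:
#' `expected = f(parent) + sum_i (f(part_i) - f(parent))`.  The propagated
#' SEM is `sqrt(sum_i sem_i^2 + (k - 1)^2 * sem_parent^2)` for `k` parts
#' (the parent mean enters the expression `k - 1` times).
#'
#' @param x A [deconvolution()].
#' @param parts List of site-index vectors, or character vector of genotype
#'   labels, one per part.
#' @param trait Trait name.
#' @return One-row tibble: `expected`, `sem`.
#' @export
additive_expectation <- function(x, parts, trait) {
  st <- split_stats(x, normalize_parts(parts, sites(x)), trait,
                    need_union = FALSE)
  tibble(expected = st$expected, sem = st$expected_sem)
}

## Lean shared core for the additive model; `lk` may be a precomputed
## trait_lookup() to avoid repeated subsetting in analyze_epistasis().
split_stats <- function(x, parts, trait, need_union = TRUE, lk = NULL) {
  lk <- lk %||% trait_lookup(x, trait)
  sts <- sites(x)
  labels <- vapply(parts, label_from_indices, character(1), sites = sts)
  union_idx <- sort(unique(unlist(parts)))
  if (length(unlist(parts)) != length(union_idx)) {
    abort("parts of a split must be disjoint")
  }
  u_label <- label_from_indices(union_idx, sts)
  req <- c(parent_label(x), labels, if (need_union) u_label)
  absent <- setdiff(req, names(lk$mean))
  if (length(absent) > 0L) {
    abort(sprintf("genotype(s) not measured for trait %s: %s",
                  trait, paste(absent, collapse = ", ")))
  }
  k <- length(parts)
  f0 <- lk$mean[[parent_label(x)]]
  s0 <- lk$sem[[parent_label(x)]]
  expected <- f0 + sum(lk$mean[labels] - f0)
  expected_sem <- sqrt(sum(lk$sem[labels]^2) + (k - 1)^2 * s0^2)
  out <- list(labels = labels, u_label = u_label, f0 = f0, s0 = s0,
              w_parts = setNames(unname(lk$mean[labels] - f0), labels),
              part_sems = setNames(unname(lk$sem[labels]), labels),
              expected = expected, expected_sem = expected_sem)
  if (need_union) {
    out$observed <- lk$mean[[u_label]]
    out$observed_sem <- lk$sem[[u_label]]
    out$epsilon <- out$observed - expected
    out$epsilon_sem <- sqrt(out$observed_sem^2 + expected_sem^2)
  }
  out
}

#' Epistasis of one split on one trait
#'
#' The interaction magnitude is the deviation from additivity,
#' `epsilon = f(union) - expected`, on the trait's own scale, with
#' `sem(epsilon)^2 = sem(union)^2 + sem(expected)^2`.  Equivalently
#' `epsilon = w_union - sum_i w_i` where `w(g) = f(g) - f(parent)`.
#'
#' @inheritParams additive_expectation
#' @return One-row tibble with the split's effects (`w_parts`, list
#'   column), `expected`, `observed`, `epsilon` and their SEMs.  No class
#'   label is assigned; see [classify_epistasis()] / [analyze_epistasis()].
#' @export
epistasis_epsilon <- function(x, parts, trait) {
  st <- split_stats(x, normalize_parts(parts, sites(x)), trait)
  tibble::new_tibble(list(
    genotype = st$u_label,
    trait = trait,
    n_parts = length(st$labels),
    w_parts = list(st$w_parts),
    part_sems = list(st$part_sems),
    expected = st$expected,
    expected_sem = st$expected_sem,
    observed = st$observed,
    observed_sem = st$observed_sem,
    epsilon = st$epsilon,
    epsilon_sem = st$epsilon_sem
  ), nrow = 1L)
}

normalize_parts <- function(parts, sites) {
  if (is.character(parts)) {
    parts <- lapply(parts, function(lbl) {
      which(strsplit(lbl, "", fixed = TRUE)[[1]] != "-")
    })
  }
  if (!is.list(parts)) parts <- list(parts)
  if (any(lengths(parts) == 0L)) abort("parts must be non-empty")
  lapply(parts, as.integer)
}
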