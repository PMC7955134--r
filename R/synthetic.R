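#' Specify a synthetic trait landscape
#'
#' `trait_spec()` describes one trait of a synthetic deconvolution as an
#' additive-plus-interaction model: the value of genotype `g` is
#' `parent + sum_{i in g} additive[i] + sum_{S subseteq g, |S| >= 2}
#' interactions[S]`, and each replicate adds i.i.d. normal noise (optionally
#' heteroscedastic, sd proportional to the mean).  `landscape_spec()`
#' bundles trait specs with the site names and replicate count.
#'
#' @param name Trait name.
#' @param parent Parent (all-absent) trait value.
#' @param additive Numeric vector of per-site additive effects (length =
#'   number of sites).
#' @param interactions Named numeric vector of interaction coefficients;
#'   names are site subsets of size >= 2, written as indices or site names
#'   joined by `+` (e.g. `c("1+2" = 51)` or `c("T49I+Y51I" = 51)`).
#' @param sd Replicate noise standard deviation (>= 0).
#' @param noise `"constant"` (sd as given) or `"proportional"` (sd is
#'   `sd * |expected value|`).
#' @param units,higher_is_better,digits Trait metadata.
#' @return A `trait_spec` / `landscape_spec` list.
#' @examples
#' spec <- landscape_spec(
#'   sites = c("R47I", "T49I", "Y51I"),
#'   traits = trait_spec("ttf", parent = 11, additive = c(-4, 0, 10),
#'                       interactions = c("2+3" = 51, "1+2+3" = 80))
#' )
#' simulate_deconvolution(spec, seed = 1)
#' @export
trait_spec <- function(name, parent = 0, additive,
                       interactions = NULL, sd = 0,
                       noise = c("constant", "proportional"),
                       units = "", higher_is_better = TRUE, digits = 1L) {
  noise <- match.arg(noise)
  if (sd < 0) abort("`sd` must be non-negative")
  structure(
    list(name = name, parent = parent, additive = additive,
         interactions = interactions, sd = sd, noise = noise,
         units = units, higher_is_better = higher_is_better,
         digits = as.integer(digits)),
    class = "trait_spec"
  )
}

#' @param sites Character vector of site names.
#' @param traits A `trait_spec` or list of them.
#' @param n_rep Replicates per genotype-trait (>= 1).
#' @param temperature Kelvin.
#' @rdname trait_spec
#' @export
landscape_spec <- function(sites, traits, n_rep = 2L, temperature = 298.15) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  if (n_rep < 1) abort("`n_rep` must be at least 1")
  for (ts in traits) {
    if (length(ts$additive) != length(sites)) {
      abort(sprintf("trait %s: `additive` must have one effect per site",
                    ts$name))
    }
  }
  structure(
    list(sites = sites, traits = traits, n_rep = as.integer(n_rep),
         temperature = temperature),
    class = "landscape_spec"
  )
}

## Interaction subset name -> integer site indices.
parse_subset <- function(key, sites) {
  toks <- strsplit(key, "+", fixed = TRUE)[[1]]
  idx <- suppressWarnings(as.integer(toks))
  if (anyNA(idx)) idx <- match(toks, sites)
  if (anyNA(idx) || length(idx) < 2L) {
    abort(sprintf("bad interaction subset %s", sQuote(key)))
  }
  sort(unique(idx))
}

## Noise-free model value for the genotype given by `idx`.
trait_model_value <- function(ts, idx, sites) {
  val <- ts$parent + sum(ts$additive[idx])
  if (!is.null(ts$interactions)) {
    for (k in seq_along(ts$interactions)) {
      sub <- parse_subset(names(ts$interactions)[k], sites)
      if (all(sub %in% idx)) val <- val + ts$interactions[[k]]
    }
  }
  val
}

#' Simulate a deconvolution dataset
#'
#' Draws a complete `2^n` dataset from a [landscape_spec()]: every
#' genotype-trait pair gets `n_rep` replicates, each
#' `Normal(model value, sd)`.  A fixed `seed` makes the dataset fully
#' reproducible; the global random state is left untouched.
#'
#' @param spec A [landscape_spec()].
#' @param seed Integer seed, or `NULL` to use the current random state.
#' @return A [deconvolution()].
#' @export
simulate_deconvolution <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  n <- length(spec$sites)
  labels <- genotype_labels(spec$sites)
  idx_list <- lapply(0:(2^n - 1), indices_from_mask, n = n)
  draw <- function() {
    per_trait <- lapply(spec$traits, function(ts) {
      mu <- vapply(idx_list, trait_model_value, numeric(1),
                   ts = ts, sites = spec$sites)
      s <- if (ts$noise == "proportional") ts$sd * abs(mu) else ts$sd
      tibble(
        genotype = rep(labels, each = spec$n_rep),
        trait = ts$name,
        value = rnorm(length(labels) * spec$n_rep,
                      mean = rep(mu, each = spec$n_rep),
                      sd = rep(s, each = spec$n_rep, length.out =
                                 length(labels) * spec$n_rep))
      )
    })
    dplyr::bind_rows(per_trait)
  }
  data <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  info <- dplyr::bind_rows(lapply(spec$traits, function(ts) {
    tibble(trait = ts$name, units = ts$units,
           higher_is_better = ts$higher_is_better, kind = "measured",
           digits = ts$digits)
  }))
  deconvolution(data, sites = spec$sites, temperature = spec$temperature,
                trait_info = info)
}

#' Read a landscape spec from YAML
#'
#' The YAML mirrors [landscape_spec()]: top-level `sites`, `n_rep`,
#' `temperature`, and a `traits` list whose entries carry `name`,
#' `parent`, `additive`, optional `interactions` (mapping subset keys like
#' `"1+2"` to coefficients), `sd`, `noise`, `units`, `higher_is_better`,
#' `digits`.
#'
#' @param path YAML file path.
#' @return A [landscape_spec()].
#' @export
read_landscape_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$sites) || is.null(y$traits)) {
    abort("landscape spec needs `sites` and `traits`")
  }
  traits <- lapply(y$traits, function(t) {
    trait_spec(
      name = t$name, parent = t$parent %||% 0,
      additive = as.numeric(t$additive),
      interactions = if (!is.null(t$interactions)) {
        unlist(t$interactions)
      },
      sd = t$sd %||% 0, noise = t$noise %||% "constant",
      units = t$units %||% "",
      higher_is_better = t$higher_is_better %||% TRUE,
      digits = t$digits %||% 1L
    )
  })
  landscape_spec(sites = unlist(y$sites), traits = traits,
                 n_rep = y$n_rep %||% 2L,
                 temperature = y$temperature %||% 298.15)
}
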