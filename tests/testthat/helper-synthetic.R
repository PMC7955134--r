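# Shared builders for the test suite.  All fixtures are generated in code.

three_sites <- c("R47I", "T49I", "Y51I")

# Deconvolution from a named vector of per-genotype means for one trait.
decon_from_means <- function(means, sites = three_sites, sems = 0,
                             trait = "y", higher_is_better = TRUE) {
  sems <- rep_len(sems, length(means))
  deconvolution(
    tibble::tibble(genotype = names(means), trait = trait,
                   mean = unname(means), sem = sems, n = 2L),
    sites = sites,
    trait_info = tibble::tibble(trait = trait,
                                higher_is_better = higher_is_better)
  )
}

# Random complete single-trait dataset over n sites (zero SEM), as a named
# mean vector keyed by genotype label.
random_means <- function(n_sites, sites = paste0("s", seq_len(n_sites), "Z")) {
  labels <- genotype_labels(sites)
  stats::setNames(stats::rnorm(length(labels), sd = 5), labels)
}

# Positive affine transform of every mean/sem of one trait.
affine_transform <- function(x, trait, a, b) {
  stopifnot(a > 0)
  tab <- tibble::as_tibble(x)
  idx <- tab$trait == trait
  tab$mean[idx] <- a * tab$mean[idx] + b
  tab$sem[idx] <- a * tab$sem[idx]
  deconvolution(tab, sites = sites(x), parent = parent_label(x),
                temperature = assay_temperature(x),
                trait_info = trait_info(x))
}
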