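#' Genotype label nomenclature
#'
#' Genotypes in a deconvolution are written as fixed-width strings with one
#' character per mutation site: `-` marks an absent mutation and any other
#' single character (conventionally the introduced residue letter, e.g. `I`
#' for an X->Ile substitution) marks a present one.  For a three-site
#' deconvolution the parent is `---`, the singles are `I--`, `-I-`, `--I`,
#' and the full variant is `III`.
#'
#' `parse_genotype()` turns labels into per-site presence flags;
#' `format_genotype()` is its inverse; `genotype_labels()` enumerates all
#' `2^n` genotypes of a complete deconvolution.
#'
#' @param label Character vector of genotype labels, each of width
#'   `length(sites)`.
#' @param sites Character vector of ordered site names (e.g.
#'   `c("R47I", "T49I", "Y51I")`).  The presence mark of a site defaults to
#'   the last character of its name when that is alphanumeric, else `+`.
#' @param strict If `TRUE`, a presence character must equal the site's own
#'   mark; by default any non-`-` character is accepted.
#' @return `parse_genotype()`: a tibble with column `label` plus one logical
#'   column per site.  `format_genotype()`: a character vector of labels.
#'   `genotype_labels()`: character vector of all `2^n` labels, parent first.
#' @examples
#' sites <- c("R47I", "T49I", "Y51I")
#' parse_genotype(c("---", "I--", "III"), sites)
#' format_genotype(matrix(c(TRUE, FALSE, TRUE), nrow = 1), sites)
#' genotype_labels(sites)
#' @export
parse_genotype <- function(label, sites, strict = FALSE) {
  n <- length(sites)
  bad <- nchar(label) != n
  if (any(bad)) {
    abort(sprintf(
      "genotype label%s %s: expected width %d (one character per site)",
      if (sum(bad) > 1) "s" else "",
      paste(sQuote(label[bad]), collapse = ", "), n
    ))
  }
  chars <- matrix(unlist(strsplit(label, "", fixed = TRUE)),
                  ncol = n, byrow = TRUE)
  present <- chars != "-"
  if (strict) {
    marks <- matrix(site_marks(sites), nrow = nrow(chars), ncol = n,
                    byrow = TRUE)
    off <- present & (chars != marks)
    if (any(off)) {
      abort(sprintf(
        "genotype label %s uses mark %s where site %s expects %s",
        sQuote(label[which(off, arr.ind = TRUE)[1, 1]]),
        sQuote(chars[off][1]),
        sites[which(off, arr.ind = TRUE)[1, 2]],
        sQuote(site_marks(sites)[which(off, arr.ind = TRUE)[1, 2]])
      ))
    }
  }
  colnames(present) <- sites
  dplyr::bind_cols(tibble(label = label), as_tibble(present))
}

#' @param present Logical matrix (or data frame / single logical vector) with
#'   one column per site.
#' @rdname parse_genotype
#' @export
format_genotype <- function(present, sites) {
  if (is.data.frame(present)) present <- as.matrix(present[sites])
  if (is.vector(present)) present <- matrix(present, nrow = 1)
  stopifnot(is.logical(present), ncol(present) == length(sites))
  marks <- site_marks(sites)
  apply(present, 1L, function(p) {
    paste0(ifelse(p, marks, "-"), collapse = "")
  })
}

#' @rdname parse_genotype
#' @export
genotype_labels <- function(sites) {
  if (is.numeric(sites) && length(sites) == 1L) {
    sites <- paste0("S", seq_len(sites), "X")
  }
  n <- length(sites)
  masks <- 0:(2^n - 1)
  vapply(masks, function(m) label_from_mask(m, sites), character(1))
}

## Presence mark per site: last character of the site name when alphanumeric.
site_marks <- function(sites) {
  m <- substr(sites, nchar(sites), nchar(sites))
  ifelse(grepl("^[A-Za-z0-9]$", m), m, "+")
}

## Bitmask helpers: bit i (1-based site index) set iff site i present.
mask_from_indices <- function(idx) sum(bitwShiftL(1L, idx - 1L))

indices_from_mask <- function(mask, n) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
}

label_from_mask <- function(mask, sites) {
  n <- length(sites)
  p <- bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L
  paste0(ifelse(p, site_marks(sites), "-"), collapse = "")
}

mask_from_label <- function(label, sites) {
  p <- strsplit(label, "", fixed = TRUE)[[1]] != "-"
  mask_from_indices(which(p))
}

## Label for a set of site indices, e.g. c(2, 3) -> "-II".
label_from_indices <- function(idx, sites) {
  label_from_mask(mask_from_indices(idx), sites)
}
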