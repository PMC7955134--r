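#' Constraint-built P450 BM3 deconvolution example dataset
#'
#' An eight-genotype, eight-trait synthetic reference dataset for the
#' R47I/T49I/Y51I deconvolution of the testosterone-hydroxylating P450 BM3
#' variant "III" in the F87A background (parent `---`, full variant
#' `III`).  It is *not* measured data: every value is a frozen constant
#' constructed to satisfy, simultaneously, the characteristic published
#' whole-enzyme numbers for this system (the TTF series 11 -> 21 -> 72 ->
#' 158 along the Y51I-first route, 37% coupling efficiency for `-II` and
#' `III`, a 2beta-selectivity free energy of 5.6 kJ/mol for `III` with a
#' -3.45 kJ/mol additive expectation of the three singles) and the
#' interaction magnitudes they imply for the remaining genotypes.  Each
#' value carries a provenance tag:
#' \describe{
#'   \item{`anchored`}{equal to a characteristic published value.}
#'   \item{`solved`}{determined by inverting interaction identities
#'     against anchored values.}
#'   \item{`assumed`}{a documented free choice consistent with all
#'     constraints (notably the per-trait SEMs and the split of the
#'     -3.45 kJ/mol singles sum).}
#' }
#'
#' Traits: `conv` (substrate conversion, %), `sel` (2beta-selectivity, %
#' of all quantified products), `ddg` (2beta-selectivity as
#' RT*ln(p/(1-p)), kJ/mol, exactly consistent with `sel`), `ncr`
#' (leak-corrected NADPH consumption rate, 1/min; negative where the leak
#' exceeds consumption), `pfr` (product formation rate, 1/min), `ce`
#' (coupling efficiency, %), `ttn` (total turnover number), `ttf` (total
#' turnover frequency, 1/min).  All traits are oriented higher-is-better
#' (the evolution targets the 2beta product).  `n = 2` replicates per
#' value, temperature 298.15 K.
#'
#' @return A [deconvolution()] with a `provenance` attribute (tibble:
#'   `genotype`, `trait`, `provenance`, `note`), also available via
#'   `fixture_provenance()`.
#' @examples
#' fx <- bm3_fixture()
#' dplyr::filter(analyze_epistasis(fx, traits = "ddg"), type == "T")
#' @export
bm3_fixture <- function() {
  path <- system.file("extdata", "p450bm3_synthetic.csv",
                      package = "epiland", mustWork = TRUE)
  prov_path <- system.file("extdata", "p450bm3_synthetic_provenance.csv",
                           package = "epiland", mustWork = TRUE)
  meas <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prov <- readr::read_csv(prov_path, show_col_types = FALSE, progress = FALSE)
  info <- tibble(
    trait = c("conv", "sel", "ddg", "ncr", "pfr", "ce", "ttn", "ttf"),
    units = c("%", "%", "kJ/mol", "1/min", "1/min", "%", "", "1/min"),
    higher_is_better = TRUE,
    kind = c("measured", "measured", "derived", "measured", "measured",
             "measured", "measured", "measured"),
    digits = c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L)
  )
  x <- deconvolution(meas, sites = c("R47I", "T49I", "Y51I"),
                     parent = "---", temperature = 298.15,
                     trait_info = info)
  attr(x, "provenance") <- prov
  x
}

#' @param x A deconvolution returned by [bm3_fixture()].
#' @rdname bm3_fixture
#' @export
fixture_provenance <- function(x) attr(x, "provenance")
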