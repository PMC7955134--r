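test_that("selectivity converts to ddG by RT*ln(p/(1-p))", {
  expect_equal(selectivity_to_ddg(0.5, 298.15), 0)
  # frozen from direct evaluation of 8.314462618e-3 * 298.15 * log(p/(1-p))
  expect_equal(selectivity_to_ddg(0.94, 298.15), 6.820938, tolerance = 1e-6)
  expect_equal(selectivity_to_ddg(0.91, 298.15), 5.735402, tolerance = 1e-6)
  expect_error(selectivity_to_ddg(1), "bound")
  expect_error(selectivity_to_ddg(0), "bound")
  expect_equal(selectivity_to_ddg(1, clamp = 1e-4),
               selectivity_to_ddg(1 - 1e-4))
})

test_that("ddG transform is antisymmetric and strictly monotone", {
  p <- seq(0.01, 0.99, by = 0.01)
  d <- selectivity_to_ddg(p)
  expect_equal(d, -rev(selectivity_to_ddg(rev(1 - p))))
  expect_true(all(diff(d) > 0))
})

test_that("ddG delta-method SEM matches Monte-Carlo resampling", {
  cases <- list(c(p = 0.94, sem = 0.01), c(p = 0.7, sem = 0.02),
                c(p = 0.3, sem = 0.01))
  withr::with_seed(42, {
    for (cs in cases) {
      draws <- rnorm(1e5, cs[["p"]], cs[["sem"]])
      draws <- draws[draws > 0 & draws < 1]
      mc <- sd(selectivity_to_ddg(draws))
      expect_equal(selectivity_ddg_sem(cs[["p"]], cs[["sem"]]), mc,
                   tolerance = 0.1)
    }
  })
  expect_equal(selectivity_ddg_sem(0.94, 0.01, 298.15), 0.439531,
               tolerance = 1e-5)
})

test_that("kinetic trait transforms are mutually consistent", {
  expect_equal(compute_pfr(100, 0.37), 37)
  expect_equal(compute_pfr(0, 0.8), 0)
  expect_error(compute_pfr(100, 37), "fraction")
  expect_equal(compute_ce(37, 100), 0.37)
  expect_equal(compute_ce(100, 100), 1)
  expect_error(compute_ce(5, 0), "undefined")
  # ce o pfr is the identity for positive ncr
  ncr <- c(10, 50, 283)
  ce <- c(0.15, 0.37, 0.9)
  expect_equal(compute_ce(compute_pfr(ncr, ce), ncr), ce)
  expect_equal(compute_ttf(1580, 10), 158)
  expect_equal(compute_ttf(0, 5), 0)
  expect_error(compute_ttf(10, 0), "positive")
})

test_that("NADPH leak correction subtracts and flags, never clamps", {
  expect_equal(correct_ncr(120, 20), 100)
  expect_equal(correct_ncr(20, 20), 0)
  expect_warning(out <- correct_ncr(15, 20), "leak exceeds")
  expect_equal(out, -5)
})

test_that("derive_trait computes per replicate when replicates exist", {
  reps <- tibble::tibble(
    genotype = rep(genotype_labels(c("aA", "bB")), each = 2),
    trait = "ncr",
    value = c(100, 104, 50, 54, 80, 84, 200, 204)
  )
  ce_reps <- tibble::tibble(
    genotype = rep(genotype_labels(c("aA", "bB")), each = 2),
    trait = "ce",
    value = c(0.30, 0.34, 0.2, 0.24, 0.4, 0.44, 0.36, 0.40)
  )
  d <- deconvolution(dplyr::bind_rows(reps, ce_reps), sites = c("aA", "bB"))
  d2 <- derive_trait(d, "pfr", formula = "pfr", inputs = c("ncr", "ce"))
  got <- d2[d2$trait == "pfr" & d2$genotype == "--", ]
  # brute force: per-replicate products
  prods <- c(100 * 0.30, 104 * 0.34)
  expect_equal(got$mean, mean(prods))
  expect_equal(got$sem, sd(prods) / sqrt(2))
  info <- trait_info(d2)
  expect_equal(info$kind[info$trait == "pfr"], "derived")
})

test_that("derive_trait falls back to delta-method SEM on aggregated data", {
  labels <- genotype_labels(c("aA", "bB"))
  d <- deconvolution(
    tibble::tibble(genotype = rep(labels, 2),
                   trait = rep(c("ncr", "ce"), each = 4),
                   mean = c(100, 50, 80, 200, 0.3, 0.2, 0.4, 0.37),
                   sem = c(4, 2, 3, 5, 0.01, 0.01, 0.02, 0.01)),
    sites = c("aA", "bB")
  )
  d2 <- derive_trait(d, "pfr", formula = "pfr", inputs = c("ncr", "ce"))
  got <- d2[d2$trait == "pfr", ]
  expect_equal(got$mean, c(30, 10, 32, 74))
  # product rule: sem^2 = (ce*sem_ncr)^2 + (ncr*sem_ce)^2
  expect_equal(got$sem[1], sqrt((0.3 * 4)^2 + (100 * 0.01)^2),
               tolerance = 1e-4)
  # missing input trait: skipped with a warning, dataset unchanged
  expect_warning(d3 <- derive_trait(d, "ttf", formula = "ttf",
                                    inputs = "ttn", elapsed = 10),
                 "skipped")
  expect_identical(tibble::as_tibble(d3), tibble::as_tibble(d))
  # no silent overwrite
  expect_error(derive_trait(d2, "pfr", formula = "pfr"), "overwrite")
})

test_that("derive_trait ddg handles percent selectivities", {
  labels <- genotype_labels(c("aA", "bB"))
  d <- deconvolution(
    tibble::tibble(genotype = labels, trait = "sel",
                   mean = c(50, 94, 30, 91), sem = 1),
    sites = c("aA", "bB"),
    trait_info = tibble::tibble(trait = "sel", units = "%")
  )
  d2 <- derive_trait(d, "ddg", formula = "ddg", inputs = "sel")
  got <- d2[d2$trait == "ddg", ]
  expect_equal(got$mean, selectivity_to_ddg(c(0.5, 0.94, 0.3, 0.91)))
  expect_equal(got$sem, selectivity_ddg_sem(c(0.5, 0.94, 0.3, 0.91), 0.01),
               tolerance = 1e-4)
})
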