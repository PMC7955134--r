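test_that("pathway enumeration yields n! lexicographic orderings", {
  expect_equal(nrow(enumerate_pathways(3)), 6L)
  expect_equal(nrow(enumerate_pathways(1)), 1L)
  expect_equal(nrow(enumerate_pathways(4)), 24L)
  p3 <- enumerate_pathways(3)$ordering
  expect_equal(p3[[1]], c(1L, 2L, 3L))
  expect_equal(p3[[6]], c(3L, 2L, 1L))
  expect_false(anyDuplicated(vapply(p3, paste, character(1),
                                    collapse = ",")) > 0)
})

test_that("a strictly increasing trait leaves every pathway favoured", {
  labels <- genotype_labels(three_sites)
  sizes <- nchar(gsub("-", "", labels))
  d <- decon_from_means(setNames(10 * sizes + seq_along(labels) / 10, labels))
  cp <- classify_pathways(d, traits = "y")
  expect_equal(cp$verdict, rep("favoured", 6))
  expect_true(all(is.na(cp$first_block_step)))
  expect_equal(attr(cp, "n_accessible"), 6L)
})

test_that("a valley genotype on all routes blocks every pathway", {
  labels <- genotype_labels(three_sites)
  means <- setNames(nchar(gsub("-", "", labels)) * 10, labels)
  means[c("I--", "-I-", "--I")] <- -50 # every first step collapses
  d <- decon_from_means(means)
  cp <- classify_pathways(d, traits = "y", abs_tol = 0)
  expect_equal(attr(cp, "n_accessible"), 0L)
  expect_equal(cp$first_block_step, rep(1L, 6))
  # brute-force local-minimum scan agrees at zero tolerance
  brute <- vapply(enumerate_pathways(3)$ordering, function(ord) {
    genos <- c("---", vapply(seq_along(ord), function(k) {
      format_genotype(
        matrix(seq_len(3) %in% ord[seq_len(k)], nrow = 1), three_sites
      )
    }, character(1)))
    all(diff(means[genos]) >= 0)
  }, logical(1))
  expect_equal(cp$verdict == "favoured", unname(brute))
})

test_that("infinite tolerance admits every pathway; ties are permitted", {
  labels <- genotype_labels(three_sites)
  withr::with_seed(5, {
    d <- decon_from_means(setNames(rnorm(8, sd = 20), labels))
  })
  cp <- classify_pathways(d, traits = "y", abs_tol = Inf)
  expect_equal(attr(cp, "n_accessible"), 6L)
  # an exactly flat step does not block
  means <- setNames(rep(1, 8), labels)
  cp0 <- classify_pathways(decon_from_means(means), traits = "y")
  expect_equal(attr(cp0, "n_accessible"), 6L)
})

test_that("multi-trait accessibility is the intersection of single traits", {
  labels <- genotype_labels(three_sites)
  withr::with_seed(31, {
    for (rep in 1:20) {
      d <- deconvolution(
        tibble::tibble(
          genotype = rep(labels, 2),
          trait = rep(c("a", "b"), each = 8),
          mean = rnorm(16, sd = 10), sem = 0, n = 2L
        ),
        sites = three_sites
      )
      fa <- classify_pathways(d, "a")$verdict == "favoured"
      fb <- classify_pathways(d, "b")$verdict == "favoured"
      fab <- classify_pathways(d, c("a", "b"))$verdict == "favoured"
      expect_equal(fab, fa & fb)
    }
  })
})

test_that("verdicts are invariant under positive affine trait rescaling", {
  labels <- genotype_labels(three_sites)
  withr::with_seed(17, {
    for (rep in 1:25) {
      d <- decon_from_means(setNames(rnorm(8, sd = 5), labels),
                            sems = abs(rnorm(8, sd = 0.5)))
      a <- exp(rnorm(1))
      b <- rnorm(1, sd = 10)
      d2 <- affine_transform(d, "y", a, b)
      v1 <- classify_pathways(d, "y")
      v2 <- classify_pathways(d2, "y")
      expect_equal(v2$verdict, v1$verdict)
      expect_equal(v2$first_block_step, v1$first_block_step)
    }
  })
})

test_that("orientation flips the permitted direction for lower-is-better traits", {
  labels <- genotype_labels(three_sites)
  sizes <- nchar(gsub("-", "", labels))
  means <- setNames(as.numeric(10 * sizes), labels)
  worse_up <- decon_from_means(means, higher_is_better = FALSE)
  cp <- classify_pathways(worse_up, traits = "y")
  expect_equal(attr(cp, "n_accessible"), 0L)
})

test_that("landscape grid is long-format, parent-shared and complete", {
  fx <- bm3_fixture()
  grid <- landscape_grid(fx, traits = "ttf")
  expect_equal(nrow(grid), 4 * 6) # (n+1) * n! rows per trait
  p6 <- grid[grid$pathway == 6, ]
  expect_equal(p6$value, c(11, 21, 72, 158))
  expect_equal(p6$genotype, c("---", "--I", "-II", "III"))
  parent_rows <- grid[grid$step == 0, ]
  expect_equal(unique(parent_rows$genotype), "---")
  expect_equal(unique(parent_rows$value), 11)
  # grid values are exactly the dataset means
  m <- tibble::as_tibble(fx)
  expect_equal(
    grid$value,
    m$mean[match(paste(grid$genotype, "ttf"), paste(m$genotype, m$trait))]
  )
})

test_that("unmeasured genotypes mark pathways unevaluable", {
  labels <- setdiff(genotype_labels(three_sites), "II-")
  d <- decon_from_means(setNames(seq_along(labels), labels))
  cp <- classify_pathways(d, "y")
  expect_equal(sum(is.na(cp$verdict)), 2L) # orderings passing through II-
  ev <- evaluate_pathway(d, c(3L, 2L, 1L), "y")
  expect_equal(ev$verdict, "favoured")
})
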