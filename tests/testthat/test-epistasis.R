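test_that("split enumeration matches brute force over disjoint subset pairs", {
  s3 <- enumerate_splits(3)
  expect_equal(nrow(s3), 7L)
  expect_equal(s3$type, c(rep("B", 3), rep("B", 3), "T"))
  expect_equal(nrow(enumerate_splits(2)), 1L)
  expect_error(enumerate_splits(1), "at least 2")

  # brute-force oracle: unordered pairs of disjoint non-empty subsets
  brute_pairs <- function(n) {
    cnt <- 0L
    for (a in 1:(2^n - 1)) {
      for (b in 1:(2^n - 1)) {
        if (a < b && bitwAnd(a, b) == 0) cnt <- cnt + 1L
      }
    }
    cnt
  }
  for (n in 2:5) {
    expect_equal(nrow(enumerate_splits(n, "binary_only")), brute_pairs(n))
    expect_equal(nrow(enumerate_splits(n, "standard")),
                 brute_pairs(n) + (n >= 3))
  }
  expect_equal(nrow(enumerate_splits(4)), 26L)

  # deterministic, duplicate-free, ordered by union size
  s4 <- enumerate_splits(4)
  keys <- vapply(s4$parts, function(ps) {
    paste(vapply(ps, paste, character(1), collapse = ","), collapse = "|")
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_true(!is.unsorted(lengths(s4$union)))
  # parts are disjoint and union is their union
  for (i in seq_len(nrow(s4))) {
    flat <- unlist(s4$parts[[i]])
    expect_false(anyDuplicated(flat) > 0)
    expect_equal(sort(flat), s4$union[[i]])
  }
})

test_that("all_kway enumerates set partitions of every sub-genotype", {
  # n=3: three 2-subsets with 1 partition each + 4 partitions of the full set
  expect_equal(nrow(enumerate_splits(3, "all_kway")), 7L)
  # n=4: six 2-subsets (1) + four 3-subsets (4) + full set (B4 - 1 = 14)
  expect_equal(nrow(enumerate_splits(4, "all_kway")), 6 + 16 + 14)
})

test_that("additive expectation is parent plus summed effects, SEM propagated", {
  means <- c("---" = 10, "I--" = 12, "-I-" = 7, "--I" = 15, "II-" = 0,
             "I-I" = 0, "-II" = 0, "III" = 0)
  sems <- c(0.5, 0.3, 0.4, 0.2, 0, 0, 0, 0)
  d <- decon_from_means(means, sems = sems)
  e <- additive_expectation(d, list(1L, 2L, 3L), "y")
  expect_equal(e$expected, 10 + 2 - 3 + 5)
  expect_equal(e$sem, sqrt(0.3^2 + 0.4^2 + 0.2^2 + 4 * 0.5^2))
  # identity case: a single part's expectation is that part itself
  e1 <- additive_expectation(d, list(2L), "y")
  expect_equal(e1$expected, 7)
  expect_equal(e1$sem, 0.4)
  expect_error(additive_expectation(decon_from_means(means[1:4]),
                                    list(c(1L, 2L)), "y"),
               "not measured")
})

test_that("epsilon reproduces the turnover-frequency worked case", {
  means <- c("---" = 11, "-I-" = 11, "--I" = 21, "-II" = 72,
             "I--" = 0, "II-" = 0, "I-I" = 0, "III" = 0)
  d <- decon_from_means(means)
  eps <- epistasis_epsilon(d, list(2L, 3L), "y")
  expect_equal(eps$epsilon, 72 - 11 - 21 + 11) # 51
  expect_equal(eps$observed, 72)
  expect_equal(eps$genotype, "-II")
})

test_that("epsilon is symmetric under part permutation and zero for additive data", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      sites <- paste0("q", 1:3, "W")
      means <- random_means(3, sites)
      d <- decon_from_means(means, sites = sites)
      e1 <- epistasis_epsilon(d, list(1L, c(2L, 3L)), "y")
      e2 <- epistasis_epsilon(d, list(c(2L, 3L), 1L), "y")
      expect_equal(e1$epsilon, e2$epsilon)
    }
  })
  # zero-noise additive landscape: epsilon vanishes for every split
  spec <- landscape_spec(three_sites,
                         trait_spec("y", parent = 3,
                                    additive = c(1, -2, 5), sd = 0))
  d <- simulate_deconvolution(spec, seed = 1)
  res <- analyze_epistasis(d)
  expect_equal(res$epsilon, rep(0, 7))
  expect_true(all(res$label == "ADD"))
})

test_that("epsilon obeys the nested decomposition identity on random data", {
  # eps(A,B,C) = eps(A, B+C) + eps(B, C), brute-force checked
  check_identity <- function(n_sites, split_lhs, split_a, split_b, n_rep) {
    sites <- paste0("m", seq_len(n_sites), "F")
    lhs <- numeric(n_rep)
    rhs <- numeric(n_rep)
    for (rep in seq_len(n_rep)) {
      d <- decon_from_means(random_means(n_sites, sites), sites = sites)
      lhs[rep] <- epistasis_epsilon(d, split_lhs, "y")$epsilon
      rhs[rep] <- epistasis_epsilon(d, split_a, "y")$epsilon +
        epistasis_epsilon(d, split_b, "y")$epsilon
    }
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  withr::with_seed(11, {
    check_identity(3, list(1L, 2L, 3L), list(1L, c(2L, 3L)), list(2L, 3L),
                   500)
    check_identity(4, list(1L, 2L, c(3L, 4L)), list(1L, c(2L, 3L, 4L)),
                   list(2L, c(3L, 4L)), 500)
  })
})

test_that("propagated epsilon SEM matches Monte-Carlo resampling", {
  means <- c("---" = 10, "I--" = 12, "-I-" = 7, "--I" = 15, "II-" = 11,
             "I-I" = 14, "-II" = 13, "III" = 20)
  sems <- c(0.4, 0.3, 0.5, 0.2, 0.3, 0.25, 0.35, 0.3)
  d <- decon_from_means(means, sems = sems)
  for (parts in list(list(1L, 2L), list(1L, 2L, 3L), list(c(1L, 2L), 3L))) {
    eps <- epistasis_epsilon(d, parts, "y")
    labels <- names(eps$w_parts[[1]])
    u <- eps$genotype
    mc <- withr::with_seed(23, {
      draw <- function(g) rnorm(1e5, means[[g]], sems[[which(names(means) == g)]])
      f0 <- draw("---")
      k <- length(labels)
      exp_draw <- f0
      for (lb in labels) exp_draw <- exp_draw + (draw(lb) - f0)
      sd(draw(u) - exp_draw)
    })
    expect_equal(eps$epsilon_sem, mc, tolerance = 0.1)
  }
})

test_that("class summaries count labels with integer percentages", {
  res <- tibble::tibble(trait = "x",
                        label = c(rep("+SE", 6), "+ME"))
  s <- summarize_epistasis(res)
  expect_equal(s$pct[s$label == "+SE"], 86L)
  expect_equal(s$pct[s$label == "+ME"], 14L)
  s1 <- summarize_epistasis(tibble::tibble(trait = "x", label = "ADD"))
  expect_equal(s1$pct, 100L)
  s2 <- summarize_epistasis(tibble::tibble(
    trait = "x", label = c(rep("+SE", 5), "-SE", "+RSE")
  ))
  pos <- sum(s2$n[s2$sign == "+"])
  neg <- sum(s2$n[s2$sign == "-"])
  expect_equal(round(100 * pos / 7), 86)
  expect_equal(round(100 * neg / 7), 14)
})

test_that("incomplete datasets skip exactly the unevaluable splits", {
  labels <- setdiff(genotype_labels(three_sites), "I-I")
  d <- decon_from_means(setNames(seq_along(labels), labels))
  res <- analyze_epistasis(d)
  sk <- attr(res, "skipped")
  # splits needing I-I: its own binary split and the (I-I, -I-) split of III
  expect_equal(nrow(sk), 2L)
  expect_true(all(grepl("I-I", sk$reason)))
  expect_equal(nrow(res), 5L)
})
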