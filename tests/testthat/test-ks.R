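test_that("KS statistic matches hand values and edge cases", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2), c(10, 11)), 1)
  expect_equal(ks_statistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
})

test_that("KS statistic equals brute-force ECDF comparison with ties", {
  set.seed(41)
  for (i in 1:30) {
    n1 <- sample(1:200, 1); n2 <- sample(1:200, 1)
    a <- sample(0:30, n1, replace = TRUE)   # heavy ties
    b <- sample(0:30, n2, replace = TRUE) + sample(c(0, 5), n2, TRUE)
    expect_equal(ks_statistic(a, b), ks_bruteforce(a, b),
                 tolerance = 1e-12)
  }
})

test_that("KS statistic and p-value agree with the stats oracle", {
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(150); b <- rnorm(120, mean = 0.3)  # continuous, no ties
    kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    D <- ks_statistic(a, b)
    expect_equal(D, unname(kt$statistic), tolerance = 1e-12)
    # the stats C routine truncates its series at tol = 1e-6; allow that
    expect_equal(ks_pvalue(D, length(a), length(b)), kt$p.value,
                 tolerance = 1e-4)
  }
})

test_that("p-value limits and monotonicity", {
  expect_equal(ks_pvalue(0, 10, 10), 1)
  expect_lt(ks_pvalue(1, 1000, 1000), 1e-6)
  p <- vapply(seq(0, 1, by = 0.02), function(D) ks_pvalue(D, 200, 300), 0)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("pooled distributions pool pixels order-invariantly", {
  imgs <- small_dataset(3, 3, seed = 43)$images
  d1 <- pooled_ecdf(imgs)
  d2 <- pooled_ecdf(rev(imgs))
  expect_identical(d1$values, d2$values)
  expect_equal(d1$n, 6 * 32 * 32)
  expect_error(pooled_ecdf(list()), "empty")
})

test_that("images are assigned to the closer group distribution", {
  c0 <- pooled_ecdf(lapply(1:3, function(s) generate_texture(
    small_spec(mean = 1901.5, sigma = 251.1, beta = 2.6, seed = s))),
    group = "Control")
  c1 <- pooled_ecdf(lapply(4:6, function(s) generate_texture(
    small_spec(seed = s))), group = "Case")
  probe <- generate_texture(
    small_spec(mean = 1901.5, sigma = 251.1, beta = 2.6, seed = 9))
  d <- classify_image(probe, c0, c1)
  expect_identical(d$predicted, "Control")
  expect_lt(d$D0, d$D1)
})

test_that("an image identical to its pool has zero distance, no rejection", {
  img <- generate_texture(small_spec(seed = 44))
  c0 <- pooled_ecdf(list(img), group = "Control")
  far <- pooled_ecdf(list(generate_texture(
    small_spec(mean = 8000, sigma = 100, seed = 45))), group = "Case")
  d <- classify_image(img, c0, far)
  expect_equal(d$D0, 0)
  expect_identical(d$predicted, "Control")
  expect_false(d$rejected)
  expect_equal(d$p0, 1)
})

test_that("an image from a third distribution is rejected", {
  c0 <- pooled_ecdf(lapply(1:2, function(s) generate_texture(
    small_spec(mean = 1901.5, sigma = 251.1, beta = 2.6, seed = s))),
    group = "Control")
  c1 <- pooled_ecdf(lapply(3:4, function(s) generate_texture(
    small_spec(seed = s))), group = "Case")
  alien <- generate_texture(small_spec(mean = 8000, sigma = 150, seed = 5))
  d <- classify_image(alien, c0, c1, alpha = 0.05)
  expect_true(d$rejected)
  expect_lt(d$p0, 0.05)
  expect_lt(d$p1, 0.05)
})

test_that("ties in the minimum distance go to Control", {
  img <- generate_texture(small_spec(seed = 46))
  pool <- pooled_ecdf(list(img), group = "Control")
  pool2 <- pool; pool2$group <- "Case"
  expect_message(d <- classify_image(img, pool, pool2), "tie")
  expect_identical(d$predicted, "Control")
})

test_that("baseline evaluation separates disjoint-brightness classes", {
  ds <- small_dataset(4, 4, seed = 47, case_mean = 1500,
                      control_mean = 8000)
  res <- evaluate_ks_baseline(ds)
  expect_equal(res$per_compartment$accuracy, 100)
  expect_equal(nrow(res$decisions), 8L)
  # accuracy + error = 100 by construction
  err <- 100 * mean(res$decisions$predicted != res$decisions$true)
  expect_equal(res$per_compartment$accuracy + err, 100)
})

test_that("identical class generators give chance-level accuracy", {
  spec <- small_spec(size = c(16L, 16L))
  ds <- generate_dataset(20, 20, case_spec = spec, control_spec = spec,
                         seed = 48)
  res <- evaluate_ks_baseline(ds)
  expect_gte(res$per_compartment$accuracy, 30)
  expect_lte(res$per_compartment$accuracy, 70)
})

test_that("baseline refuses groups that are too small", {
  ds <- small_dataset(1, 4, seed = 49)
  expect_error(evaluate_ks_baseline(ds), "at least 2")
})
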