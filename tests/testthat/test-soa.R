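test_that("tucker congruence satisfies its closed forms", {
  x <- c(0.8, 0.7, 0.6, 0.5)
  expect_equal(tucker_congruence(x, x), 1)
  expect_equal(tucker_congruence(x, -x), -1)
  expect_equal(tucker_congruence(c(1, 0, 0, 0), c(0, 1, 0, 0)), 0)
  expect_error(tucker_congruence(x, c(0, 0, 0, 0)), "all zero")
  expect_error(tucker_congruence(x, x[1:3]), "equal length")
})

test_that("congruence is scale-invariant up to sign on random vector pairs", {
  set.seed(101)
  for (i in 1:1000) {
    k <- sample(2:8, 1)
    x <- stats::rnorm(k); y <- stats::rnorm(k)
    a <- stats::runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    b <- stats::runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    expect_equal(tucker_congruence(a * x, b * y),
                 sign(a * b) * tucker_congruence(x, y), tolerance = 1e-12)
  }
})

test_that("weighted sum scores follow their arithmetic definition", {
  rm <- synth_responses(n = 10, seed = 13)
  # unit loadings: plain item sum
  ws <- weighted_sum_score(rm, rep(1, 4))
  expect_equal(ws[, "P"], rowSums(rm[, , "P"]))
  # all-100 responses with loadings 0.5 each -> 200
  all100 <- response_matrix(array(100, dim = c(3, 4, 2),
                                  dimnames = list(NULL, NULL, c("B", "P"))))
  expect_true(all(weighted_sum_score(all100, rep(0.5, 4)) == 200))
  expect_true(all(weighted_sum_score(rm, rep(0, 4)) == 0))
  expect_error(weighted_sum_score(rm, rep(1, 3)), "length")
  # linearity in responses and loadings
  l1 <- c(0.9, 0.8, 0.7, 0.6); l2 <- c(0.1, 0.3, 0.2, 0.4)
  expect_equal(weighted_sum_score(rm, l1 + l2),
               weighted_sum_score(rm, l1) + weighted_sum_score(rm, l2))
})

test_that("loadings carry a positive-sum sign convention and name zero-variance items", {
  rm <- synth_responses(n = 50, seed = 17)
  l <- pca_loadings(rm)
  expect_gt(sum(l), 0)
  vals <- unclass(rm)
  vals[, 2, ] <- 50  # flatten item2
  expect_error(pca_loadings(response_matrix(vals)), "item2")
})

test_that("a symmetric one-factor model yields near-equal loadings at n = 500", {
  rm <- synth_responses(n = 500, loadings = rep(0.75, 4), seed = 23)
  l <- pca_loadings(rm)
  expect_lt(diff(range(l)), 0.05)
})

test_that("true loadings are recovered from synthetic responses (phi >= 0.95)", {
  truth <- c(0.8, 0.75, 0.7, 0.65)
  rm <- synth_responses(n = 200, loadings = truth, noise_sd = 10, seed = 29)
  est <- pca_loadings(rm)
  expect_gte(tucker_congruence(truth, est), 0.95)
})

test_that("condition-general and condition-specific loadings agree under invariance", {
  rm <- synth_responses(n = 500, seed = 31)
  phi <- tucker_congruence(pca_loadings(rm), pca_loadings(rm, "P"))
  expect_gte(phi, 0.99)
  inv <- invariance_check(rm)
  expect_true(all(inv$phi >= 0.95))
  # benchmark flags are optional and report-only by default
  expect_null(inv$pass)
  expect_true(all(invariance_check(rm, benchmark = 0.85)$pass))
})

test_that("an invariance-violating condition gets the strictly lowest phi", {
  truth <- c(0.9, 0.8, 0.3, 0.2)
  rm <- synth_responses(n = 500, loadings = truth, seed = 37)
  vals <- unclass(rm)
  bad <- synth_responses(n = 500, loadings = rev(truth), seed = 38)
  vals[, , "E"] <- unclass(bad)[, , "E"]   # permuted loading pattern in E
  rm2 <- response_matrix(vals)
  inv <- invariance_check(rm2)
  expect_equal(inv$condition[which.min(inv$phi)], "E")
  expect_lt(min(inv$phi), sort(inv$phi)[2])
})

test_that("a single-condition matrix is congruent with itself by construction", {
  rm <- synth_responses(n = 100, condition_means = c(PE = 60), seed = 41)
  inv <- invariance_check(rm)
  expect_equal(inv$phi, 1, tolerance = 1e-12)
})

test_that("synthetic responses are clamped, seeded, and recover the condition ordering", {
  a <- synth_responses(n = 50, seed = 43)
  b <- synth_responses(n = 50, seed = 43)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 100))
  big <- synth_responses(n = 200, seed = 47)
  means <- colMeans(weighted_sum_score(big, pca_loadings(big)))
  expect_true(means[["B"]] < means[["P"]])
  expect_true(means[["P"]] < means[["E"]])
  expect_true(means[["E"]] <= means[["PE"]])
})

test_that("long-format response CSVs round-trip", {
  rm <- synth_responses(n = 12, seed = 53)
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(rm, f)
  back <- read_responses(f)
  expect_equal(unclass(back), unclass(rm), tolerance = 1e-9)
  # header is the documented long schema
  expect_equal(names(utils::read.csv(f, nrows = 1)),
               c("participant", "condition", "item", "value"))
  # missing columns are format errors
  df <- utils::read.csv(f); df$item <- NULL
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_responses(f2), class = "mirror_format_error")
})
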