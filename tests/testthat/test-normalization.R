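test_that("identical covariates leave values unchanged (zero adjustment)", {
  vals <- c(8, 9, 10, 11, 12, 13)
  groups <- rep(c("GF", "SPF"), each = 3)
  expect_warning(
    fit <- ancova_adjust(vals, data.frame(lean = rep(20, 6)), groups),
    "degenerate")
  expect_equal(fit$adjusted, vals)
})

test_that("the two-mouse hand example adjusts both values to 13", {
  # value = 2 + 1 * lean, lean = {10, 12}: grand mean 11, prediction 13,
  # residuals 0, so both adjusted values are 13 (exact least squares)
  fit <- ancova_adjust(c(12, 14), data.frame(lean = c(10, 12)), c("A", "A"))
  expect_equal(fit$adjusted, c(13, 13))
  expect_equal(unname(fit$grand_means), 11)
  expect_equal(fit$residuals, c(0, 0), tolerance = 1e-12)
})

test_that("adjusted group contrasts equal ANCOVA adjusted means (closed form)", {
  # 3 mice, one covariate: solve the normal equations by hand as the oracle
  lean <- c(18, 20, 22)
  vals <- c(8.0, 9.5, 10.4)
  groups <- c("OLIGO", "OLIGO", "SPF")
  expect_warning(
    fit <- ancova_adjust(vals, data.frame(lean = lean), groups),
    "single mouse")
  # oracle: X = [1, lean, I(SPF)], beta = (X'X)^-1 X'y
  x <- cbind(1, lean, c(0, 0, 1))
  beta <- solve(t(x) %*% x, t(x) %*% vals)
  resid <- as.numeric(vals - x %*% beta)
  pred <- as.numeric(cbind(1, mean(lean), c(0, 0, 1)) %*% beta)
  expect_equal(fit$adjusted, resid + pred)
})

test_that("adjustment is invariant to shifting a covariate by a constant", {
  set.seed(1)
  lean <- rnorm(30, 20, 1.5)
  fat <- rnorm(30, 0.8, 0.2)
  vals <- 1 + 0.4 * lean + 0.6 * fat + rnorm(30, 0, 0.3)
  groups <- rep(c("GF", "OLIGO", "SPF"), each = 10)
  f1 <- ancova_adjust(vals, data.frame(lean = lean, fat = fat), groups)
  f2 <- ancova_adjust(vals, data.frame(lean = lean + 100, fat = fat), groups)
  expect_equal(f2$adjusted, f1$adjusted, tolerance = 1e-9)
  expect_equal(mean(f1$residuals), 0, tolerance = 1e-10)
})

test_that("collinear covariates error naming the pair; n = 1 groups warn", {
  lean <- c(18, 19, 20, 21, 22, 23)
  expect_error(
    ancova_adjust(1:6, data.frame(a = lean, b = 2 * lean),
                  rep(c("GF", "SPF"), 3)),
    "collinear.*a.*b")
  expect_warning(
    ancova_adjust(c(1, 2, 3, 4), data.frame(x = c(1, 2, 3, 4)),
                  c("GF", "GF", "GF", "SPF")),
    "single mouse")
})

test_that("hydrogen adjustment uses cecal mass and excludes germ-free mice", {
  set.seed(2)
  cecal <- c(rep(3, 4), rnorm(4, 1.5, 0.2), rnorm(4, 0.5, 0.1))
  groups <- rep(c("GF", "OLIGO", "SPF"), each = 4)
  h2 <- c(rep(0, 4), 20 * cecal[5:8] + rnorm(4, 0, 1),
          10 * cecal[9:12] + rnorm(4, 0, 1))
  fit <- adjust_hydrogen(h2, cecal, groups)
  expect_equal(length(fit$adjusted), 8)            # GF not fitted
  expect_false("GF" %in% levels(fit$groups))
  expect_equal(fit$covariate_names, "cecal_mass_g")
})

test_that("ratio normalization divides by the selected mass", {
  profiles <- tibble::tibble(total_mass_g = 30, total_mass_nocecum_g = 27,
                             lean_mass_g = 20, cecal_mass_g = 3)
  expect_equal(ratio_normalize(9, profiles, "total"), 0.3)
  expect_equal(ratio_normalize(9, profiles, "lean"), 0.45)
  expect_equal(ratio_normalize(30, profiles, "total"), 1)
  # total vs no-cecum differ exactly by the cecal-mass effect
  expect_equal(ratio_normalize(9, profiles, "total_nocecum"), 9 / (30 - 3))
  expect_error(ratio_normalize(9, 0), "non-positive")
})
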