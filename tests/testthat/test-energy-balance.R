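test_that("uncertain addition and subtraction combine in quadrature", {
  d <- u_add(uval(10, 0.5), uval(2.5, 0.2), sign = -1)
  expect_equal(d$mean, 7.5)
  expect_equal(d$u, sqrt(0.5^2 + 0.2^2))          # 0.53852
  expect_equal(signif(d$u, 3), signif(mc_sd(`-`, c(10, 2.5), c(0.5, 0.2)), 3),
               tolerance = 0.01)
  # exact second operand leaves u unchanged
  expect_equal(u_add(uval(1, 0.3), uval(5, 0))$u, 0.3)
  # independent copies do not cancel: a - a has u * sqrt(2)
  a <- uval(4, 0.1)
  expect_equal(u_add(a, a, -1)$u, 0.1 * sqrt(2))
  expect_equal(u_add(a, a, -1)$mean, 0)
})

test_that("products and quotients propagate first-order Taylor uncertainty", {
  p <- u_mul(uval(2, 0.1), uval(3, 0.2))
  expect_equal(p$mean, 6)
  expect_equal(p$u, 0.5)  # sqrt((3*0.1)^2 + (2*0.2)^2)
  expect_equal(p$u, mc_sd(`*`, c(2, 3), c(0.1, 0.2)), tolerance = 0.02)
  # multiplying by an exact 1 is the identity
  expect_equal(u_mul(uval(7, 0.3), uval(1, 0)), uval(7, 0.3))
  # exact inputs give an exact quotient
  q <- u_div(uval(9, 0), uval(3, 0))
  expect_equal(q$mean, 3); expect_equal(q$u, 0)
  q2 <- u_div(uval(10, 0.5), uval(4, 0.2))
  expect_equal(q2$u, mc_sd(`/`, c(10, 4), c(0.5, 0.2)), tolerance = 0.02)
  expect_error(u_div(uval(1, 0), uval(0, 0.1)), "zero-mean")
  # operator sugar routes through the same propagation
  expect_equal((uval(2, 0.1) * uval(3, 0.2))$u, 0.5)
})

test_that("energy input and excretion carry their uncertainties", {
  zero <- daily_energy_input(uval(0, 0))
  expect_equal(zero$mean, 0)
  inp <- daily_energy_input(uval(2.5, 0.1))
  expect_equal(inp$mean, 9.85)
  expect_equal(inp$u, 0.394)
  # linear in intake
  expect_equal(daily_energy_input(uval(5, 0.2))$mean, 2 * inp$mean)
  exc <- daily_energy_excretion(uval(0.5, 0.05), uval(4.0, 0.1))
  expect_equal(exc$mean, 2.0)
  expect_equal(exc$u, sqrt((4 * 0.05)^2 + (0.5 * 0.1)^2))  # 0.206
  expect_equal(daily_energy_excretion(uval(0, 0), uval(4, 0.1))$mean, 0)
})

test_that("the balance propagates percent extraction through exact partials", {
  b <- balance(uval(10, 0.5), uval(2.5, 0.2))
  expect_equal(b$extraction$mean, 7.5)
  expect_equal(b$percent_extraction$mean, 75)
  expect_equal(b$percent_extraction$u,
               sqrt((100 * 2.5 / 100 * 0.5)^2 + (100 / 10 * 0.2)^2))  # 2.358
  pct_mc <- mc_sd(function(x, y) 100 * (x - y) / x, c(10, 2.5), c(0.5, 0.2))
  expect_equal(b$percent_extraction$u, pct_mc, tolerance = 0.02)
  # conservation of means: extraction + excretion = input exactly
  expect_equal(b$extraction$mean + b$excretion$mean, b$input$mean)
  expect_equal(balance(uval(10, 0.5), uval(0, 0))$percent_extraction$mean, 100)
  expect_equal(balance(uval(10, 0.5),
                       uval(10, 0.5))$percent_extraction$mean, 0)
  expect_error(balance(uval(0, 0), uval(1, 0)), "non-positive")
})

test_that("microbial fecal energy reproduces the published worked examples", {
  expect_warning(d <- microbial_energy_density(c(1.1e11, 1.6e11)), "dry")
  expect_equal(round(d, 2), c(0.11, 0.17))
  expect_equal(microbial_energy_density(0, warn_units = FALSE), 0)
  # linear in cell density
  expect_equal(microbial_energy_density(2.2e11, warn_units = FALSE),
               2 * microbial_energy_density(1.1e11, warn_units = FALSE))
})

test_that("cecal metabolite pools multiply concentration by cecal mass", {
  pool <- cecal_metabolite_pool(uval(10, 1), uval(3, 0.3))
  expect_equal(pool$mean, 30)
  expect_equal(pool$u, sqrt((3 * 1)^2 + (10 * 0.3)^2))  # 4.243
  expect_equal(cecal_metabolite_pool(uval(10, 1), uval(0, 0))$mean, 0)
  exact <- cecal_metabolite_pool(uval(8, 0), uval(2, 0))
  expect_equal(exact$mean, 16); expect_equal(exact$u, 0)
})

test_that("group_uval is the mean with its standard error", {
  x <- c(2, 4, 6, 8)
  g <- group_uval(x)
  expect_equal(g$mean, 5)
  expect_equal(g$u, sd(x) / 2)
  expect_error(group_uval(3), "length")
})
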