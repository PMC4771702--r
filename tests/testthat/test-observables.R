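# observables_scan: dimerization probability, response functions, design
# window.

test_that("the dimerization probability averages 2 n_cc / N_c", {
  sat <- toy_sample_table(n_s = rep(10L, 5), n_c = rep(6L, 5), n_cc = 3L)
  expect_equal(as.numeric(chaperone_dimer_probability(sat)), 1.0)

  none <- toy_sample_table(n_s = rep(10L, 5), n_c = rep(6L, 5), n_cc = 0L)
  expect_equal(as.numeric(chaperone_dimer_probability(none)), 0.0)

  one <- toy_sample_table(n_s = 2L, n_c = 4L, n_cc = 1L)
  expect_equal(as.numeric(chaperone_dimer_probability(one)), 0.5)
})

test_that("snapshots without chaperones are excluded with reported weight", {
  mixed <- toy_sample_table(n_s = rep(5L, 4), n_c = c(0L, 4L, 4L, 0L),
                            n_cc = c(0L, 2L, 0L, 0L))
  p <- chaperone_dimer_probability(mixed, weights = c(1, 1, 1, 1))
  expect_equal(as.numeric(p), 0.5)
  expect_equal(attr(p, "excluded_weight"), 0.5)
  empty <- toy_sample_table(n_s = rep(5L, 3), n_c = rep(0L, 3))
  expect_error(chaperone_dimer_probability(empty), "N_c = 0")
})

make_grid <- function(fun, x_c = c(0.1, 0.2, 0.3),
                      ecs = c(1, 2, 3, 4, 5), se = 0.01) {
  g <- expand.grid(x_c = x_c, beta_eps_cs = ecs)
  g$beta_eps_star <- mapply(fun, g$x_c, g$beta_eps_cs)
  g$se <- se
  g$mode <- "promiscuous"
  g
}

test_that("response functions are exact for polynomial surfaces", {
  lin <- make_grid(function(x, e) 0.5 + 2 * x + 0.1 * e)
  r <- response_function(lin, "x_c")
  expect_equal(r$deriv, rep(2, nrow(r)), tolerance = 1e-12)
  r2 <- response_function(lin, "beta_eps_cs")
  expect_equal(r2$deriv, rep(0.1, nrow(r2)), tolerance = 1e-12)

  const <- make_grid(function(x, e) 0.7)
  expect_equal(response_function(const, "x_c")$deriv, rep(0, 15))

  quad <- make_grid(function(x, e) 3 * x^2)
  r3 <- response_function(quad, "x_c")
  mid <- r3[r3$x_c == 0.2, ]
  expect_equal(mid$deriv, rep(2 * 3 * 0.2, nrow(mid)), tolerance = 1e-12)
})

test_that("a degenerate axis is rejected", {
  g <- make_grid(function(x, e) x)
  g$x_c[g$x_c == 0.3] <- 0.2    # duplicated axis value
  expect_error(response_function(g, "x_c"), "at least 3|monotone")
})

test_that("the design window reports interval overlap", {
  # a saturating miscibility surface beta_eps* = x_c * A(e): the x_c
  # response is A itself (large near and past the shoulder) while the
  # binding-strength response is A'"'"' (large on the rise), so both are
  # maximized together just below the shoulder at e = 3
  A <- c(0.0, 1.0, 2.4, 3.0, 3.1)
  g <- make_grid(function(x, e) x * A[e] - 0.5, ecs = 1:5)
  g$p_cc <- exp(-(g$beta_eps_cs - 3)^2 / 2)
  dw <- design_window(g, frac = 0.5)
  expect_true(all(dw$overlap))
  expect_true(all(dw$window_lo <= dw$window_hi))

  # p_cc peaking only at the far end of the axis must not overlap a
  # response window that sits in the interior
  g$p_cc <- 1e-6
  g$p_cc[g$beta_eps_cs == 5] <- 1
  dw2 <- design_window(g, frac = 0.5)
  expect_true(all(dw2$overlap == (dw2$window_hi >= 5)))
})
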