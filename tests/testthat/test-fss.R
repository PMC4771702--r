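# fss_critical: universal distribution, ordering histogram, the printed
# error formulas, and the matching objective.

test_that("the universal ordering density is normalized, symmetric and bimodal", {
  x <- seq(0, 3.5, by = 0.01)
  expect_equal(ising_ordering_density(x), ising_ordering_density(-x))
  expect_equal(stats::integrate(ising_ordering_density, -Inf, Inf,
                                rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  expect_equal(stats::integrate(function(y) y^2 * ising_ordering_density(y),
                                -Inf, Inf, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  g <- ising_ordering_density(seq(-3, 3, by = 0.005))
  peaks <- which(diff(sign(diff(g))) == -2) + 1
  expect_length(peaks, 2L)                       # exactly two local maxima
  expect_equal(g[peaks[1]], g[peaks[2]], tolerance = 1e-9)
  mid <- ising_ordering_density(0)
  expect_lt(mid, g[peaks[1]])                    # local minimum at the origin
})

test_that("the ordering operator is the stated linear combination", {
  expect_equal(ordering_operator(0.2, 0.9, -7, list(nu_s = 1, nu_c = 0, s = 0)),
               0.2)
  expect_equal(ordering_operator(0.1, 0.05, -0.2,
                                 list(nu_s = 0.8, nu_c = 0.6, s = 0.5)),
               0.08 + 0.03 + 0.1)
  expect_equal(ordering_operator(0, 0, 0, list(nu_s = 0.6, nu_c = 0.8, s = 2)),
               0)
})

test_that("the mixing solution enforces normalization and the sign gauge", {
  mx <- mixing_solution(2, 0, s = 0.3, Lambda = 5)
  expect_equal(mx$nu_s, 1)
  mx2 <- mixing_solution(-0.6, -0.8, s = 0.3, Lambda = 5)
  expect_equal(mx2$nu_s, 0.6)
  expect_equal(mx2$nu_c, 0.8)
  expect_equal(mx2$s, -0.3)   # s flips with nu
  expect_error(mixing_solution(1, 0, Lambda = -1), "positive")
})

test_that("the ordering histogram bins, centres and normalizes as declared", {
  mix <- list(nu_s = 1, nu_c = 0, s = 0, Lambda = 2)
  one <- toy_sample_table(n_s = 100L, n_c = 0L)
  h1 <- ordering_histogram(one, NULL, mix)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$mass, 1)

  four <- toy_sample_table(n_s = c(100L, 100L, 120L, 120L), n_c = rep(0L, 4))
  h4 <- ordering_histogram(four, NULL, mix)
  expect_equal(sort(h4$mass), c(0.5, 0.5))
  expect_equal(attr(h4, "bin_width"), 12^-3)
  # centring: the weighted mean of delta_m is zero by construction of M*
  expect_equal(sum(h4$mass * h4$m), 0, tolerance = 1e-12)
  expect_error(ordering_histogram(four, rep(0, 4), mix), "zero")
})

test_that("the per-bin error formula reproduces hand evaluations", {
  expect_equal(histogram_error(rep(1, 4), c(1, 1, 0, 0)), (2 - 4 / 4) / 4)
  expect_equal(histogram_error(rep(1, 4), c(0, 0, 0, 0)), 0)
  expect_equal(histogram_error(c(2, 1, 1), c(1, 0, 0)), (4 - 4 / 3) / 4)
})

test_that("the composition error reproduces the printed quadratic form", {
  expect_equal(composition_error(rho = c(s = 0.3, c = 0.1),
                                 rho_cov = matrix(0, 2, 2)),
               c(s = 0, c = 0))
  got <- composition_error(rho = c(s = 0.1, c = 0.1),
                           rho_cov = diag(0.01, 2))
  expect_equal(got, c(s = 0.125, c = 0.125))

  # brute-force oracle on a toy table with anticorrelated densities
  set.seed(13)
  V <- 12^3
  n_s <- sample(200:400, 10)
  tbl <- toy_sample_table(n_s = n_s, n_c = 600L - n_s)
  w <- runif(10)
  got <- composition_error(tbl, w)
  wn <- w / sum(w)
  rho <- c(s = sum(wn * n_s / V), c = sum(wn * (600 - n_s) / V))
  C <- matrix(0, 2, 2)
  obs <- cbind(n_s / V, (600 - n_s) / V)
  for (j in 1:2) for (k in 1:2)
    C[j, k] <- sum(wn * obs[, j] * obs[, k]) - sum(wn * obs[, j]) * sum(wn * obs[, k])
  phi <- sum(rho)
  want <- sapply(1:2, function(i) {
    tot <- 0
    for (j in 1:2) for (k in 1:2)
      tot <- tot + ((i == j) - rho[i] / phi) * C[j, k] * ((i == k) - rho[i] / phi)
    tot / phi^2
  })
  expect_equal(unname(got), unname(want))
})

test_that("chi-squared on synthetic universal samples is consistent with its dof", {
  set.seed(99)
  V <- 12^3
  x <- r_ising_ordering(8000)
  n_s <- as.integer(round(V * 0.5 + x * 150))
  tbl <- toy_sample_table(n_s = n_s, n_c = 0L, species = "client")
  ch <- chi_squared(tbl, list(fields = field_vector(),
                              mix = list(nu_s = 1, nu_c = 0, s = 0,
                                         Lambda = NULL)))
  dof <- attr(ch, "dof")
  expect_gt(dof, 30)
  expect_gt(as.numeric(ch), stats::qchisq(1e-5, dof))
  expect_lt(as.numeric(ch), stats::qchisq(1 - 1e-5, dof))
})

test_that("the composition term contributes as printed and scales with sigma", {
  set.seed(31)
  n_s <- sample(300:500, 60, replace = TRUE)
  n_c <- sample(100:200, 60, replace = TRUE)
  tbl <- toy_sample_table(n_s = n_s, n_c = n_c)
  mix <- list(nu_s = 1 / sqrt(2), nu_c = 1 / sqrt(2), s = 0, Lambda = NULL)
  ch <- chi_squared(tbl, list(fields = field_vector(), mix = mix), x_c = 0.2)
  # independent recomputation of the composition term from the exported
  # pieces
  sig <- composition_error(tbl, NULL)
  V <- 12^3
  rho <- c(s = mean(n_s), c = mean(n_c)) / V
  x_hat <- rho / sum(rho)
  want <- sum((x_hat - c(0.8, 0.2))^2 / sig)
  expect_equal(attr(ch, "comp_term"), want, tolerance = 1e-8)
  # doubling both sigma^2 terms halves^2 the composition contribution
  expect_equal(sum((x_hat - c(0.8, 0.2))^2 / (2 * sig)), want / 2)
})

test_that("chi-squared is invariant under the joint sign flip of (nu, s)", {
  set.seed(17)
  n_s <- sample(300:500, 400, replace = TRUE)
  n_c <- sample(100:200, 400, replace = TRUE)
  tbl <- toy_sample_table(n_s = n_s, n_c = n_c, n_iso = sample(500:900, 400, TRUE),
                          fields = field_vector(beta_eps = 0.2))
  mix <- list(nu_s = 0.8, nu_c = 0.6, s = 0.1, Lambda = 4)
  flip <- list(nu_s = -0.8, nu_c = -0.6, s = -0.1, Lambda = 4)
  f <- field_vector(beta_eps = 0.2)
  a <- chi_squared(tbl, list(fields = f, mix = mix))
  b <- chi_squared(tbl, list(fields = f, mix = flip))
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-10)
})

test_that("chi-squared demands a fresh simulation when the ESS collapses", {
  tbl <- toy_sample_table(n_s = c(rep(10L, 50), 400L), n_c = 0L,
                          fields = field_vector(beta_mu_s = -5),
                          species = "client")
  far <- field_vector(beta_mu_s = 0)
  expect_error(chi_squared(tbl, list(fields = far,
                                     mix = list(nu_s = 1, nu_c = 0, s = 0,
                                                Lambda = NULL)),
                           ess_min = 0.5),
               "closer")
})
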