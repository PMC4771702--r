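# oracle_enum: exact truncated enumeration and engine validation.

test_that("single-site averages match the closed form exactly", {
  # one site, one species: Z = 1 + 24 z, <N> = 24 z / (1 + 24 z)
  en <- enumerate_grand_partition(c(1, 1, 1), 1, field_vector(),
                                  species = "client")
  expect_equal(en$mean_n_s, 24 / 25, tolerance = 1e-12)
  z <- exp(-1)
  en2 <- enumerate_grand_partition(c(1, 1, 1), 1,
                                   field_vector(beta_mu_s = -1),
                                   species = "client")
  expect_equal(en2$mean_n_s, 24 * z / (1 + 24 * z), tolerance = 1e-12)
})

test_that("the empty-lattice limit is reached as beta_mu -> -Inf", {
  en <- enumerate_grand_partition(c(2, 1, 1), 2,
                                  field_vector(beta_mu_s = -30, beta_mu_c = -30))
  expect_lt(en$mean_n_s + en$mean_n_c, 1e-10)
})

test_that("two-site client enumeration matches a hand-computed partition sum", {
  # 2x1x1 open lattice, clients only, N_max = 2.  Each site holds one of 24
  # orientations; 12 of 24 present a patch on +x and 12 on -x, so 144 of
  # the 576 adjacent pairs form a directional bond on top of the isotropic
  # contact.
  eps <- 0.3; e_ss <- 1.2; mu <- -2
  z <- exp(mu)
  f <- field_vector(beta_eps = eps, beta_eps_ss = e_ss, beta_mu_s = mu)
  en <- enumerate_grand_partition(c(2, 1, 1), 2, f, species = "client")
  Zpair <- z^2 * exp(eps) * (432 + 144 * exp(e_ss))
  Z <- 1 + 48 * z + Zpair
  expect_equal(exp(en$log_z), Z, tolerance = 1e-12)
  expect_equal(en$mean_n_s, (48 * z + 2 * Zpair) / Z, tolerance = 1e-12)
  U2 <- -(eps + e_ss) * z^2 * exp(eps) * 144 * exp(e_ss) -
    eps * z^2 * exp(eps) * 432
  expect_equal(en$mean_u, U2 / Z, tolerance = 1e-12)
})

test_that("the enumeration budget guard triggers", {
  expect_error(enumerate_grand_partition(c(3, 3, 3), 3, field_vector(),
                                         state_budget = 1e5),
               "budget")
})

test_that("the sampler matches exact enumeration on an ideal system", {
  rep <- validate_sampler(c(3, 3, 3), 2, field_vector(beta_mu_s = -6,
                                                      beta_mu_c = -6),
                          schedule = list(burnin = 300, n_samples = 3000,
                                          spacing = 4),
                          seed = 51)
  expect_true(rep$pass)
})

test_that("the sampler matches exact enumeration with strong interactions", {
  f <- field_vector(beta_eps = 0.6, beta_eps_ss = 2.0, beta_eps_cs = 1.5,
                    beta_eps_cc = 1.0, beta_mu_s = -4, beta_mu_c = -4)
  rep <- validate_sampler(c(2, 2, 1), 3, f,
                          schedule = list(burnin = 500, n_samples = 5000,
                                          spacing = 4),
                          seed = 53)
  expect_true(rep$pass)
})

test_that("reweighted estimates agree with direct enumeration at the target", {
  f1 <- field_vector(beta_eps = 0.3, beta_eps_ss = 1.0, beta_mu_s = -3.5)
  f2 <- field_vector(beta_eps = 0.45, beta_eps_ss = 1.0, beta_mu_s = -3.2)
  samp <- run_gcmc(f1, dims = c(2, 2, 2), boundary = "open",
                   species = "client", n_cap = 3,
                   schedule = list(burnin = 400, n_samples = 6000, spacing = 4),
                   seed = 57)
  rw <- reweight(samp, f2, warn_ess = FALSE)
  exact <- enumerate_grand_partition(c(2, 2, 2), 3, f2, species = "client")
  est <- sum(rw$w * samp$n_s) / sum(rw$w)
  # block bootstrap standard error of the weighted mean
  nb <- 50
  boots <- replicate(nb, {
    i <- sample.int(nrow(samp), nrow(samp), replace = TRUE)
    sum(rw$w[i] * samp$n_s[i]) / sum(rw$w[i])
  })
  expect_lt(abs(est - exact$mean_n_s), 4 * stats::sd(boots) + 1e-9)
})

test_that("the truncation bound is finite and small for dilute systems", {
  en <- enumerate_grand_partition(c(2, 2, 1), 3,
                                  field_vector(beta_mu_s = -8, beta_mu_c = -8))
  expect_lt(en$truncation_bound, 1e-3)
  expect_gt(en$truncation_bound, 0)
})
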