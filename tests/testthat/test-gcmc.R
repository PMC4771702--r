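# gcmc_engine: sampling correctness, determinism, bias construction,
# reweighting.

test_that("runs are reproducible from the seed", {
  f <- field_vector(beta_eps = 0.3, beta_mu_s = -3, beta_mu_c = -3)
  sch <- list(burnin = 50, n_samples = 200, spacing = 2)
  a <- run_gcmc(f, dims = c(4, 4, 4), boundary = "open", schedule = sch, seed = 123)
  b <- run_gcmc(f, dims = c(4, 4, 4), boundary = "open", schedule = sch, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a zero-length schedule yields an empty table with metadata", {
  tbl <- run_gcmc(field_vector(), dims = c(3, 3, 3), boundary = "open",
                  schedule = list(burnin = 0, n_samples = 0, spacing = 1),
                  seed = 1)
  expect_equal(nrow(tbl), 0)
  expect_equal(attr(tbl, "dims"), c(3L, 3L, 3L))
  expect_s3_class(tbl, "sample_table")
})

test_that("ideal-solution occupancy matches the closed form", {
  # single-site grand partition: 1 + Omega z per site, Omega = 48
  mu <- -5
  f <- field_vector(beta_mu_s = mu, beta_mu_c = mu)
  tbl <- run_gcmc(f, dims = c(3, 3, 3), boundary = "open",
                  schedule = list(burnin = 300, n_samples = 5000, spacing = 3),
                  seed = 7)
  z <- exp(mu)
  expected <- 27 * 48 * z / (1 + 48 * z)
  N <- tbl$n_s + tbl$n_c
  expect_lt(abs(mean(N) - expected), 3 * latmix:::batch_se(N))
})

test_that("snapshot contact counts respect the patch-count bounds", {
  f <- field_vector(beta_eps = 0.4, beta_eps_ss = 1.5, beta_eps_cs = 1.0,
                    beta_eps_cc = 0.8, beta_mu_s = -2, beta_mu_c = -2)
  tbl <- run_gcmc(f, dims = c(4, 4, 4), boundary = "open",
                  schedule = list(burnin = 200, n_samples = 1000, spacing = 2),
                  seed = 3)
  expect_true(all(tbl$n_cc <= tbl$n_c %/% 2))
  expect_true(all(tbl$n_ss <= (3 * tbl$n_s) %/% 2))
  expect_true(all(tbl$n_cs <= pmin(3 * tbl$n_s, tbl$n_c)))
  expect_true(all(tbl$n_iso <= 3 * 64))
})

test_that("Wang-Landau weights recover the ideal-gas entropy", {
  V <- 9
  b <- build_bias(field_vector(), dims = c(3, 3, 1), boundary = "open",
                  n_range = c(0, V), lnf_final = 5e-5, seed = 11,
                  refine_passes = 2)
  expect_true(b$converged)
  # exact: eta(N) = -ln [ C(V,N) 48^N ] + const
  exact <- -(lchoose(V, 0:V) + (0:V) * log(48))
  dev <- (unname(b$eta) - exact) - mean(unname(b$eta) - exact)
  expect_lt(max(abs(dev)), 0.35)
})

test_that("a width-1 N range is trivially flat", {
  b <- build_bias(field_vector(beta_mu_s = -1), dims = c(3, 3, 3),
                  boundary = "open", species = "client", n_range = c(4, 4),
                  seed = 2)
  expect_length(b$eta, 1L)
  expect_true(b$converged)
})

test_that("identity reweighting of an unbiased run gives equal weights", {
  f <- field_vector(beta_mu_s = -3, beta_mu_c = -3)
  tbl <- run_gcmc(f, dims = c(3, 3, 3), boundary = "open",
                  schedule = list(burnin = 50, n_samples = 300, spacing = 1),
                  seed = 5)
  rw <- reweight(tbl, f)
  expect_equal(rw$w, rep(1, 300))
  expect_equal(rw$ess, 300)
})

test_that("a pure chemical-potential shift reweights as exp(dmu * N)", {
  tbl <- toy_sample_table(n_s = c(2L, 5L, 9L), n_c = c(0L, 0L, 0L),
                          fields = field_vector(beta_mu_s = -4))
  rw <- reweight(tbl, field_vector(beta_mu_s = -3.5), warn_ess = FALSE)
  expect_equal(rw$log_w, 0.5 * c(2, 5, 9))
  expect_equal(rw$w, exp(0.5 * c(2, 5, 9)) / exp(0.5 * 9))
})

test_that("non-finite field deltas are rejected by name", {
  tbl <- toy_sample_table(n_s = 1L, n_c = 0L)
  f_bad <- field_vector()
  f_bad[["beta_mu_c"]] <- Inf
  expect_error(reweight(tbl, f_bad), "beta_mu_c")
})

test_that("reweighted averages agree with direct simulation", {
  sch <- list(burnin = 300, n_samples = 6000, spacing = 3)
  f1 <- field_vector(beta_mu_s = -4.8, beta_mu_c = -4.8)
  f2 <- field_vector(beta_mu_s = -5.0, beta_mu_c = -5.0)
  t1 <- run_gcmc(f1, dims = c(3, 3, 3), boundary = "open", schedule = sch,
                 seed = 31)
  t2 <- run_gcmc(f2, dims = c(3, 3, 3), boundary = "open", schedule = sch,
                 seed = 32)
  rw <- reweight(t1, f2)
  n1 <- t1$n_s + t1$n_c
  n2 <- t2$n_s + t2$n_c
  est <- sum(rw$w * n1) / sum(rw$w)
  se <- sqrt(latmix:::batch_se(n1)^2 + latmix:::batch_se(n2)^2)
  expect_lt(abs(est - mean(n2)), 3 * se + 1e-9)
})

test_that("bias weights cancel out of production estimates", {
  # biased and unbiased runs of the same small system must agree once the
  # bias is removed through the recorded eta values
  V <- 27
  f <- field_vector(beta_eps = 0.4, beta_mu_s = -3.2)
  b <- build_bias(f, dims = c(3, 3, 3), boundary = "open", species = "client",
                  n_range = c(0, 20), seed = 41, lnf_final = 1e-3)
  biased <- run_gcmc(f, bias = b,
                     schedule = list(burnin = 300, n_samples = 6000, spacing = 3))
  plain <- run_gcmc(f, dims = c(3, 3, 3), boundary = "open", species = "client",
                    n_cap = 20,
                    schedule = list(burnin = 300, n_samples = 6000, spacing = 3),
                    seed = 42)
  rw <- reweight(biased, f, warn_ess = FALSE)
  est <- sum(rw$w * biased$n_s) / sum(rw$w)
  se <- sqrt(latmix:::batch_se(biased$n_s)^2 + latmix:::batch_se(plain$n_s)^2)
  expect_lt(abs(est - mean(plain$n_s)), 4 * se + 1e-9)
})
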