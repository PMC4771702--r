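# model_core: patch geometry, contact energies, bookkeeping.

test_that("orientation table enumerates the 24 proper rotations of the cube", {
  ors <- orientation_table()
  keys <- vapply(ors, function(m) paste(m, collapse = ","), character(1))
  expect_length(unique(keys), 24L)
  for (m in ors) {
    expect_equal(det(m), 1)                        # proper rotation
    expect_equal(m %*% t(m), diag(3), ignore_attr = TRUE)  # orthogonal
  }
  expect_equal(ors[[1]], diag(3), ignore_attr = TRUE)
})

test_that("every orientation presents 3 client patches and 1 chaperone patch", {
  m <- model_spec()
  expect_equal(unname(rowSums(m$patch_mask[1:24, ])), rep(3, 24))
  expect_equal(unname(rowSums(m$patch_mask[25:48, ])), rep(1, 24))
  expect_equal(m$omega, 48L)
})

test_that("contact energy combines the isotropic and directional terms", {
  m <- model_spec()
  # identity-oriented clients: patches on +x,+y,+z; the right-hand partner
  # has no patch on its -x face, so only the isotropic term applies
  a <- list(species = "client", orientation = 1)
  expect_equal(contact_energy(a, a, c(1, 0, 0), field_vector(beta_eps = 0.3), m),
               -0.3)
  cl_ori <- which(m$patch_mask[1:24, "-x"] == 1)[1]
  ch_ori <- which(m$patch_mask[25:48, "-x"] == 1)[1]
  # chaperone patch facing a client patch
  expect_equal(contact_energy(list(species = "chaperone", orientation = 1),
                              list(species = "client", orientation = cl_ori),
                              c(1, 0, 0),
                              field_vector(beta_eps = 0, beta_eps_cs = 2), m),
               -2.0)
  # two facing chaperone patches on top of the isotropic term
  expect_equal(contact_energy(list(species = "chaperone", orientation = 1),
                              list(species = "chaperone", orientation = ch_ori),
                              c(1, 0, 0),
                              field_vector(beta_eps = 0.1, beta_eps_cc = 1.5), m),
               -1.6)
  expect_error(contact_energy(a, a, c(1, 1, 0), field_vector()), "unit")
})

test_that("contact energy is symmetric under swapping the pair", {
  m <- model_spec()
  f <- field_vector(beta_eps = 0.2, beta_eps_ss = 1.1, beta_eps_cs = 0.7,
                    beta_eps_cc = 0.4)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  set.seed(5)
  for (pair in list(c("client", "client"), c("client", "chaperone"),
                    c("chaperone", "chaperone"))) {
    for (rep in 1:120) {
      a <- list(species = pair[1], orientation = sample(24, 1))
      b <- list(species = pair[2], orientation = sample(24, 1))
      d <- dirs[[sample(6, 1)]]
      expect_equal(contact_energy(a, b, d, f, m),
                   contact_energy(b, a, -d, f, m))
    }
  }
})

test_that("total energy counts each adjacent pair once", {
  f1 <- field_vector(beta_eps = 1)
  expect_equal(total_energy(lattice_config(4), f1)$energy, 0)

  cfg <- lattice_config(5)
  cfg <- place_monomer(cfg, c(1, 1, 1), "client", 1)
  cfg <- place_monomer(cfg, c(3, 3, 3), "chaperone", 1)
  expect_equal(total_energy(cfg, f1)$energy, 0)

  # full periodic L=4 lattice of identically oriented chaperones: no facing
  # patches, so 3 L^3 isotropic bonds under periodicity
  cfg <- lattice_config(4)
  for (x in 1:4) for (y in 1:4) for (z in 1:4)
    cfg <- place_monomer(cfg, c(x, y, z), "chaperone", 1)
  te <- total_energy(cfg, f1)
  expect_equal(te$energy, -3 * 4^3)
  expect_equal(te$n_iso, 3 * 4^3)
  expect_equal(te$n_cc, 0)
})

test_that("energy is extensive over non-interacting copies", {
  set.seed(21)
  f <- field_vector(beta_eps = 0.5, beta_eps_ss = 1.2, beta_eps_cs = 0.8,
                    beta_eps_cc = 0.3)
  cfg <- lattice_config(dims = c(3, 3, 3), boundary = "open")
  for (i in 1:12) {
    mv <- random_move(cfg)
    if (!is.null(mv) && mv$kind == "insert") cfg <- apply_move(cfg, mv)
  }
  e1 <- total_energy(cfg, f)$energy
  # duplicate into a doubled open box with an empty separating plane
  big <- lattice_config(dims = c(7, 3, 3), boundary = "open")
  d <- attr(cfg, "dims")
  for (x in 1:3) for (y in 1:3) for (z in 1:3) {
    i <- (x - 1) + 3 * ((y - 1) + 3 * (z - 1)) + 1
    if (cfg[i] >= 0) {
      big[(x - 1) + 7 * ((y - 1) + 3 * (z - 1)) + 1] <- cfg[i]
      big[(x + 3) + 7 * ((y - 1) + 3 * (z - 1)) + 1] <- cfg[i]
    }
  }
  expect_equal(total_energy(big, f)$energy, 2 * e1)
})

test_that("local energy changes track full recomputation over a move sequence", {
  set.seed(9)
  f <- field_vector(beta_eps = 0.4, beta_eps_ss = 1.5, beta_eps_cs = 1.0,
                    beta_eps_cc = 0.6)
  cfg <- lattice_config(4)
  e <- total_energy(cfg, f)$energy
  acc <- 0
  for (i in 1:200) {
    mv <- random_move(cfg)
    if (is.null(mv)) next
    de <- delta_energy(cfg, mv, f)
    cfg2 <- apply_move(cfg, mv)
    e2 <- total_energy(cfg2, f)$energy
    expect_equal(de, e2 - e, tolerance = 1e-9)
    cfg <- cfg2; e <- e2; acc <- acc + 1
  }
  expect_gt(acc, 150)
})

test_that("inconsistent move descriptions are rejected", {
  cfg <- lattice_config(4)
  cfg <- place_monomer(cfg, c(1, 1, 1), "client", 1)
  f <- field_vector()
  expect_error(delta_energy(cfg, list(kind = "insert", at = c(1, 1, 1),
                                      species = "client", orientation = 1), f),
               "occupied")
  expect_error(delta_energy(cfg, list(kind = "delete", at = c(2, 2, 2)), f),
               "empty")
  expect_error(delta_energy(cfg, list(kind = "translate", at = c(2, 2, 2),
                                      to = c(1, 1, 1)), f),
               "empty")
})

test_that("directional energies must be non-negative", {
  expect_error(field_vector(beta_eps_ss = -0.1), "non-negative")
  expect_silent(field_vector(beta_eps = -2))  # repulsive isotropic is allowed
})
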