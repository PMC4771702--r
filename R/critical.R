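# Self-consistent location of a critical point: simulate near the trial
# fields with a flat-histogram bias, minimize the mixed-field chi-squared by
# reweighting, move the fields to the optimum, re-simulate, and repeat until
# the solved miscibility limit beta_eps* stops moving.

.weighted_skewness <- function(x, w) {
  wn <- w / sum(w)
  mu <- sum(wn * x)
  v <- sum(wn * (x - mu)^2)
  if (!is.finite(v) || v <= 0) return(NaN)
  sum(wn * (x - mu)^3) / v^1.5
}

# Poisson-deviance matching objective used by the numerical minimization.
# The reported Eq-3 chi-squared is undefined or violently unstable in bins
# with few effective samples; the G-statistic on effective counts
# O_k = mass_k * ESS vs E_k = q_k * ESS is asymptotically equivalent where
# both are valid and remains well-behaved in the small-count regime:
# interior holes cost 2 E_k, and model mass escaping the sampled support is
# charged the same way.
.match_deviance <- function(samples, trial, x_c = NULL) {
  f <- .as_field_vector(trial$fields)
  mix <- trial$mix
  rw <- reweight(samples, f, warn_ess = FALSE)
  if (is.null(mix$Lambda)) {
    V <- prod(attr(samples, "dims"))
    u <- sample_energy(samples, f) / V
    M <- ordering_operator(samples$n_s / V, samples$n_c / V, u, mix)
    wn <- rw$w / sum(rw$w)
    v <- sum(wn * M^2) - sum(wn * M)^2
    mix$Lambda <- if (v > 0) 1 / sqrt(v) else 1
  }
  h <- ordering_histogram(samples, rw, mix, f = f)
  V <- prod(attr(samples, "dims"))
  ess <- rw$ess
  kk <- min(h$k):max(h$k)
  O <- numeric(length(kk))
  O[match(h$k, kk)] <- h$mass * ess
  E <- mix$Lambda * ising_ordering_density(mix$Lambda * kk / V) / V * ess
  g <- 2 * sum(ifelse(O > 0, O * log(O / pmax(E, 1e-300)) - (O - E), E))
  g <- g + 2 * max(ess - sum(E), 0)   # model mass beyond the sampled support
  n_comp <- 0L
  if (!is.null(x_c)) {
    wn <- rw$w / sum(rw$w)
    rho <- c(s = sum(wn * samples$n_s) / V, c = sum(wn * samples$n_c) / V)
    x_hat <- rho / sum(rho)
    # The printed composition variance is a population quantity and much too
    # permissive as a steering term: a trial point whose composition cannot
    # be brought onto target (the wrong branch of the critical line) must be
    # rejected outright, so the objective charges composition error on a
    # fixed 0.02 scale.  The reported chi-squared keeps the printed form.
    g <- g + ((x_hat[["c"]] - x_c) / 0.02)^2
    n_comp <- 2L
  }
  dof <- max(length(kk) + n_comp - (if (is.null(x_c)) 4L else 6L), 1L)
  structure(g / dof, ess = ess)
}

# parameter packing for the chi-squared minimization
.trial_from_par <- function(par, fixed, species) {
  if (species == "both") {
    f <- field_vector(beta_eps = par[1], beta_eps_ss = fixed$beta_eps_ss,
                      beta_eps_cs = fixed$beta_eps_cs,
                      beta_eps_cc = fixed$beta_eps_cc,
                      beta_mu_s = par[2], beta_mu_c = par[3])
    mix <- list(nu_s = cos(par[4]), nu_c = sin(par[4]), s = par[5],
                Lambda = NULL)
  } else {
    mu_s <- if (species == "client") par[2] else -30
    mu_c <- if (species == "chaperone") par[2] else -30
    f <- field_vector(beta_eps = par[1], beta_eps_ss = fixed$beta_eps_ss,
                      beta_eps_cs = fixed$beta_eps_cs,
                      beta_eps_cc = fixed$beta_eps_cc,
                      beta_mu_s = mu_s, beta_mu_c = mu_c)
    mix <- list(nu_s = as.numeric(species == "client"),
                nu_c = as.numeric(species == "chaperone"),
                s = par[3], Lambda = NULL)
  }
  list(fields = f, mix = mix)
}

.par_from_fields <- function(fields, mix, species) {
  if (species == "both")
    c(fields[["beta_eps"]], fields[["beta_mu_s"]], fields[["beta_mu_c"]],
      atan2(mix$nu_c, mix$nu_s), mix$s)
  else
    c(fields[["beta_eps"]],
      if (species == "client") fields[["beta_mu_s"]] else fields[["beta_mu_c"]],
      mix$s)
}

# initial mixing guess from the sample fluctuations at the starting fields
.init_mix <- function(samples, fields, species) {
  rw <- reweight(samples, fields, warn_ess = FALSE)
  V <- prod(attr(samples, "dims"))
  w <- rw$w
  if (species == "both") {
    rs <- samples$n_s / V; rc <- samples$n_c / V
    C <- matrix(c(weighted_cov(rs, rs, w), weighted_cov(rs, rc, w),
                  weighted_cov(rs, rc, w), weighted_cov(rc, rc, w)), 2, 2)
    v1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
    if (v1[1] < 0) v1 <- -v1
    mix <- list(nu_s = v1[1], nu_c = v1[2], s = 0, Lambda = 1)
  } else {
    mix <- list(nu_s = as.numeric(species == "client"),
                nu_c = as.numeric(species == "chaperone"), s = 0, Lambda = 1)
  }
  u <- sample_energy(samples, fields) / V
  M <- ordering_operator(samples$n_s / V, samples$n_c / V, u, mix)
  sdM <- sqrt(weighted_cov(M, M, w))
  mix$Lambda <- if (is.finite(sdM) && sdM > 0) 1 / sdM else 1
  mix
}

.fit_mixing <- function(samples, start_fields, start_mix, fixed, x_c, species,
                        n_starts = 2L, ess_min = 0.02, maxit = 400L,
                        light = FALSE) {
  n <- nrow(samples)
  V <- prod(attr(samples, "dims"))
  mix_base <- list(nu_s = start_mix$nu_s, nu_c = start_mix$nu_c, s = 0,
                   Lambda = NULL)

  fields_at <- function(eps, mu_shift, dmu_c = NULL) {
    # move the isotropic coupling and shift the chemical potential(s); for
    # mixtures both potentials shift together (density direction) with the
    # difference controlled separately (composition direction)
    f <- unclass(start_fields)
    f["beta_eps"] <- eps
    if (species == "client") f["beta_mu_s"] <- f["beta_mu_s"] + mu_shift
    else if (species == "chaperone") f["beta_mu_c"] <- f["beta_mu_c"] + mu_shift
    else {
      f["beta_mu_s"] <- f["beta_mu_s"] + mu_shift
      f["beta_mu_c"] <- f["beta_mu_c"] + mu_shift + (dmu_c %||% 0)
    }
    do.call(field_vector, as.list(f))
  }

  skew_at <- function(eps, mu_shift, dmu_c = NULL) {
    f <- fields_at(eps, mu_shift, dmu_c)
    rw <- reweight(samples, f, warn_ess = FALSE)
    if (rw$ess < 3) return(1e6)
    u <- sample_energy(samples, f) / V
    M <- ordering_operator(samples$n_s / V, samples$n_c / V, u, mix_base)
    .weighted_skewness(M, rw$w)
  }

  ess_at <- function(f) reweight(samples, f, warn_ess = FALSE)$ess
  # trust-region floor: half the ESS achievable at the generating fields
  # (a flat-histogram sample never reaches ESS = n even at its own fields)
  ess_soft <- max(0.05, 0.5 * ess_at(start_fields) / n)

  symmetrize <- function(eps) {
    # root-find the skewness zero in a narrow window around the current
    # potential: a wide quadratic search can land in a spurious low-ESS
    # basin (a narrow off-critical blob is also skewless)
    g <- function(m) {
      v <- skew_at(eps, m)
      if (!is.finite(v)) 1e6 else v
    }
    lo <- -0.35; hi <- 0.35
    slo <- g(lo); shi <- g(hi)
    if (is.finite(slo) && is.finite(shi) && slo * shi < 0)
      tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-4)$root,
               error = function(e)
                 stats::optimize(function(m) g(m)^2, c(lo, hi),
                                 tol = 1e-4)$minimum)
    else stats::optimize(function(m) g(m)^2, c(lo, hi), tol = 1e-4)$minimum
  }

  red_chi2 <- function(trial) {
    # trust region of statistical validity: outside it the noise-inflated
    # error estimates would let any shape "match" the universal form, so
    # the fit is confined to trials the current sample can resolve
    ess <- ess_at(trial$fields)
    if (ess < ess_soft * n)
      return(1e6 * (1 + ess_soft * n / max(ess, 1)))
    as.numeric(.match_deviance(samples, trial, x_c = x_c))
  }

  # composition steering (mixtures): the chemical-potential difference is
  # root-found so the reweighted stoichiometric fraction hits the target,
  # rather than left to the weak printed composition term
  x_hat_at <- function(eps, m, dmu) {
    f <- fields_at(eps, m, dmu)
    rw <- reweight(samples, f, warn_ess = FALSE)
    if (rw$ess < 3) return(NA_real_)
    wn <- rw$w / sum(rw$w)
    rc <- sum(wn * samples$n_c)
    rc / (sum(wn * samples$n_s) + rc)
  }
  comp_adjust <- function(eps, m) {
    if (species != "both") return(NULL)
    # interior evaluations can lose all effective samples; treat those as
    # on-target so the root-finder steps past them instead of aborting
    g <- function(d) {
      v <- x_hat_at(eps, m, d) - x_c
      if (is.finite(v)) v else 0
    }
    glo <- g(-1.5); ghi <- g(1.5)
    if (glo * ghi < 0)
      tryCatch(stats::uniroot(g, c(-1.5, 1.5), tol = 1e-3)$root,
               error = function(e) 0)
    else 0
  }

  # stage 1: nested 1-D search in beta_eps, symmetrizing the ordering
  # distribution in the chemical potential at every trial coupling
  eps0 <- start_fields[["beta_eps"]]
  shape_obj <- function(eps) {
    m <- symmetrize(eps)
    dmu <- comp_adjust(eps, m)
    v <- red_chi2(list(fields = fields_at(eps, m, dmu), mix = mix_base))
    if (!is.finite(v)) 1e7 else v
  }
  # coarse grid then a bracketed line search: robust to the cliffs that a
  # bare golden search can fall over
  reach <- if (light) 0.02 else 0.08
  grid_e <- eps0 + seq(-reach, reach, length.out = if (light) 5L else 9L)
  grid_v <- vapply(grid_e, shape_obj, numeric(1))
  i_best <- which.min(grid_v)
  bracket <- grid_e[c(max(i_best - 1L, 1L), min(i_best + 1L, length(grid_e)))]
  o1 <- stats::optimize(shape_obj, interval = bracket,
                        tol = if (light) 5e-4 else 2e-4)
  eps1 <- if (o1$objective < grid_v[i_best]) o1$minimum else grid_e[i_best]
  mu1 <- symmetrize(eps1)
  dmu1 <- comp_adjust(eps1, mu1) %||% 0

  # stage 2: constrained simplex polish over the remaining mixing freedom
  pack <- function(par) {
    if (species == "both")
      list(fields = fields_at(par[1], mu1 + par[2], dmu1 + par[3]),
           mix = list(nu_s = cos(par[4]), nu_c = sin(par[4]), s = par[5],
                      Lambda = NULL))
    else
      list(fields = fields_at(par[1], mu1 + par[2]),
           mix = list(nu_s = mix_base$nu_s, nu_c = mix_base$nu_c, s = par[3],
                      Lambda = NULL))
  }
  theta0 <- atan2(start_mix$nu_c, start_mix$nu_s)
  par0 <- if (species == "both") c(eps1, 0, 0, theta0, 0) else c(eps1, 0, 0)
  lim <- if (species == "both") c(0.05, 0.25, 0.6, 0.5, 0.3)
         else c(0.05, 0.25, 0.3)
  scale <- pmin(lim / 3, c(0.01, 0.03, if (species == "both") c(0.1, 0.1), 0.02))
  obj <- function(par) {
    if (any(abs(par - par0) > lim)) return(1e9 + sum(abs(par - par0)))
    v <- red_chi2(pack(par))
    if (!is.finite(v)) 1e7 else v
  }
  best <- NULL
  for (k in seq_len(max(n_starts, 1L))) {
    p0 <- if (k == 1) par0 else par0 + stats::rnorm(length(par0)) * scale
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-7,
                                       parscale = scale))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  tr <- pack(best$par)
  chi2 <- chi_squared(samples, tr, x_c = x_c, ess_min = ess_min,
                      on_low_ess = "penalty")
  mix <- mixing_solution(tr$mix$nu_s, tr$mix$nu_c, tr$mix$s,
                         attr(chi2, "Lambda") %||% 1,
                         M_star = attr(chi2, "M_star"))
  list(fields = tr$fields, mix = mix, chi2 = chi2, par = best$par,
       value = best$value)
}

# analytic bias update after a field move: subtract the change in the
# conditional mean log-weight at each N, estimated from the previous samples
.shift_bias <- function(bias, samples, f_new) {
  f_old <- .as_field_vector(attr(samples, "fields"))
  d <- unclass(.as_field_vector(f_new)) - unclass(f_old)
  N <- samples$n_s + samples$n_c
  dlw <- d[["beta_eps"]] * samples$n_iso + d[["beta_eps_ss"]] * samples$n_ss +
    d[["beta_eps_cs"]] * samples$n_cs + d[["beta_eps_cc"]] * samples$n_cc +
    d[["beta_mu_s"]] * samples$n_s + d[["beta_mu_c"]] * samples$n_c
  grid <- bias$n_lo:bias$n_hi
  cond <- tapply(dlw, factor(N, levels = grid), mean)
  filled <- as.numeric(cond)
  if (anyNA(filled)) {
    known <- which(!is.na(filled))
    if (length(known) < 2) return(bias)
    filled <- stats::approx(grid[known], filled[known], xout = grid,
                            rule = 2)$y
  }
  eta <- unname(bias$eta) - filled
  bias$eta <- stats::setNames(eta - max(eta), grid)
  bias$fields <- .as_field_vector(f_new)
  bias
}

#' Locate a critical point by mixed-field finite-size scaling
#'
#' Solves self-consistently for the miscibility limit `beta_eps*` and the
#' conjugate chemical potentials at fixed directional interaction energies
#' and target chaperone fraction `x_c`.  Each outer iteration: (re)builds
#' the flat-histogram bias at the current trial fields, collects a biased
#' grand-canonical sample, minimizes the [chi_squared()] matching objective
#' over `(beta_eps, beta_mu_s, beta_mu_c, nu, s, Lambda)` by reweighting,
#' and moves the trial fields to the optimum; iteration stops when
#' `beta_eps*` changes by less than `tol`.  A non-converged result is
#' flagged and warned about, never silently accepted.
#'
#' @param fixed List with `beta_eps_ss`, `beta_eps_cs`, `beta_eps_cc` and
#'   (for two-species systems) the target `x_c`.
#' @param L,dims,boundary Lattice geometry; production runs use a periodic
#'   cubic lattice.
#' @param species `"both"` for the chaperone-client mixture, `"client"` or
#'   `"chaperone"` for single-species systems (e.g. the patch-free lattice
#'   gas limit); single-species fits drop the composition constraint.
#' @param init_fields Starting [field_vector()]; defaults to a heuristic
#'   near the lattice-gas critical point with ideal-solution chemical
#'   potentials.
#' @param n_range Biased range of total N; defaults to `[0.02 V, 0.98 V]`.
#' @param schedule Production schedule per outer iteration (see
#'   [run_gcmc()]).
#' @param bias_opts Extra arguments passed to [build_bias()] for the first
#'   (full Wang-Landau) build.
#' @param tol Outer convergence tolerance on `beta_eps*`.
#' @param max_outer,min_outer Outer iteration bounds.
#' @param chi2_dof_max Flag the result non-converged when the final
#'   chi-squared per degree of freedom exceeds this.
#' @param n_starts Multi-start count for the inner simplex minimization.
#' @param n_boot Bootstrap resamples for the `beta_eps*` uncertainty.
#' @param ess_min Minimum ESS fraction accepted during reweighting.
#' @param q_c Chaperone insertion proposal probability.
#' @param keep_samples Attach the final sample table and weights (needed for
#'   critical-ensemble observables such as
#'   [chaperone_dimer_probability()]).
#' @param model A [model_spec()].
#' @param seed Optional integer seed.
#' @param verbose Print per-iteration progress.
#' @return A `critical_point` object; see Details.  Key fields:
#'   `beta_eps_star` with bootstrap `se`, the solved `fields`, the
#'   [mixing_solution()], achieved composition `x_c_hat` with `sigma_comp`,
#'   `chi2`, `chi2_dof`, `ess`, `skewness` of the matched distribution, and
#'   `converged`.
#' @export
find_critical_point <- function(fixed = list(beta_eps_ss = 0, beta_eps_cs = 0,
                                             beta_eps_cc = 0, x_c = NULL),
                                L = 12, dims = NULL, boundary = "periodic",
                                species = "both", init_fields = NULL,
                                n_range = NULL,
                                schedule = list(burnin = 2000, n_samples = 12000,
                                                spacing = 40),
                                bias_opts = list(), tol = 0.005,
                                max_outer = 12L, min_outer = 2L,
                                chi2_dof_max = 5, n_starts = 3L, n_boot = 16L,
                                ess_min = 0.02, q_c = 0.5,
                                keep_samples = FALSE,
                                model = model_spec(), seed = NULL,
                                verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  species <- match.arg(species, c("both", "client", "chaperone"))
  fixed <- utils::modifyList(list(beta_eps_ss = 0, beta_eps_cs = 0,
                                  beta_eps_cc = 0, x_c = NULL), fixed)
  x_c <- if (species == "both") fixed$x_c else NULL
  if (species == "both" && is.null(x_c))
    stop("two-species solves need a target x_c in `fixed`")
  dims <- .resolve_dims(L, dims, match.arg(boundary, c("periodic", "open")))
  V <- prod(dims)
  n_range <- as.integer(n_range %||% c(round(0.02 * V), round(0.98 * V)))

  if (is.null(init_fields)) {
    # patch bonds carry part of the cohesive energy, so the critical
    # isotropic coupling drops roughly linearly with the bond strengths;
    # this is only a starting guess, refined by the outer iteration
    bond <- fixed$beta_eps_ss +
      if (species == "both") fixed$beta_eps_cs * (fixed$x_c %||% 0) else 0
    eps0 <- 0.85 - 0.5 * bond
    mu0 <- -3 * max(eps0, 0.2) - log(24)
    init_fields <- field_vector(beta_eps = eps0,
                                beta_eps_ss = fixed$beta_eps_ss,
                                beta_eps_cs = fixed$beta_eps_cs,
                                beta_eps_cc = fixed$beta_eps_cc,
                                beta_mu_s = if (species == "chaperone") -30 else mu0,
                                beta_mu_c = if (species == "both")
                                  mu0 + log(x_c / (1 - x_c))
                                else if (species == "chaperone") mu0 else -30)
  }
  fields <- .as_field_vector(init_fields)

  bias_args <- utils::modifyList(
    list(dims = dims, boundary = boundary, species = species, q_c = q_c,
         n_range = n_range, model = model, strict = FALSE),
    bias_opts)
  bias <- do.call(build_bias, c(list(f = fields), bias_args))

  history <- data.frame(iter = integer(), beta_eps = numeric(),
                        chi2_dof = numeric(), ess = numeric())
  outer_converged <- FALSE
  samples <- NULL
  fit <- NULL

  for (it in seq_len(max_outer)) {
    samples <- run_gcmc(fields, bias = bias, schedule = schedule,
                        q_c = q_c, model = model)
    mix0 <- if (is.null(fit)) .init_mix(samples, fields, species) else fit$mix
    fit <- tryCatch(
      .fit_mixing(samples, fields, mix0, fixed, x_c, species,
                  n_starts = n_starts, ess_min = ess_min),
      error = function(e) {
        if (verbose) message("  outer ", it, ": fit error: ",
                             conditionMessage(e))
        NULL
      })
    if (is.null(fit)) {
      bias <- do.call(build_bias, c(list(f = fields), bias_args))
      next
    }
    d_eps <- abs(fit$fields[["beta_eps"]] - fields[["beta_eps"]])
    history <- rbind(history,
                     data.frame(iter = it, beta_eps = fit$fields[["beta_eps"]],
                                chi2_dof = as.numeric(fit$chi2) /
                                  max(attr(fit$chi2, "dof"), 1),
                                ess = attr(fit$chi2, "ess")))
    if (verbose)
      message(sprintf("  outer %d: beta_eps* = %+.4f (moved %.4f), chi2/dof = %.2f, ESS = %.0f",
                      it, fit$fields[["beta_eps"]], d_eps,
                      history$chi2_dof[it], history$ess[it]))
    if (fit$value > 50) {
      # the sample could not resolve a trustworthy optimum, but the
      # direction of the (unreliable) fit is still informative: step a
      # bounded distance toward it and re-simulate there, rather than
      # accepting the full move or stalling in place
      d_move <- fit$fields[["beta_eps"]] - fields[["beta_eps"]]
      step <- sign(d_move) * min(abs(d_move), 0.08)
      if (verbose)
        message(sprintf("  outer %d: fit unresolved, stepping beta_eps by %+.3f",
                        it, step))
      capped <- unclass(fit$fields)
      capped["beta_eps"] <- fields[["beta_eps"]] + step
      # retain the fitted potentials only if the coupling move was accepted
      # in full; otherwise keep the current ones (the bias shift and the
      # next symmetrization absorb the difference)
      if (abs(d_move) > 0.08) {
        capped["beta_mu_s"] <- fields[["beta_mu_s"]]
        capped["beta_mu_c"] <- fields[["beta_mu_c"]]
      }
      fit <- NULL
      new_fields <- do.call(field_vector, as.list(capped))
      bias <- .shift_bias(bias, samples, new_fields)
      bias$state <- attr(samples, "state")
      bias <- do.call(build_bias,
                      c(list(f = new_fields),
                        utils::modifyList(bias_args,
                                          list(eta0 = unname(bias$eta),
                                               wl = FALSE, init = bias$state,
                                               refine_passes = 1L))))
      fields <- new_fields
      next
    }
    new_fields <- fit$fields
    if (species == "both") {
      # mass-action feedback: whatever composition the fit could not reach
      # by reweighting is corrected through the chaperone potential before
      # the next simulation
      x_hat_it <- attr(fit$chi2, "x_hat")[["c"]]
      if (is.finite(x_hat_it) && x_hat_it > 0 && x_hat_it < 1) {
        dmu_corr <- log(x_c / (1 - x_c)) - log(x_hat_it / (1 - x_hat_it))
        dmu_corr <- max(min(dmu_corr, 1.5), -1.5)
        f2 <- unclass(new_fields)
        f2["beta_mu_c"] <- f2["beta_mu_c"] + dmu_corr
        new_fields <- do.call(field_vector, as.list(f2))
      }
    }
    converged_now <- it >= min_outer && d_eps < tol
    if (converged_now) { fields <- new_fields; outer_converged <- TRUE; break }
    bias <- .shift_bias(bias, samples, new_fields)
    bias$state <- attr(samples, "state")
    bias <- do.call(build_bias,
                    c(list(f = new_fields),
                      utils::modifyList(bias_args,
                                        list(eta0 = unname(bias$eta), wl = FALSE,
                                             init = bias$state,
                                             refine_passes = 1L))))
    fields <- new_fields
  }

  if (is.null(fit))
    stop("critical-point solve failed: no fit iteration succeeded")
  # bootstrap uncertainty on beta_eps* from the final sample table
  boot <- rep(NA_real_, n_boot)
  n <- nrow(samples)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    sb <- samples[idx, ]
    for (a in c("fields", "dims", "boundary", "species", "schedule"))
      attr(sb, a) <- attr(samples, a)
    class(sb) <- class(samples)
    fb <- tryCatch(.fit_mixing(sb, fields, fit$mix, fixed, x_c, species,
                               n_starts = 1L, ess_min = ess_min, maxit = 150L,
                               light = TRUE),
                   error = function(e) NULL)
    if (!is.null(fb)) boot[b] <- fb$fields[["beta_eps"]]
  }
  se_boot <- stats::sd(boot, na.rm = TRUE)
  if (!is.finite(se_boot)) se_boot <- 0   # fewer than two bootstrap refits
  # Near its resolution limit the outer loop oscillates around the fixed
  # point rather than meeting the tolerance; the tail of the iteration
  # history is then a set of noisy draws of the answer, so a non-converged
  # solve reports their mean, and the scatter enters the error either way.
  eps_star <- unname(fields[["beta_eps"]])
  se_outer <- 0
  if (nrow(history) >= 3) {
    k <- min(5L, nrow(history))
    tail_eps <- utils::tail(history$beta_eps, k)
    if (outer_converged) {
      se_outer <- stats::sd(utils::tail(history$beta_eps, 3))
    } else {
      eps_star <- mean(tail_eps)
      # the tail iterates are a strongly correlated walk, not iid draws:
      # the full tail scatter, not scatter/sqrt(k), matches the observed
      # run-to-run reproducibility of the tail mean
      se_outer <- stats::sd(tail_eps)
    }
  }
  se <- sqrt(se_boot^2 + se_outer^2)

  chi2 <- fit$chi2
  dof <- max(attr(chi2, "dof"), 1)
  chi2_dof <- as.numeric(chi2) / dof
  rw <- reweight(samples, fields, warn_ess = FALSE)
  u <- sample_energy(samples, fields) / V
  M <- ordering_operator(samples$n_s / V, samples$n_c / V, u, fit$mix)
  skew <- .weighted_skewness(M, rw$w)
  x_hat <- attr(chi2, "x_hat")
  sig <- attr(chi2, "sigma_comp")
  comp_ok <- if (is.null(x_c)) TRUE else
    abs(x_hat[["c"]] - x_c) <= 2 * sqrt(sig[["c"]])
  converged <- outer_converged && chi2_dof <= chi2_dof_max && comp_ok
  if (!converged)
    warning(sprintf(paste0("critical-point solve flagged non-converged ",
                           "(outer %s, chi2/dof = %.2f, composition %s)"),
                    if (outer_converged) "ok" else "not converged",
                    chi2_dof, if (comp_ok) "ok" else "off-target"))

  out <- list(beta_eps_star = eps_star, se = se,
              se_boot = se_boot, se_outer = se_outer,
              fields = fields, mixing = fit$mix,
              fixed = fixed, x_c_target = x_c,
              x_c_hat = unname(x_hat[["c"]]), sigma_comp = sig,
              chi2 = as.numeric(chi2), dof = dof, chi2_dof = chi2_dof,
              ess = attr(chi2, "ess"),
              bins_used = attr(chi2, "bins_used"),
              excluded_bins = attr(chi2, "excluded_bins"),
              skewness = skew, iterations = nrow(history), history = history,
              converged = converged, outer_converged = outer_converged,
              L = dims[1], dims = dims, species = species,
              n_samples = n, seed = seed,
              version = as.character(utils::packageVersion("latmix")))
  if (keep_samples) { out$samples <- samples; out$weights <- rw }
  class(out) <- "critical_point"
  out
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("critical point (L = %d, species = %s)%s\n", x$L, x$species,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  beta_eps* = %+.4f +/- %.4f\n", x$beta_eps_star, x$se))
  cat(sprintf("  nu = (%.3f, %.3f), s = %+.4f, Lambda = %.2f\n",
              x$mixing$nu_s, x$mixing$nu_c, x$mixing$s, x$mixing$Lambda))
  if (!is.null(x$x_c_target))
    cat(sprintf("  x_c = %.4f (target %.4f)\n", x$x_c_hat, x$x_c_target))
  cat(sprintf("  chi2/dof = %.2f (%d bins, %d excluded), ESS = %.0f of %d\n",
              x$chi2_dof, x$bins_used, x$excluded_bins, x$ess, x$n_samples))
  invisible(x)
}

#' Calibrate the client-client bond strength
#'
#' Scans `beta_eps_ss` upward until the client-only solution demixes at
#' negative isotropic interaction (`beta_eps* < 0`), i.e. until directional
#' interactions alone are strong enough to drive aggregation of a
#' concentrated client solution in a well-screened solvent.  The first value
#' crossing the threshold is returned as the calibrated bond strength for
#' chaperone-client production runs.
#'
#' @param e_values Candidate `beta_eps_ss` values, scanned in order.
#' @param L Lattice size for the calibration solves.
#' @param target Threshold on `beta_eps*` (default 0).
#' @param ... Passed to [find_critical_point()] (schedules etc.).
#' @param seed Optional integer seed.
#' @return List with the calibrated `beta_eps_ss`, the scan `trace`
#'   (a data frame of `beta_eps_ss` and solved `beta_eps_star`), and the
#'   critical-point objects.
#' @export
calibrate_ss <- function(e_values = seq(1.5, 5, by = 0.5), L = 8,
                         target = 0, ..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trace <- data.frame(beta_eps_ss = numeric(), beta_eps_star = numeric(),
                      se = numeric(), converged = logical())
  pts <- list()
  init <- NULL
  chosen <- NA_real_
  for (e in e_values) {
    cp <- find_critical_point(fixed = list(beta_eps_ss = e),
                              L = L, species = "client",
                              init_fields = init, ...)
    init <- cp$fields
    trace <- rbind(trace, data.frame(beta_eps_ss = e,
                                     beta_eps_star = cp$beta_eps_star,
                                     se = cp$se, converged = cp$converged))
    pts[[as.character(e)]] <- cp
    if (cp$beta_eps_star < target) { chosen <- e; break }
  }
  if (is.na(chosen))
    warning("no scanned beta_eps_ss drove beta_eps* below the threshold")
  list(beta_eps_ss = chosen, trace = trace, points = pts)
}
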