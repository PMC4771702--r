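# fss_critical: Wilding-Bruce mixed-field finite-size scaling.
#
# The ordering operator M = nu_s rho_s + nu_c rho_c - s u mixes the two
# number densities and the energy density; at a critical point the
# distribution of the scaled, centred deviation delta_M = Lambda (M - M*)
# collapses onto the universal 3D-Ising ordering distribution p*.  A
# chi-squared objective compares the sampled (reweighted) histogram with p*
# and constrains the mixture composition; minimizing it over the trial
# fields and mixing parameters locates the critical point.

#' Universal 3D-Ising critical ordering distribution
#'
#' The fixed, symmetric, bimodal density of the scaled ordering operator in
#' the three-dimensional Ising universality class, implemented from the
#' exponential-of-quartic parametric fit
#' `p(y) ~ exp(-(y^2 - 1)^2 (a y^2 + c))` with `a = 0.158`, `c = 0.776`,
#' rescaled by quadrature to unit integral and unit variance.
#'
#' @param x Numeric vector of scaled ordering deviations.
#' @return Density values `p*(x)`.
#' @examples
#' integrate(ising_ordering_density, -Inf, Inf)$value   # 1
#' @export
ising_ordering_density <- function(x) {
  cst <- .latmix_env$ising_cst
  if (is.null(cst)) {
    g <- function(y) exp(-(y^2 - 1)^2 * (0.158 * y^2 + 0.776))
    norm <- stats::integrate(g, -Inf, Inf, rel.tol = 1e-10)$value
    m2 <- stats::integrate(function(y) y^2 * g(y), -Inf, Inf,
                           rel.tol = 1e-10)$value / norm
    cst <- list(norm = norm, sd = sqrt(m2))
    .latmix_env$ising_cst <- cst
  }
  y <- x * cst$sd
  cst$sd * exp(-(y^2 - 1)^2 * (0.158 * y^2 + 0.776)) / cst$norm
}

#' Field-mixing parameters of the ordering operator
#'
#' @param nu_s,nu_c Components of the composition-difference direction; the
#'   constructor normalizes them to unit Euclidean length and fixes the sign
#'   gauge `nu_s >= 0` (flipping `(nu, s)` jointly, which leaves the
#'   ordering distribution invariant up to reflection).
#' @param s Energy field-mixing parameter.
#' @param Lambda Positive system-dependent scaling constant mapping `M - M*`
#'   onto the unit-variance universal variable.
#' @param M_star Ensemble mean of M (filled in by the histogram code).
#' @return A `mixing_solution` list.
#' @export
mixing_solution <- function(nu_s, nu_c, s = 0, Lambda = 1, M_star = NA_real_) {
  len <- sqrt(nu_s^2 + nu_c^2)
  if (len == 0) stop("nu must be non-zero")
  nu_s <- nu_s / len; nu_c <- nu_c / len
  if (nu_s < 0 || (nu_s == 0 && nu_c < 0)) {
    nu_s <- -nu_s; nu_c <- -nu_c; s <- -s
  }
  if (Lambda <= 0) stop("Lambda must be positive")
  structure(list(nu_s = nu_s, nu_c = nu_c, s = s, Lambda = Lambda,
                 M_star = M_star),
            class = "mixing_solution")
}

#' Ordering operator M
#'
#' `M = nu_s rho_s + nu_c rho_c - s u`, the linear combination of the two
#' number densities and the energy density whose critical distribution is
#' universal.
#'
#' @param rho_s,rho_c,u Observables (vectors of equal length).
#' @param mix A [mixing_solution()] (or any list with `nu_s`, `nu_c`, `s`).
#' @return Numeric vector of M values.
#' @export
ordering_operator <- function(rho_s, rho_c, u, mix) {
  mix$nu_s * rho_s + mix$nu_c * rho_c - mix$s * u
}

#' Weighted marginal distribution of the ordering operator
#'
#' Bins the per-snapshot ordering-operator values into bins of width
#' `L^-3` (the granularity of the density-like part of M), centred on the
#' weighted mean M*, and normalizes the bin masses to unit total.  In the
#' scaled variable `delta_M = Lambda (M - M*)` the bin masses estimate
#' `p*(delta_M) * Lambda * L^-3`.
#'
#' @param samples A `sample_table`.
#' @param weights A `sample_weights` from [reweight()], a bare numeric
#'   vector, or `NULL` for equal weights.
#' @param mix A [mixing_solution()].
#' @param f Fields at which to evaluate the energy density; defaults to the
#'   sample table's generating fields.
#' @return An `ordering_histogram`: data frame with bin index `k`, centre
#'   `m` (in M - M* units), scaled centre `delta_m`, normalized `mass`,
#'   Eq-4 error `sigma2` and occupancy `count`; the weighted mean `M_star`,
#'   bin width and sample count are attributes.
#' @export
ordering_histogram <- function(samples, weights = NULL, mix,
                               f = attr(samples, "fields")) {
  w <- if (is.null(weights)) rep(1, nrow(samples))
       else if (inherits(weights, "sample_weights")) weights$w
       else as.numeric(weights)
  if (length(w) != nrow(samples)) stop("weights do not align with samples")
  if (nrow(samples) == 0 || sum(w) <= 0) stop("all-zero weight mass")
  V <- prod(attr(samples, "dims"))
  u <- sample_energy(samples, f) / V
  M <- ordering_operator(samples$n_s / V, samples$n_c / V, u, mix)
  wn <- w / sum(w)
  M_star <- sum(wn * M)
  m <- M - M_star
  k <- as.integer(round(m * V))
  agg <- rowsum(cbind(wn, wn^2, 1), group = k)
  kk <- as.integer(rownames(agg))
  n <- nrow(samples)
  mass <- agg[, 1]
  sigma2 <- agg[, 2] - mass^2 / n      # Eq-4 with weights normalized to sum 1
  out <- data.frame(k = kk, m = kk / V, delta_m = mix$Lambda * kk / V,
                    mass = unname(mass), sigma2 = unname(sigma2),
                    count = unname(agg[, 3]))
  out <- out[order(out$k), ]
  rownames(out) <- NULL
  attr(out, "M_star") <- M_star
  attr(out, "bin_width") <- 1 / V
  attr(out, "Lambda") <- mix$Lambda
  attr(out, "n_samples") <- n
  class(out) <- c("ordering_histogram", "data.frame")
  out
}

#' Per-bin sampling error of the weighted histogram
#'
#' The printed error formula
#' `sigma_k^2 = (sum_v w_v^2 1_kv - (sum_v w_v 1_kv)^2 / n) / sum_v w_v`,
#' evaluated verbatim on the supplied weights.  Note it is scale-covariant
#' in the weights (`w -> c w` gives `sigma^2 -> c sigma^2`); with weights
#' normalized to unit sum it equals the sampling variance of the bin mass.
#'
#' @param w Per-sample weights.
#' @param indicator Logical/0-1 vector marking membership of the bin.
#' @return The error estimate `sigma_k^2`.
#' @export
histogram_error <- function(w, indicator) {
  ind <- as.numeric(indicator)
  stopifnot(length(w) == length(ind), length(w) >= 1)
  (sum(w^2 * ind) - sum(w * ind)^2 / length(w)) / sum(w)
}

#' Error of the observed composition
#'
#' `sigma_i^2 = (1/phi^2) sum_jk (delta_ij - rho_i/phi) <drho_j drho_k>
#'  (delta_ik - rho_i/phi)` with `phi = rho_s + rho_c`, evaluated from the
#' weighted means and covariance of the snapshot densities (or from moments
#' supplied directly).
#'
#' @param samples A `sample_table` (ignored if `rho`/`rho_cov` given).
#' @param weights Weights as in [ordering_histogram()].
#' @param rho Optional named numeric `c(s = , c = )` of mean densities.
#' @param rho_cov Optional 2x2 covariance matrix of `(rho_s, rho_c)`.
#' @return Named numeric `c(s = sigma_s^2, c = sigma_c^2)`.
#' @export
composition_error <- function(samples = NULL, weights = NULL,
                              rho = NULL, rho_cov = NULL) {
  if (is.null(rho) || is.null(rho_cov)) {
    stopifnot(!is.null(samples))
    w <- if (is.null(weights)) rep(1, nrow(samples))
         else if (inherits(weights, "sample_weights")) weights$w
         else as.numeric(weights)
    V <- prod(attr(samples, "dims"))
    rs <- samples$n_s / V; rc <- samples$n_c / V
    rho <- c(s = weighted_mean(rs, w), c = weighted_mean(rc, w))
    rho_cov <- matrix(c(weighted_cov(rs, rs, w), weighted_cov(rs, rc, w),
                        weighted_cov(rs, rc, w), weighted_cov(rc, rc, w)), 2, 2)
  }
  phi <- sum(rho)
  if (phi <= 0) stop("no particles: phi = 0")
  out <- numeric(2)
  for (i in 1:2) {
    a <- -rho[i] / phi + (seq_len(2) == i)
    out[i] <- drop(a %*% rho_cov %*% a) / phi^2
  }
  stats::setNames(out, c("s", "c"))
}

#' Mixed-field matching objective
#'
#' The chi-squared function comparing the reweighted ordering-operator
#' histogram with the universal 3D-Ising density, plus the composition
#' constraint: bins with zero error estimate (empty bins) are excluded from
#' the first sum and their number reported; the second term compares the
#' achieved stoichiometric fractions with the targets `x_c` and
#' `x_s = 1 - x_c` and is omitted for single-species systems.
#'
#' @param samples A `sample_table` (typically a biased near-critical run).
#' @param trial List with `fields` (a [field_vector()]) and `mix` (a
#'   [mixing_solution()] or plain list).  When `mix$Lambda` is `NULL` the
#'   scale constant is profiled out self-consistently as the inverse
#'   weighted standard deviation of M (the value that maps the sampled
#'   fluctuations onto the unit-variance universal form); the profiled
#'   value is reported in the `Lambda` attribute.
#' @param x_c Target chaperone stoichiometric fraction, or `NULL` to omit
#'   the composition constraint.
#' @param ess_min Minimum acceptable ESS as a fraction of the sample count.
#' @param on_low_ess `"error"` (default, instructing a new simulation closer
#'   to the trial point) or `"penalty"` (return a large finite value so
#'   optimizers back away).
#' @param n_eff_min Minimum effective occupancy for a bin to enter the
#'   Eq-4-weighted sum; below it the bin is charged at the one-sample
#'   resolution floor (see the source comment).
#' @return The chi-squared value, with attributes `hist_term`, `comp_term`,
#'   `bins_used`, `excluded_bins`, `ess`, `M_star`, `x_hat`, `sigma_comp`
#'   and `dof` (bins + composition terms - fitted parameters).
#' @export
chi_squared <- function(samples, trial, x_c = NULL, ess_min = 0.02,
                        on_low_ess = c("error", "penalty"), n_eff_min = 8) {
  on_low_ess <- match.arg(on_low_ess)
  f <- .as_field_vector(trial$fields)
  mix <- trial$mix
  n <- nrow(samples)
  rw <- reweight(samples, f, warn_ess = FALSE)
  if (rw$ess < ess_min * n) {
    if (on_low_ess == "penalty")
      return(structure(1e8 * (1 + ess_min * n / max(rw$ess, 1e-6)), ess = rw$ess))
    stop(sprintf(paste0("ESS %.1f below %.0f%% of %d samples when reweighting; ",
                        "run a new simulation closer to the trial fields"),
                 rw$ess, 100 * ess_min, n))
  }
  if (is.null(mix$Lambda)) {
    V0 <- prod(attr(samples, "dims"))
    u0 <- sample_energy(samples, f) / V0
    M0 <- ordering_operator(samples$n_s / V0, samples$n_c / V0, u0, mix)
    wn0 <- rw$w / sum(rw$w)
    v0 <- sum(wn0 * M0^2) - sum(wn0 * M0)^2
    mix$Lambda <- if (v0 > 0) 1 / sqrt(v0) else 1
  }
  h <- ordering_histogram(samples, rw, mix, f = f)
  V <- prod(attr(samples, "dims"))
  Lam <- mix$Lambda
  q <- Lam * ising_ordering_density(Lam * h$m) / V
  # Eq-4 error bars are only meaningful where a bin holds appreciable
  # effective sampling mass; below that the estimated sigma_k^2 is itself
  # noise and single terms can dominate the sum by many orders of
  # magnitude.  The sum therefore runs over bins whose effective occupancy
  # mass_k * ESS reaches `n_eff_min`; the rest -- near-empty tails and any
  # interior holes -- are reported in `excluded_bins` as sampling-limited.
  well <- h$sigma2 > 0 & h$mass * rw$ess >= n_eff_min
  hist_term <- sum((h$mass[well] - q[well])^2 / h$sigma2[well])
  excluded <- (max(h$k) - min(h$k) + 1L) - sum(well)
  comp_term <- 0
  x_hat <- c(s = NA_real_, c = NA_real_)
  sig <- c(s = NA_real_, c = NA_real_)
  n_comp <- 0L
  if (!is.null(x_c)) {
    wn <- rw$w / sum(rw$w)
    rho <- c(s = sum(wn * samples$n_s) / V, c = sum(wn * samples$n_c) / V)
    phi <- sum(rho)
    if (phi <= 0) stop("no particles at the trial point")
    sig <- composition_error(samples, rw)
    x_hat <- rho / phi
    targ <- c(s = 1 - x_c, c = x_c)
    comp_term <- sum((x_hat - targ)^2 / sig)
    n_comp <- 2L
  }
  n_par <- if (is.null(x_c)) 4L else 6L
  structure(hist_term + comp_term,
            hist_term = hist_term, comp_term = comp_term,
            bins_used = sum(well), excluded_bins = excluded,
            ess = rw$ess, M_star = attr(h, "M_star"), Lambda = Lam,
            x_hat = x_hat, sigma_comp = sig,
            dof = sum(well) + n_comp - n_par)
}
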