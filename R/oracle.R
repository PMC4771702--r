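# oracle_enum: brute-force truncated grand-canonical enumeration on tiny
# open-boundary lattices, used to validate energies, sampling, reweighting
# and the error formulas.  The oracle shares the compiled energy
# implementation with the engine, so agreement tests isolate sampling
# correctness rather than energy bookkeeping.

#' Exact truncated grand-canonical enumeration
#'
#' Enumerates every placement of at most `n_max` monomers (allowed species
#' times 24 orientations per site) on a tiny lattice, with exact energies
#' and grand-canonical weights, and reports the truncated partition sum,
#' exact averages and the particle-number distribution.  The neglected
#' weight mass of states with `N > n_max` is bounded by an ideal-gas-style
#' tail estimate and reported; exact averages carry that bound as their
#' systematic error relative to the untruncated ensemble.
#'
#' @param dims Lattice extents (kept tiny; the state count grows as
#'   `sum_k C(V,k) A^k` with `A` allowed states per site).
#' @param n_max Particle-number truncation.
#' @param f A [field_vector()].
#' @param boundary `"open"` (default, avoiding the periodic small-lattice
#'   double-bond artifact) or `"periodic"`.
#' @param species Allowed species, as in [run_gcmc()].
#' @param state_budget Abort if the enumeration would exceed this many
#'   states.
#' @param model A [model_spec()].
#' @return A `truncated_ensemble`: exact `log_z`, means of `N_s`, `N_c`,
#'   `U`, the contact counts, the distribution `p_n` over `0..n_max`, the
#'   visited `n_states` and the relative `truncation_bound`.
#' @export
enumerate_grand_partition <- function(dims, n_max, f, boundary = "open",
                                      species = "both", state_budget = 1e7,
                                      model = model_spec()) {
  f <- .as_field_vector(f)
  boundary <- match.arg(boundary, c("open", "periodic"))
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), n_max >= 0)
  res <- cpp_enumerate(dims, boundary == "periodic", model$patch_mask,
                       unclass(f), .species_mode(species), as.integer(n_max),
                       state_budget)
  V <- prod(dims)
  A <- if (species == "both") 48 else 24
  mu_max <- switch(species,
                   both = max(f[["beta_mu_s"]], f[["beta_mu_c"]]),
                   client = f[["beta_mu_s"]], chaperone = f[["beta_mu_c"]])
  # per-particle weight bound: <= 6 new contacts, each at most the most
  # attractive pair energy
  e_gain <- 6 * (max(f[["beta_eps"]], 0) +
                   max(f[["beta_eps_ss"]], f[["beta_eps_cs"]], f[["beta_eps_cc"]]))
  lam <- V * A * exp(mu_max + e_gain)
  tail <- if (lam < n_max + 2) {
    lead <- exp((n_max + 1) * log(lam) - lgamma(n_max + 2))
    lead / (1 - lam / (n_max + 2))
  } else Inf
  bound <- tail / exp(res$log_z)
  structure(c(res, list(truncation_bound = bound, dims = dims,
                        boundary = boundary, species = species,
                        n_max = n_max, fields = f)),
            class = "truncated_ensemble")
}

#' @export
print.truncated_ensemble <- function(x, ...) {
  cat(sprintf("truncated grand-canonical ensemble: %d x %d x %d (%s), N <= %d, %d states\n",
              x$dims[1], x$dims[2], x$dims[3], x$boundary, x$n_max,
              as.integer(x$n_states)))
  cat(sprintf("  <N_s> = %.6f, <N_c> = %.6f, <U> = %.6f, <n_cc> = %.6f\n",
              x$mean_n_s, x$mean_n_c, x$mean_u, x$mean_n_cc))
  cat(sprintf("  relative truncation bound: %.3g\n", x$truncation_bound))
  invisible(x)
}

#' Validate the GCMC engine against exact enumeration
#'
#' Runs the sampling engine on the identical truncated system (same open
#' boundaries, hard cap `N <= n_max`, no bias) and compares `<N_s>`,
#' `<N_c>`, `<U>`, `<n_cc>` and the full particle-number distribution
#' `p(N)` against the exact enumeration.  A comparison passes when the
#' deviation is below `tol_se` batch-means standard errors (plus a small
#' absolute floor).  Failures are reported in the returned table, not
#' thrown.
#'
#' @inheritParams enumerate_grand_partition
#' @param schedule Sampling schedule, see [run_gcmc()].
#' @param tol_se Tolerance in standard errors.
#' @param seed Optional integer seed.
#' @return A `sampler_validation`: data frame `comparison` (observable,
#'   exact, estimate, se, ok), overall `pass`, the engine acceptance rates
#'   and the oracle truncation bound.
#' @export
validate_sampler <- function(dims, n_max, f, species = "both",
                             schedule = list(burnin = 500, n_samples = 4000,
                                             spacing = 5),
                             tol_se = 3, state_budget = 1e7,
                             model = model_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  exact <- enumerate_grand_partition(dims, n_max, f, boundary = "open",
                                     species = species,
                                     state_budget = state_budget, model = model)
  samp <- run_gcmc(f, L = NULL, dims = dims, boundary = "open",
                   species = species, schedule = schedule, n_cap = n_max,
                   model = model)
  u <- sample_energy(samp)
  N <- samp$n_s + samp$n_c
  obs <- list(mean_n_s = samp$n_s, mean_n_c = samp$n_c,
              mean_u = u, mean_n_cc = samp$n_cc)
  rows <- lapply(names(obs), function(nm) {
    x <- obs[[nm]]
    data.frame(observable = nm, exact = exact[[nm]], estimate = mean(x),
               se = batch_se(x))
  })
  for (k in 0:n_max) {
    ind <- as.numeric(N == k)
    # rare states: the batch-means error collapses when a batch holds a
    # handful of correlated visits, so the binomial error at the exact
    # probability provides a floor
    pk <- exact$p_n[k + 1]
    floor_se <- sqrt(pk * (1 - pk) / length(ind))
    rows[[length(rows) + 1]] <-
      data.frame(observable = sprintf("p_n[%d]", k), exact = pk,
                 estimate = mean(ind), se = max(batch_se(ind), floor_se))
  }
  cmp <- do.call(rbind, rows)
  cmp$ok <- abs(cmp$estimate - cmp$exact) <= tol_se * cmp$se + 1e-9
  out <- list(comparison = cmp, pass = all(cmp$ok),
              acceptance = attr(samp, "acceptance"),
              truncation_bound = exact$truncation_bound,
              n_samples = nrow(samp), dims = dims, n_max = n_max,
              fields = .as_field_vector(f), species = species)
  class(out) <- "sampler_validation"
  out
}

#' @export
print.sampler_validation <- function(x, ...) {
  cat(sprintf("sampler validation on %d x %d x %d, N <= %d: %s\n",
              x$dims[1], x$dims[2], x$dims[3], x$n_max,
              if (x$pass) "PASS" else "FAIL"))
  print(x$comparison, digits = 4)
  invisible(x)
}
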