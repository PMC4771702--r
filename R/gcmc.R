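# gcmc_engine: biased grand-canonical Monte Carlo sampling.
#
# The sampled measure is pi(config) ~ exp(-E + beta_mu_s N_s + beta_mu_c N_c
# + eta(N)) with N = N_s + N_c; eta is the flat-histogram bias built by
# Wang-Landau iteration plus a fixed-weight refinement pass.  Moves: paired
# insert/delete (equal probability), nonlocal translation and rotation.

.species_mode <- function(species) {
  switch(match.arg(species, c("both", "client", "chaperone")),
         both = 0L, client = 1L, chaperone = 2L)
}

.move_probs <- function(moves) {
  m <- utils::modifyList(list(insert_delete = 0.4, translate = 0.4, rotate = 0.2),
                         moves %||% list())
  p <- c(m$insert_delete / 2, m$insert_delete / 2, m$translate, m$rotate)
  if (abs(sum(p) - 1) > 1e-12) stop("move proposal probabilities must sum to 1")
  p
}

.resolve_dims <- function(L, dims, boundary) {
  if (is.null(dims)) dims <- c(L, L, L)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  if (boundary == "periodic" && any(dims < 3))
    stop("periodic boundaries require every extent >= 3")
  dims
}

#' Build flat-histogram bias weights over total particle number
#'
#' Wang-Landau iteration with a halving modification factor flattens the
#' sampled distribution of the total particle number N over `n_range`,
#' followed by fixed-weight refinement passes that polish the weights from a
#' visit histogram.  The returned weights are frozen before production use.
#'
#' @param f A [field_vector()].
#' @param L,dims,boundary Lattice geometry as in [lattice_config()].
#' @param species `"both"`, `"client"` or `"chaperone"` (which species may
#'   be inserted).
#' @param q_c Proposal probability of inserting a chaperone when both
#'   species are allowed.
#' @param n_range Integer range `c(n_lo, n_hi)` of total N to cover;
#'   defaults to the full `0..V`.
#' @param lnf_init,lnf_final Initial and terminal Wang-Landau modification
#'   factors (natural log units).
#' @param flat_tol Histogram flatness criterion: every N visited and the
#'   minimum at least `flat_tol` times the mean.
#' @param check_sweeps Sweeps between flatness checks (1 sweep = V attempted
#'   moves); default scales with the width of `n_range`.
#' @param max_sweeps Hard cap on Wang-Landau sweeps.
#' @param refine_sweeps,refine_passes Fixed-weight refinement schedule.
#' @param eta0 Optional starting weights (e.g. from a previous build at
#'   nearby fields); must span `n_range`.
#' @param wl If `FALSE`, skip the Wang-Landau stage and only refine `eta0`.
#' @param init Optional initial configuration (a [lattice_config()] or the
#'   `state` of a previous run).
#' @param moves Move-mix overrides, see [run_gcmc()].
#' @param model A [model_spec()].
#' @param seed Optional integer seed (`set.seed` is called if supplied).
#' @param strict If `TRUE` (default), failure to converge is an error with
#'   diagnostics; otherwise a warning, and the partial weights are returned
#'   flagged as non-converged.
#' @return A `bias_function`: weights `eta` named by N over `n_range`, plus
#'   convergence diagnostics and the generating fields.
#' @export
build_bias <- function(f, L = NULL, dims = NULL, boundary = "periodic",
                       species = "both", q_c = 0.5, n_range = NULL,
                       lnf_init = 1.0, lnf_final = 1e-4, flat_tol = 0.7,
                       check_sweeps = NULL, max_sweeps = 1e6,
                       refine_sweeps = NULL, refine_passes = 2L,
                       eta0 = NULL, wl = TRUE, init = NULL, moves = NULL,
                       model = model_spec(), seed = NULL, strict = TRUE) {
  f <- .as_field_vector(f)
  boundary <- match.arg(boundary, c("periodic", "open"))
  dims <- .resolve_dims(L, dims, boundary)
  V <- prod(dims)
  if (!is.null(seed)) set.seed(seed)
  n_range <- as.integer(n_range %||% c(0L, V))
  stopifnot(length(n_range) == 2, n_range[1] >= 0, n_range[2] <= V,
            n_range[1] <= n_range[2])
  width <- n_range[2] - n_range[1] + 1L
  check_sweeps <- as.integer(check_sweeps %||% max(50L, ceiling(width / 2)))
  # the fixed-weight refinement must span many round trips of the
  # multicanonical random walk (traversal time ~ width^2 / D sweeps) or the
  # visit histogram it feeds on is one noisy excursion
  refine_sweeps <- as.integer(refine_sweeps %||%
                                max(2000, ceiling(50 * width^2 / V)))
  mp <- .move_probs(moves)
  init_state <- if (is.null(init)) integer(0) else as.integer(init)

  eta <- as.numeric(eta0 %||% numeric(0))
  if (length(eta) > 0 && length(eta) != width)
    stop("eta0 does not span n_range")
  converged <- TRUE
  sweeps_used <- 0L
  stages <- 0L
  state <- init_state

  if (wl) {
    res <- cpp_wl_bias(dims, boundary == "periodic", model$patch_mask,
                       unclass(f), .species_mode(species), q_c,
                       n_range[1], n_range[2],
                       if (length(eta)) eta else numeric(0),
                       lnf_init, lnf_final, flat_tol,
                       check_sweeps, as.integer(max_sweeps), init_state, mp)
    eta <- res$eta
    converged <- res$converged
    sweeps_used <- res$sweeps
    stages <- res$stages
    state <- res$state
  } else if (length(eta) == 0) {
    eta <- numeric(width)
  }

  # fixed-weight refinement: re-estimate the sampled p(N) and fold it in
  flatness <- NA_real_
  for (p in seq_len(refine_passes)) {
    run <- cpp_run_gcmc(dims, boundary == "periodic", model$patch_mask,
                        unclass(f), .species_mode(species), q_c,
                        n_range[1], n_range[2], eta,
                        burnin = min(200L, refine_sweeps %/% 4L),
                        n_samples = 1L, spacing = refine_sweeps,
                        init_state = state, move_probs = mp)
    h <- run$visits
    vis <- h > 0
    if (any(vis)) {
      lh <- log(h[vis])
      eta[vis] <- eta[vis] - (lh - mean(lh))  # unvisited N left untouched
    }
    eta <- eta - max(eta)
    state <- run$state
    flatness <- min(h) / mean(h)
  }

  if (!converged) {
    msg <- sprintf(paste0("bias construction did not converge: lnf stage %d ",
                          "after %d sweeps (width %d); increase max_sweeps"),
                   stages, sweeps_used, width)
    if (strict) stop(msg) else warning(msg)
  }

  structure(list(eta = stats::setNames(eta, n_range[1]:n_range[2]),
                 n_lo = n_range[1], n_hi = n_range[2],
                 converged = converged,
                 diagnostics = list(wl_sweeps = sweeps_used, wl_stages = stages,
                                    refine_passes = refine_passes,
                                    final_flatness = flatness),
                 fields = f, dims = dims, boundary = boundary,
                 species = species, q_c = q_c, state = state),
            class = "bias_function")
}

#' @export
print.bias_function <- function(x, ...) {
  cat(sprintf("flat-histogram bias over N in [%d, %d] (%s)\n",
              x$n_lo, x$n_hi, if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  Wang-Landau: %d sweeps, %d stages; refinement flatness %.2f\n",
              x$diagnostics$wl_sweeps, x$diagnostics$wl_stages,
              x$diagnostics$final_flatness))
  invisible(x)
}

#' Run biased grand-canonical Monte Carlo
#'
#' Samples the biased grand-canonical measure and records one snapshot of
#' the particle numbers and the four contact counts every `spacing` sweeps
#' after `burnin` sweeps.  The contact counts reproduce the configurational
#' energy exactly at any field vector, which is what makes the snapshots
#' reweightable; see [reweight()].
#'
#' @inheritParams build_bias
#' @param bias A `bias_function` from [build_bias()], or `NULL` for an
#'   unbiased run.
#' @param schedule List with `burnin`, `n_samples` and `spacing` (sweeps).
#' @param n_cap Optional hard upper bound on total N for unbiased runs
#'   (used by the enumeration-oracle validation, which samples the same
#'   truncated ensemble the oracle enumerates).
#' @return A `sample_table`: a data frame with one row per snapshot
#'   (`n_s`, `n_c`, `n_iso`, `n_ss`, `n_cs`, `n_cc`, `eta`) carrying the
#'   generating fields, geometry, schedule, bias, acceptance counters and an
#'   integrated autocorrelation estimate for N as attributes.
#' @export
run_gcmc <- function(f, bias = NULL, L = NULL, dims = NULL,
                     boundary = "periodic", species = "both", q_c = 0.5,
                     schedule = list(), n_cap = NULL, init = NULL,
                     moves = NULL, model = model_spec(), seed = NULL) {
  f <- .as_field_vector(f)
  if (!is.null(bias)) {
    dims <- bias$dims; boundary <- bias$boundary
    species <- bias$species; q_c <- bias$q_c
    n_lo <- bias$n_lo; n_hi <- bias$n_hi
    eta <- unname(bias$eta)
    if (is.null(init)) init <- bias$state
  } else {
    boundary <- match.arg(boundary, c("periodic", "open"))
    dims <- .resolve_dims(L, dims, boundary)
    n_lo <- 0L; n_hi <- as.integer(n_cap %||% prod(dims))
    eta <- numeric(n_hi - n_lo + 1L)
  }
  if (!is.null(seed)) set.seed(seed)
  sch <- utils::modifyList(list(burnin = 1000L, n_samples = 1000L, spacing = 10L),
                           schedule)
  stopifnot(sch$burnin >= 0, sch$n_samples >= 0, sch$spacing >= 1)
  mp <- .move_probs(moves)
  init_state <- if (is.null(init)) integer(0) else as.integer(init)

  res <- cpp_run_gcmc(dims, boundary == "periodic", model$patch_mask,
                      unclass(f), .species_mode(species), q_c,
                      n_lo, n_hi, eta,
                      as.integer(sch$burnin), as.integer(sch$n_samples),
                      as.integer(sch$spacing), init_state, mp)
  s <- res$samples
  tbl <- data.frame(n_s = s[, 1], n_c = s[, 2], n_iso = s[, 3],
                    n_ss = s[, 4], n_cs = s[, 5], n_cc = s[, 6],
                    eta = res$eta_v)
  acc <- data.frame(kind = c("insert", "delete", "translate", "rotate"),
                    attempts = res$attempts, accepts = res$accepts)
  attr(tbl, "fields") <- f
  attr(tbl, "dims") <- dims
  attr(tbl, "boundary") <- boundary
  attr(tbl, "species") <- species
  attr(tbl, "q_c") <- q_c
  attr(tbl, "n_range") <- c(n_lo, n_hi)
  attr(tbl, "eta_table") <- eta
  attr(tbl, "schedule") <- sch
  attr(tbl, "acceptance") <- acc
  attr(tbl, "visits") <- res$visits
  attr(tbl, "state") <- res$state
  attr(tbl, "seed") <- seed
  attr(tbl, "tau_int_n") <- if (nrow(tbl) > 0) tau_int(tbl$n_s + tbl$n_c) else NA_real_
  class(tbl) <- c("sample_table", "data.frame")
  tbl
}

#' @export
print.sample_table <- function(x, ...) {
  d <- attr(x, "dims")
  acc <- attr(x, "acceptance")
  cat(sprintf("sample_table: %d snapshots, %d x %d x %d (%s), species %s\n",
              nrow(x), d[1], d[2], d[3], attr(x, "boundary"), attr(x, "species")))
  cat(sprintf("  acceptance: %s\n",
              paste(sprintf("%s %.2f", acc$kind,
                            ifelse(acc$attempts > 0, acc$accepts / acc$attempts, NA)),
                    collapse = ", ")))
  cat(sprintf("  tau_int(N) ~ %.1f snapshots at spacing %d sweeps\n",
              attr(x, "tau_int_n"), attr(x, "schedule")$spacing))
  invisible(x)
}

#' Configurational energy of snapshots at arbitrary fields
#'
#' Reconstructs the total energy of each snapshot from its contact counts:
#' `U = -(beta_eps n_iso + beta_eps_ss n_ss + beta_eps_cs n_cs + beta_eps_cc n_cc)`.
#'
#' @param samples A `sample_table`.
#' @param f A [field_vector()]; defaults to the generating fields.
#' @return Numeric vector of energies.
#' @export
sample_energy <- function(samples, f = attr(samples, "fields")) {
  f <- .as_field_vector(f)
  -(f[["beta_eps"]] * samples$n_iso + f[["beta_eps_ss"]] * samples$n_ss +
      f[["beta_eps_cs"]] * samples$n_cs + f[["beta_eps_cc"]] * samples$n_cc)
}

#' Reweight snapshots to a different field vector
#'
#' Computes per-snapshot statistical weights in the grand-canonical ensemble
#' at `f_to`, starting from samples generated under the (possibly biased)
#' measure at their recorded fields:
#' `log w_v = sum_t Delta(coefficient_t) * count_t,v + Delta(beta_mu_s) N_s,v
#'  + Delta(beta_mu_c) N_c,v - eta_v`.
#' Weights are returned normalized to a maximum of 1, with the effective
#' sample size `ESS = (sum w)^2 / sum w^2`.
#'
#' @param samples A `sample_table`.
#' @param f_to Target [field_vector()].
#' @param warn_ess Warn when ESS drops below 10% of the sample count.
#' @return A `sample_weights` object: list with `w`, `log_w`, `ess`, `n`.
#' @export
reweight <- function(samples, f_to, warn_ess = TRUE) {
  f_from <- .as_field_vector(attr(samples, "fields"))
  f_to <- .as_field_vector(f_to)
  d <- unclass(f_to) - unclass(f_from)
  bad <- names(d)[!is.finite(d)]
  if (length(bad))
    stop("non-finite field delta for: ", paste(bad, collapse = ", "))
  log_w <- d[["beta_eps"]] * samples$n_iso + d[["beta_eps_ss"]] * samples$n_ss +
    d[["beta_eps_cs"]] * samples$n_cs + d[["beta_eps_cc"]] * samples$n_cc +
    d[["beta_mu_s"]] * samples$n_s + d[["beta_mu_c"]] * samples$n_c -
    samples$eta
  if (!all(is.finite(log_w))) stop("non-finite log-weights in reweighting")
  w <- exp(log_w - max(log_w))
  ess <- sum(w)^2 / sum(w^2)
  n <- length(w)
  if (warn_ess && n > 0 && ess < 0.1 * n)
    warning(sprintf("effective sample size %.1f is below 10%% of %d samples; %s",
                    ess, n, "consider simulating closer to the target fields"))
  structure(list(w = w, log_w = log_w, ess = ess, n = n,
                 f_from = f_from, f_to = f_to),
            class = "sample_weights")
}

#' @export
print.sample_weights <- function(x, ...) {
  cat(sprintf("sample_weights: n = %d, ESS = %.1f (%.1f%%)\n",
              x$n, x$ess, 100 * x$ess / max(x$n, 1)))
  invisible(x)
}
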