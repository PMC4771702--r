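# observables_scan: critical-ensemble observables and parameter-space scans —
# the chaperone dimerization probability, the miscibility-limit surface
# beta_eps*(beta_eps_cs, x_c), its response functions, and the design window.

#' Chaperone dimerization probability at a critical point
#'
#' The critical-ensemble average `<p_cc>* = <2 n_cc / N_c>*`: the
#' probability that a chaperone binding interface is engaged with another
#' chaperone monomer.  Snapshots with `N_c = 0` are excluded (the ratio is
#' undefined there); their weight fraction is reported.
#'
#' @param samples A `sample_table` at (or reweightable to) the critical
#'   point.
#' @param weights A `sample_weights`, bare numeric weights, or `NULL` for
#'   equal weights.
#' @param n_boot Bootstrap resamples for the attached standard error.
#' @return The probability in `[0, 1]`, with attributes `se` and
#'   `excluded_weight` (weight fraction of `N_c = 0` snapshots).
#' @export
chaperone_dimer_probability <- function(samples, weights = NULL,
                                        n_boot = 200L) {
  w <- if (is.null(weights)) rep(1, nrow(samples))
       else if (inherits(weights, "sample_weights")) weights$w
       else as.numeric(weights)
  stopifnot(length(w) == nrow(samples))
  ok <- samples$n_c > 0
  if (!any(ok)) stop("every snapshot has N_c = 0; no chaperones to average over")
  excluded <- sum(w[!ok]) / sum(w)
  p <- 2 * samples$n_cc[ok] / samples$n_c[ok]
  wo <- w[ok]
  est <- sum(wo * p) / sum(wo)
  nb <- length(p)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(nb, nb, replace = TRUE)
    sum(wo[i] * p[i]) / sum(wo[i])
  }, numeric(1))
  structure(est, se = stats::sd(boot), excluded_weight = excluded)
}

#' Scan the critical surface over a (x_c, beta_eps_cs) grid
#'
#' Runs [find_critical_point()] for every grid node, warm-starting each
#' solve from the previously solved neighbour.  The chaperone-interaction
#' mode is either `"promiscuous"` (`beta_eps_cc = beta_eps_cs`) or
#' `"disabled"` (`beta_eps_cc = 0`).  Cell-level non-convergence is
#' recorded in the result and the scan continues.  When `out_dir` is given,
#' completed cells are persisted as JSON and a re-run resumes from them.
#'
#' @param x_c Chaperone stoichiometric fractions (strictly increasing).
#' @param beta_eps_cs Chaperone-client binding strengths (strictly
#'   increasing).
#' @param beta_eps_ss Fixed client-client bond strength (e.g. from
#'   [calibrate_ss()]).
#' @param mode `"promiscuous"` or `"disabled"`.
#' @param L Lattice size.
#' @param init_fields Optional starting fields for the first cell.  For an
#'   unassisted start, solve the client-only system first (e.g. the
#'   [calibrate_ss()] end point) and pass its fields with
#'   `beta_mu_c = beta_mu_s + log(x_c/(1-x_c))`: the `beta_eps_cs = 0`
#'   corner of the surface continues smoothly from the client-only
#'   instability, while a blind start can latch onto the condensation
#'   branch instead.
#' @param out_dir Optional checkpoint directory for resumable scans.
#' @param ... Passed to [find_critical_point()].
#' @param seed Optional integer seed.
#' @return A `critical_surface`: a data frame with one row per cell
#'   (`x_c`, `beta_eps_cs`, `mode`, `beta_eps_star`, `se`, `chi2_dof`,
#'   `p_cc`, `p_cc_se`, `x_c_hat`, `converged`), with the grid metadata as
#'   attributes.
#' @export
scan_critical_surface <- function(x_c, beta_eps_cs, beta_eps_ss,
                                  mode = c("promiscuous", "disabled"),
                                  L = 12, init_fields = NULL, out_dir = NULL,
                                  ..., seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(x_c) >= 1, length(beta_eps_cs) >= 1,
            !is.unsorted(x_c, strictly = TRUE),
            !is.unsorted(beta_eps_cs, strictly = TRUE))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  col_init <- init_fields
  for (xc in x_c) {
    init <- col_init
    for (ecs in beta_eps_cs) {
      tag <- sprintf("cell_x%0.4f_e%0.4f_%s", xc, ecs, mode)
      ckpt <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".json"))
      if (!is.null(out_dir) && file.exists(ckpt)) {
        row <- as.data.frame(jsonlite::read_json(ckpt, simplifyVector = TRUE))
        rows[[tag]] <- row
        init <- field_vector(beta_eps = row$beta_eps, beta_eps_ss = beta_eps_ss,
                             beta_eps_cs = ecs,
                             beta_eps_cc = if (mode == "promiscuous") ecs else 0,
                             beta_mu_s = row$beta_mu_s, beta_mu_c = row$beta_mu_c)
        if (ecs == beta_eps_cs[1]) col_init <- init
        next
      }
      fixed <- list(beta_eps_ss = beta_eps_ss, beta_eps_cs = ecs,
                    beta_eps_cc = if (mode == "promiscuous") ecs else 0,
                    x_c = xc)
      if (!is.null(init))
        init <- field_vector(beta_eps = init[["beta_eps"]],
                             beta_eps_ss = beta_eps_ss, beta_eps_cs = ecs,
                             beta_eps_cc = fixed$beta_eps_cc,
                             beta_mu_s = init[["beta_mu_s"]],
                             beta_mu_c = init[["beta_mu_c"]])
      cp <- tryCatch(
        withCallingHandlers(
          find_critical_point(fixed = fixed, L = L, species = "both",
                              init_fields = init, keep_samples = TRUE, ...),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      if (inherits(cp, "error")) {
        rows[[tag]] <- data.frame(x_c = xc, beta_eps_cs = ecs, mode = mode,
                                  beta_eps_star = NA_real_, se = NA_real_,
                                  chi2_dof = NA_real_, p_cc = NA_real_,
                                  p_cc_se = NA_real_, x_c_hat = NA_real_,
                                  beta_mu_s = NA_real_, beta_mu_c = NA_real_,
                                  converged = FALSE,
                                  note = conditionMessage(cp))
        next
      }
      pcc <- tryCatch(chaperone_dimer_probability(cp$samples, cp$weights),
                      error = function(e) structure(NA_real_, se = NA_real_))
      row <- data.frame(x_c = xc, beta_eps_cs = ecs, mode = mode,
                        beta_eps_star = cp$beta_eps_star, se = cp$se,
                        chi2_dof = cp$chi2_dof,
                        p_cc = as.numeric(pcc), p_cc_se = attr(pcc, "se"),
                        x_c_hat = cp$x_c_hat,
                        beta_mu_s = cp$fields[["beta_mu_s"]],
                        beta_mu_c = cp$fields[["beta_mu_c"]],
                        converged = cp$converged, note = "")
      rows[[tag]] <- row
      if (!is.null(out_dir))
        jsonlite::write_json(as.list(row), ckpt, auto_unbox = TRUE, digits = NA)
      init <- cp$fields
      if (ecs == beta_eps_cs[1]) col_init <- cp$fields
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  attr(grid, "axes") <- list(x_c = x_c, beta_eps_cs = beta_eps_cs)
  attr(grid, "beta_eps_ss") <- beta_eps_ss
  attr(grid, "mode") <- mode
  attr(grid, "L") <- L
  class(grid) <- c("critical_surface", "data.frame")
  grid
}

#' Response functions of the miscibility limit
#'
#' Finite-difference derivative of `beta_eps*` along a grid axis: central
#' differences in the interior, one-sided at the edges, with uncertainty
#' propagated from the per-node errors.
#'
#' @param grid A `critical_surface` (or data frame with `x_c`,
#'   `beta_eps_cs`, `beta_eps_star`, `se`).
#' @param axis `"x_c"` or `"beta_eps_cs"`.
#' @return Data frame of the grid with columns `deriv` (the requested
#'   `d beta_eps* / d axis`) and `deriv_se` added.
#' @export
response_function <- function(grid, axis = c("x_c", "beta_eps_cs")) {
  axis <- match.arg(axis)
  other <- setdiff(c("x_c", "beta_eps_cs"), axis)
  out <- lapply(split(as.data.frame(grid), grid[[other]]), function(g) {
    g <- g[order(g[[axis]]), ]
    x <- g[[axis]]; y <- g$beta_eps_star; e <- g$se
    if (length(x) < 3) stop("need at least 3 grid nodes along ", axis)
    if (is.unsorted(x, strictly = TRUE)) stop("non-monotone axis ", axis)
    n <- length(x)
    d <- dse <- numeric(n)
    for (i in seq_len(n)) {
      if (i == 1) {
        h <- x[2] - x[1]; d[i] <- (y[2] - y[1]) / h
        dse[i] <- sqrt(e[2]^2 + e[1]^2) / h
      } else if (i == n) {
        h <- x[n] - x[n - 1]; d[i] <- (y[n] - y[n - 1]) / h
        dse[i] <- sqrt(e[n]^2 + e[n - 1]^2) / h
      } else {
        h <- x[i + 1] - x[i - 1]; d[i] <- (y[i + 1] - y[i - 1]) / h
        dse[i] <- sqrt(e[i + 1]^2 + e[i - 1]^2) / h
      }
    }
    g$deriv <- d; g$deriv_se <- dse
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "axis") <- axis
  res
}

#' Chaperone design window
#'
#' Operationalizes the optimal-chaperone criterion: per chaperone fraction
#' `x_c`, the set of binding strengths `beta_eps_cs` at which both response
#' functions (`d beta_eps*/d x_c` and `d beta_eps*/d beta_eps_cs`) exceed
#' `frac` of their column maximum, together with the interval where the
#' chaperone dimerization probability `<p_cc>*` exceeds the same quantile,
#' and whether the two intervals overlap.
#'
#' @param grid A `critical_surface` with a `p_cc` column, covering at least
#'   3 nodes along each axis.
#' @param frac Quantile of the column maximum defining "maximized".
#' @return Data frame with one row per `x_c`: the `beta_eps_cs` ranges of
#'   the response window and of the `p_cc` window, and `overlap`.
#' @export
design_window <- function(grid, frac = 0.8) {
  r_ecs <- response_function(grid, "beta_eps_cs")
  r_xc <- response_function(grid, "x_c")
  key <- function(g) paste(g$x_c, g$beta_eps_cs)
  g <- as.data.frame(grid)
  g$d_ecs <- r_ecs$deriv[match(key(g), key(r_ecs))]
  g$d_xc <- r_xc$deriv[match(key(g), key(r_xc))]
  out <- lapply(split(g, g$x_c), function(col) {
    col <- col[order(col$beta_eps_cs), ]
    col <- col[is.finite(col$d_ecs) & is.finite(col$d_xc) &
                 is.finite(col$p_cc), ]
    if (nrow(col) < 2)
      return(data.frame(x_c = col$x_c[1] %||% NA_real_,
                        window_lo = NA_real_, window_hi = NA_real_,
                        p_cc_lo = NA_real_, p_cc_hi = NA_real_,
                        overlap = NA))
    both <- col$d_ecs >= frac * max(col$d_ecs) &
      col$d_xc >= frac * max(col$d_xc)
    pcc <- col$p_cc >= frac * max(col$p_cc)
    resp_rng <- if (any(both)) range(col$beta_eps_cs[both]) else c(NA_real_, NA_real_)
    pcc_rng <- range(col$beta_eps_cs[pcc])
    data.frame(x_c = col$x_c[1],
               window_lo = resp_rng[1], window_hi = resp_rng[2],
               p_cc_lo = pcc_rng[1], p_cc_hi = pcc_rng[2],
               overlap = !anyNA(resp_rng) &&
                 resp_rng[1] <= pcc_rng[2] && pcc_rng[1] <= resp_rng[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a critical surface as tidy CSV
#'
#' @param grid A `critical_surface`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_critical_surface <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Plot a miscibility-limit surface
#'
#' Miscibility limit `beta_eps*` against the chaperone-client binding
#' strength, one curve per chaperone fraction.  Requires ggplot2.
#'
#' @param grid A `critical_surface`.
#' @return A ggplot object.
#' @export
plot_critical_surface <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
  g <- as.data.frame(grid)
  g$x_c_f <- factor(g$x_c)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$beta_eps_cs,
                                  y = .data$beta_eps_star,
                                  colour = .data$x_c_f,
                                  shape = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$beta_eps_star - .data$se,
                                          ymax = .data$beta_eps_star + .data$se)) +
    ggplot2::labs(x = expression(beta * epsilon["c-s"]),
                  y = expression(beta * epsilon^"*"),
                  colour = expression(x[c]), shape = NULL) +
    ggplot2::theme_minimal()
}
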