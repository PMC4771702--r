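# model_core: the two-species patchy lattice model.
#
# Clients (species "client", internally s) carry three directional patches on
# mutually orthogonal faces of the unit cube; chaperones ("chaperone", c)
# carry a single patch.  Monomers occupy sites of a 3D lattice in one of the
# 24 proper rotations of the cube.  Adjacent monomers always share one
# isotropic contact of free energy -beta_eps; if both present a patch on the
# shared pair of faces they additionally form a directional bond of free
# energy -beta_eps_xy with xy in {s-s, c-s, c-c} by species pair.

.FACES <- c("+x", "-x", "+y", "-y", "+z", "-z")
.FACE_VECTORS <- cbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

#' The 24 proper rotations of the cube
#'
#' Enumerates the cubic rotation group as 3x3 integer matrices, generated by
#' closure from the 90-degree rotations about x and y.  The identity is the
#' first element; the remaining order is a fixed lexicographic canonical
#' order, so orientation indices are stable across sessions.
#'
#' @return A list of 24 integer 3x3 rotation matrices.
#' @export
orientation_table <- function() {
  if (!is.null(.latmix_env$orientations)) return(.latmix_env$orientations)
  rx <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)  # 90 deg about x
  ry <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)  # 90 deg about y
  seen <- list(diag(3))
  keys <- paste(diag(3), collapse = ",")
  queue <- seen
  while (length(queue) > 0) {
    m <- queue[[1]]; queue <- queue[-1]
    for (g in list(rx, ry)) {
      nm <- g %*% m
      key <- paste(nm, collapse = ",")
      if (!(key %in% keys)) {
        keys <- c(keys, key)
        seen <- c(seen, list(nm))
        queue <- c(queue, list(nm))
      }
    }
  }
  stopifnot(length(seen) == 24L)
  ident <- seen[[1]]
  rest <- seen[-1]
  ord <- order(vapply(rest, function(m) paste(sprintf("%+d", m), collapse = ""),
                      character(1)))
  out <- c(list(ident), rest[ord])
  out <- lapply(out, function(m) { storage.mode(m) <- "integer"; m })
  .latmix_env$orientations <- out
  out
}

.face_index <- function(v) {
  for (f in 1:6) if (all(v == .FACE_VECTORS[, f])) return(f)
  stop("not a face vector")
}

#' Model constants: patch geometry and orientation lookup table
#'
#' Defines the swappable model constants: which cube faces of the reference
#' orientation carry patches for each species, and the derived lookup table
#' mapping every (species, orientation) state to the faces that present a
#' patch.  The defaults are the three mutually orthogonal "corner" faces for
#' the client and a single face for the chaperone.
#'
#' @param client_faces Character vector of reference-orientation faces
#'   (subset of `"+x","-x","+y","-y","+z","-z"`) carrying client patches.
#'   Must have length 3.
#' @param chaperone_faces As above for the chaperone; length 1.
#' @return An object of class `latmix_model`: a list with the face sets, the
#'   orientation table, the 48 x 6 patch mask (rows are species * 24 +
#'   orientation states, columns faces) and `omega`, the number of
#'   species-orientation states per site (48).
#' @examples
#' m <- model_spec()
#' rowSums(m$patch_mask[1:24, ])   # clients present 3 patches in any orientation
#' @export
model_spec <- function(client_faces = c("+x", "+y", "+z"),
                       chaperone_faces = "+x") {
  stopifnot(length(client_faces) == 3L, length(chaperone_faces) == 1L,
            all(client_faces %in% .FACES), all(chaperone_faces %in% .FACES),
            !anyDuplicated(client_faces))
  ors <- orientation_table()
  mask <- matrix(0L, nrow = 48, ncol = 6,
                 dimnames = list(NULL, .FACES))
  for (o in 1:24) {
    R <- ors[[o]]
    for (f in match(client_faces, .FACES))
      mask[o, .face_index(R %*% .FACE_VECTORS[, f])] <- 1L
    for (f in match(chaperone_faces, .FACES))
      mask[24 + o, .face_index(R %*% .FACE_VECTORS[, f])] <- 1L
  }
  structure(list(client_faces = client_faces,
                 chaperone_faces = chaperone_faces,
                 orientations = ors,
                 patch_mask = mask,
                 omega = 48L),
            class = "latmix_model")
}

.species_code <- function(species) {
  match.arg(species, c("client", "chaperone"))
  if (species == "client") 0L else 1L
}

.state_code <- function(species, orientation) {
  stopifnot(orientation >= 1, orientation <= 24)
  .species_code(species) * 24L + as.integer(orientation) - 1L
}

#' Thermodynamic field vector
#'
#' The six dimensionless fields of the model: the orientationally averaged
#' nonspecific interaction `beta_eps` (unrestricted in sign; negative is
#' repulsive), the three directional patch energies (non-negative: the
#' directional interactions are always attractive), and the two chemical
#' potentials.  The chemical-potential convention is activity per site per
#' discrete species-orientation state, so an ideal solution has mean
#' occupancy `z * Omega / (1 + z * Omega)` per site with `z = exp(beta_mu)`
#' and `Omega` orientation states per species-resolved monomer.
#'
#' @param beta_eps Isotropic interaction strength (dimensionless, any sign).
#' @param beta_eps_ss,beta_eps_cs,beta_eps_cc Client-client, chaperone-client
#'   and chaperone-chaperone directional patch energies; must be `>= 0`.
#' @param beta_mu_s,beta_mu_c Dimensionless chemical potentials of clients
#'   and chaperones.
#' @return A classed named numeric vector of length 6.
#' @export
field_vector <- function(beta_eps = 0, beta_eps_ss = 0, beta_eps_cs = 0,
                         beta_eps_cc = 0, beta_mu_s = 0, beta_mu_c = 0) {
  f <- c(beta_eps = beta_eps, beta_eps_ss = beta_eps_ss,
         beta_eps_cs = beta_eps_cs, beta_eps_cc = beta_eps_cc,
         beta_mu_s = beta_mu_s, beta_mu_c = beta_mu_c)
  if (!all(is.finite(f))) stop("all fields must be finite")
  if (any(f[2:4] < 0))
    stop("directional energies beta_eps_ss, beta_eps_cs, beta_eps_cc must be non-negative")
  structure(f, class = "field_vector")
}

.as_field_vector <- function(f) {
  if (inherits(f, "field_vector")) return(f)
  if (is.numeric(f) && length(f) == 6) return(do.call(field_vector, as.list(f)))
  stop("expected a field_vector")
}

#' Empty lattice configuration
#'
#' @param L Linear size of a cubic lattice (ignored if `dims` given).
#' @param dims Integer vector of three extents.
#' @param boundary `"periodic"` or `"open"`.  Open boundaries exist for the
#'   enumeration oracle and its validation runs; production uses periodic
#'   boundaries with `L >= 3` (periodic `L <= 2` double-counts bonds through
#'   the boundary).
#' @return A `lat_config`: an integer site-state vector (-1 empty, otherwise
#'   `species * 24 + orientation - 1`) with dimension metadata.
#' @export
lattice_config <- function(L = NULL, dims = NULL, boundary = c("periodic", "open")) {
  boundary <- match.arg(boundary)
  if (is.null(dims)) dims <- c(L, L, L)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  if (boundary == "periodic" && any(dims < 3))
    stop("periodic boundaries require every extent >= 3; use boundary = \"open\"")
  structure(rep(-1L, prod(dims)),
            dims = dims, boundary = boundary, class = "lat_config")
}

.site_index <- function(cfg, at) {
  d <- attr(cfg, "dims")
  at <- as.integer(at)
  stopifnot(length(at) == 3, all(at >= 1), all(at <= d))
  (at[1] - 1L) + d[1] * ((at[2] - 1L) + d[2] * (at[3] - 1L)) + 1L
}

#' Place a monomer on a lattice configuration
#'
#' @param cfg A [lattice_config()].
#' @param at Integer site coordinates (1-based, length 3).
#' @param species `"client"` or `"chaperone"`.
#' @param orientation Orientation index, 1..24.
#' @return The updated configuration.
#' @export
place_monomer <- function(cfg, at, species, orientation = 1L) {
  i <- .site_index(cfg, at)
  if (cfg[i] >= 0) stop("site is already occupied")
  cfg[i] <- .state_code(species, orientation)
  cfg
}

#' @export
print.lat_config <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("lattice configuration %d x %d x %d (%s), N_s = %d, N_c = %d\n",
              d[1], d[2], d[3], attr(x, "boundary"),
              sum(x >= 0 & x < 24), sum(x >= 24)))
  invisible(x)
}

.direction_to_face <- function(direction) {
  direction <- as.integer(direction)
  if (length(direction) != 3 || sum(abs(direction)) != 1L)
    stop("direction must be a unit lattice step along one axis")
  .face_index(direction)
}

#' Pairwise contact energy of two adjacent monomers
#'
#' The isotropic term `-beta_eps` applies to every adjacent occupied pair;
#' a directional term `-beta_eps_xy` is added when monomer `a` presents a
#' patch on the face toward `b` and `b` presents a patch on the face toward
#' `a`, with `xy` determined by the species pair.
#'
#' @param a,b Lists with elements `species` and `orientation`.
#' @param direction Unit lattice step from `a` to `b` (e.g. `c(1, 0, 0)`).
#' @param f A [field_vector()].
#' @param model A [model_spec()].
#' @return Dimensionless contact energy (scalar).
#' @export
contact_energy <- function(a, b, direction, f, model = model_spec()) {
  f <- .as_field_vector(f)
  fa <- .direction_to_face(direction)
  fb <- .direction_to_face(-as.integer(direction))
  sta <- .state_code(a$species, a$orientation)
  stb <- .state_code(b$species, b$orientation)
  e <- -f[["beta_eps"]]
  if (model$patch_mask[sta + 1L, fa] == 1L && model$patch_mask[stb + 1L, fb] == 1L) {
    pair <- paste(sort(c(a$species, b$species)), collapse = "-")
    e <- e - switch(pair,
                    "client-client" = f[["beta_eps_ss"]],
                    "chaperone-client" = f[["beta_eps_cs"]],
                    "chaperone-chaperone" = f[["beta_eps_cc"]])
  }
  unname(e)
}

#' Total energy and contact counts of a configuration
#'
#' Sums [contact_energy()] over all nearest-neighbour occupied pairs, each
#' unordered pair counted once, and reports the contact bookkeeping
#' (isotropic contacts and directional bonds by species pair) from which the
#' energy is reconstructed as
#' `-(beta_eps * n_iso + beta_eps_ss * n_ss + beta_eps_cs * n_cs + beta_eps_cc * n_cc)`.
#'
#' @inheritParams contact_energy
#' @param cfg A [lattice_config()].
#' @return List with `energy`, the four contact counts, and `n_s`, `n_c`.
#' @export
total_energy <- function(cfg, f, model = model_spec()) {
  f <- .as_field_vector(f)
  res <- cpp_total_energy(as.integer(cfg), attr(cfg, "dims"),
                          attr(cfg, "boundary") == "periodic",
                          model$patch_mask, unclass(f))
  res
}

#' Energy change of a single Monte Carlo move
#'
#' Computes the local energy difference of an insert, delete, translate or
#' rotate move, equal to `total_energy(after) - total_energy(before)` but
#' evaluated from the neighbourhood of the touched sites only.
#'
#' @inheritParams total_energy
#' @param move A list with `kind` (one of `"insert"`, `"delete"`,
#'   `"translate"`, `"rotate"`), `at` (site coordinates), and, as needed,
#'   `species`, `orientation` (insert, rotate) and `to` (translate).
#' @return Dimensionless energy change.
#' @export
delta_energy <- function(cfg, move, f, model = model_spec()) {
  f <- .as_field_vector(f)
  dims <- attr(cfg, "dims")
  periodic <- attr(cfg, "boundary") == "periodic"
  st <- as.integer(cfg)
  loc <- function(site, code, skip = -1L)
    cpp_local_energy(st, dims, periodic, model$patch_mask, unclass(f),
                     site - 1L, code, skip - 1L + (skip == -1L))$energy
  i <- .site_index(cfg, move$at)
  kind <- match.arg(move$kind, c("insert", "delete", "translate", "rotate"))
  if (kind == "insert") {
    if (st[i] >= 0) stop("insert move references an occupied site")
    loc(i, .state_code(move$species, move$orientation))
  } else if (kind == "delete") {
    if (st[i] < 0) stop("delete move references an empty site")
    -loc(i, st[i])
  } else if (kind == "translate") {
    j <- .site_index(cfg, move$to)
    if (st[i] < 0) stop("translate move references an empty site")
    if (st[j] >= 0) stop("translate destination is occupied")
    code <- st[i]
    st2 <- st; st2[i] <- -1L
    after <- cpp_local_energy(st2, dims, periodic, model$patch_mask, unclass(f),
                              j - 1L, code, -1L)$energy
    after - loc(i, code)
  } else {
    if (st[i] < 0) stop("rotate move references an empty site")
    code <- st[i]
    new_code <- (code %/% 24L) * 24L + as.integer(move$orientation) - 1L
    st2 <- st; st2[i] <- -1L
    before <- cpp_local_energy(st2, dims, periodic, model$patch_mask, unclass(f),
                               i - 1L, code, -1L)$energy
    after <- cpp_local_energy(st2, dims, periodic, model$patch_mask, unclass(f),
                              i - 1L, new_code, -1L)$energy
    after - before
  }
}

#' Apply a move description to a configuration
#'
#' @inheritParams delta_energy
#' @return The updated configuration.
#' @export
apply_move <- function(cfg, move) {
  i <- .site_index(cfg, move$at)
  kind <- match.arg(move$kind, c("insert", "delete", "translate", "rotate"))
  if (kind == "insert") {
    if (cfg[i] >= 0) stop("insert move references an occupied site")
    cfg[i] <- .state_code(move$species, move$orientation)
  } else if (kind == "delete") {
    if (cfg[i] < 0) stop("delete move references an empty site")
    cfg[i] <- -1L
  } else if (kind == "translate") {
    j <- .site_index(cfg, move$to)
    if (cfg[i] < 0) stop("translate move references an empty site")
    if (cfg[j] >= 0) stop("translate destination is occupied")
    cfg[j] <- cfg[i]; cfg[i] <- -1L
  } else {
    if (cfg[i] < 0) stop("rotate move references an empty site")
    cfg[i] <- (cfg[i] %/% 24L) * 24L + as.integer(move$orientation) - 1L
  }
  cfg
}

#' Dimension of the critical surface
#'
#' A multicomponent mixture with `n_fields` independent thermodynamic fields
#' has a critical surface of dimension `n_fields - 2`.  This model has six
#' fields (four interaction energies and two chemical potentials), so its
#' critical surface is 4-dimensional.
#'
#' @param n_fields Number of independent thermodynamic fields.
#' @return Integer dimension of the critical surface.
#' @export
critical_surface_dimension <- function(n_fields = 6L) {
  stopifnot(n_fields >= 2)
  as.integer(n_fields) - 2L
}

#' Stoichiometric passivation fraction
#'
#' The chaperone stoichiometric fraction `x_c` at which the chaperone patch
#' count exactly matches the client patch count: with `p_s` patches per
#' client and `p_c` per chaperone, `N_c p_c = N_s p_s` gives
#' `x_c = p_s / (p_s + p_c)`; 0.75 for the three-patch client and
#' single-patch chaperone.
#'
#' @param client_patches Patches per client monomer.
#' @param chaperone_patches Patches per chaperone monomer.
#' @return The passivating chaperone fraction.
#' @export
passivation_fraction <- function(client_patches = 3L, chaperone_patches = 1L) {
  stopifnot(client_patches >= 1, chaperone_patches >= 1)
  client_patches / (client_patches + chaperone_patches)
}
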