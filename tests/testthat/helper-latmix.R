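# Shared fixtures, all built in code.

# a minimal synthetic sample_table with the attributes the analysis code needs
toy_sample_table <- function(n_s, n_c, n_iso = 0, n_ss = 0, n_cs = 0,
                             n_cc = 0, eta = 0, dims = c(12, 12, 12),
                             fields = field_vector(), species = "both") {
  k <- length(n_s)
  tbl <- data.frame(n_s = n_s, n_c = n_c,
                    n_iso = rep_len(n_iso, k), n_ss = rep_len(n_ss, k),
                    n_cs = rep_len(n_cs, k), n_cc = rep_len(n_cc, k),
                    eta = rep_len(eta, k))
  attr(tbl, "fields") <- fields
  attr(tbl, "dims") <- as.integer(dims)
  attr(tbl, "boundary") <- "periodic"
  attr(tbl, "species") <- species
  attr(tbl, "schedule") <- list(burnin = 0, n_samples = k, spacing = 1)
  class(tbl) <- c("sample_table", "data.frame")
  tbl
}

# rejection sampler for the universal 3D-Ising ordering density
r_ising_ordering <- function(n) {
  env <- 1.05 * max(ising_ordering_density(seq(-3.5, 3.5, by = 0.005)))
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(4 * n, -3.5, 3.5)
    keep <- runif(4 * n) < ising_ordering_density(x) / env
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# random valid move on a configuration, or NULL if none applies
random_move <- function(cfg) {
  d <- attr(cfg, "dims")
  rand_site <- function() c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
  occ <- which(cfg >= 0)
  pick <- function(v) v[sample.int(length(v), 1)]
  kind <- sample(c("insert", "delete", "translate", "rotate"), 1)
  if (kind %in% c("delete", "translate", "rotate") && length(occ) == 0)
    kind <- "insert"
  site_coords <- function(i) {
    i <- i - 1L
    c(i %% d[1], (i %/% d[1]) %% d[2], i %/% (d[1] * d[2])) + 1L
  }
  if (kind == "insert") {
    empty <- which(cfg < 0)
    if (length(empty) == 0) return(NULL)
    list(kind = "insert", at = site_coords(pick(empty)),
         species = sample(c("client", "chaperone"), 1),
         orientation = sample(24, 1))
  } else if (kind == "delete") {
    list(kind = "delete", at = site_coords(pick(occ)))
  } else if (kind == "translate") {
    empty <- which(cfg < 0)
    if (length(empty) == 0) return(NULL)
    list(kind = "translate", at = site_coords(pick(occ)),
         to = site_coords(pick(empty)))
  } else {
    list(kind = "rotate", at = site_coords(pick(occ)),
         orientation = sample(24, 1))
  }
}
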