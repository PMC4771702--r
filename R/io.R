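# cli_io support: run configurations, artifact persistence, provenance.

#' Write a sample table to a self-describing CSV
#'
#' The metadata (fields, geometry, schedule, bias range, seed, config hash)
#' is stored as a JSON object on a leading `#`-comment line, followed by the
#' snapshot columns in CSV form, so the artifact is a single plain-text
#' file.  [read_sample_table()] restores the table with its attributes.
#'
#' @param x A `sample_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path) {
  meta <- list(fields = as.list(unclass(attr(x, "fields"))),
               dims = attr(x, "dims"), boundary = attr(x, "boundary"),
               species = attr(x, "species"), q_c = attr(x, "q_c"),
               n_range = attr(x, "n_range"),
               eta_table = attr(x, "eta_table"),
               schedule = attr(x, "schedule"),
               acceptance = attr(x, "acceptance"),
               tau_int_n = attr(x, "tau_int_n"),
               seed = attr(x, "seed"),
               version = as.character(utils::packageVersion("latmix")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA, null = "null")), con)
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Read a sample table written by [write_sample_table()]
#'
#' @param path Path to the artifact.
#' @return A `sample_table`.
#' @export
read_sample_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ")) stop("not a sample-table artifact: ", path)
  meta <- jsonlite::fromJSON(substring(first, 3L))
  tbl <- utils::read.csv(path, comment.char = "#")
  attr(tbl, "fields") <- do.call(field_vector, as.list(meta$fields))
  attr(tbl, "dims") <- as.integer(meta$dims)
  attr(tbl, "boundary") <- meta$boundary
  attr(tbl, "species") <- meta$species
  attr(tbl, "q_c") <- meta$q_c
  attr(tbl, "n_range") <- as.integer(meta$n_range)
  attr(tbl, "eta_table") <- as.numeric(meta$eta_table)
  attr(tbl, "schedule") <- as.list(meta$schedule)
  attr(tbl, "acceptance") <- as.data.frame(meta$acceptance)
  attr(tbl, "tau_int_n") <- meta$tau_int_n
  attr(tbl, "seed") <- meta$seed
  class(tbl) <- c("sample_table", "data.frame")
  tbl
}

#' Serialize a critical point to JSON
#'
#' Writes the full provenance record (fixed and solved fields, mixing
#' solution, diagnostics, seed, software version); the attached sample
#' table, if any, is dropped.
#'
#' @param cp A `critical_point`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_critical_point <- function(cp, path) {
  cp$samples <- NULL
  cp$weights <- NULL
  cp$fields <- as.list(unclass(cp$fields))
  cp$mixing <- unclass(cp$mixing)
  jsonlite::write_json(unclass(cp), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

.config_schema <- list(
  common = c("L", "dims", "boundary", "species", "q_c", "seed", "fields",
             "moves", "output"),
  simulate = c("schedule", "bias"),
  critical = c("critical", "schedule", "bias"),
  scan = c("scan", "schedule", "bias"),
  validate = c("validate"),
  `calibrate-ss` = c("calibrate", "schedule", "bias"))

.field_names <- c("beta_eps", "beta_eps_ss", "beta_eps_cs", "beta_eps_cc",
                  "beta_mu_s", "beta_mu_c")

#' Read and validate a run configuration
#'
#' Run configurations are YAML mappings with strict schema validation:
#' unknown keys are errors (guarding against silent typos in interaction
#' names), and basic type and range checks are applied.
#'
#' @param path Path to a YAML configuration.
#' @param command The subcommand the configuration is for: one of
#'   `"simulate"`, `"critical"`, `"scan"`, `"validate"`, `"calibrate-ss"`.
#' @return The validated configuration list, with a `hash` attribute.
#' @export
read_run_config <- function(path, command = "simulate") {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, command)
  attr(cfg, "hash") <- fnv1a(yaml::as.yaml(cfg))
  cfg
}

#' @rdname read_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg, command = "simulate") {
  command <- match.arg(command, names(.config_schema)[-1])
  allowed <- c(.config_schema$common, .config_schema[[command]])
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$L) && (!is.numeric(cfg$L) || cfg$L < 1 || cfg$L != round(cfg$L)))
    stop("L must be a positive integer")
  if (!is.null(cfg$boundary) && !cfg$boundary %in% c("periodic", "open"))
    stop("boundary must be 'periodic' or 'open'")
  if (!is.null(cfg$species) && !cfg$species %in% c("both", "client", "chaperone"))
    stop("species must be 'both', 'client' or 'chaperone'")
  if (!is.null(cfg$fields)) {
    bad <- setdiff(names(cfg$fields), .field_names)
    if (length(bad))
      stop("unknown field names: ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$schedule)) {
    bad <- setdiff(names(cfg$schedule), c("burnin", "n_samples", "spacing"))
    if (length(bad))
      stop("unknown schedule keys: ", paste(bad, collapse = ", "))
    if (any(unlist(cfg$schedule) < 0)) stop("schedule entries must be >= 0")
  }
  invisible(TRUE)
}
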