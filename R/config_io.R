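## Structured-text (YAML) configuration files.  A config file carries the
## parameter sets (neuron types, plasticity, programmable-synapse
## dynamics, row-integrator constants, demux factor, seed) -- the network
## connectivity itself is programmed through configuration address-events
## or the experiment builders.

#' Read / write device configuration files
#'
#' The file is YAML with sections `neuron_types` (a list of up to four
#' parameter sets), `neuron_type` (optional per-neuron type indices),
#' `plasticity`, `std`, `dpi`, `virtual_w`, `w_unit`, `demux_factor`,
#' `mismatch_cv` and `seed`.  Missing fields fall back to the package
#' defaults; all values are validated through the parameter
#' constructors.
#'
#' @param path File path.
#' @param cfg A [chip_config()].
#' @return `read_chip_config()` returns a [chip_config()];
#'   `write_chip_config()` returns `path` invisibly.
#' @export
read_chip_config <- function(path) {
  y <- yaml::read_yaml(path)
  nts <- if (is.null(y$neuron_types)) list(neuron_params())
         else lapply(y$neuron_types, function(nt)
           do.call(neuron_params, nt))
  args <- list(neuron_types = nts)
  if (!is.null(y$neuron_type)) args$neuron_type <- as.integer(y$neuron_type)
  if (!is.null(y$plasticity))
    args$plasticity <- do.call(plasticity_params, y$plasticity)
  if (!is.null(y$std)) args$std <- do.call(std_params, y$std)
  if (!is.null(y$dpi)) {
    dpi <- formals(chip_config)$dpi
    dpi <- eval(dpi)
    dpi[names(y$dpi)] <- y$dpi
    args$dpi <- dpi
  }
  if (!is.null(y$virtual_w)) args$virtual_w <- y$virtual_w
  for (f in c("w_unit", "demux_factor", "mismatch_cv", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(chip_config, args)
}

#' @rdname read_chip_config
#' @export
write_chip_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "chip_config"))
  strip <- function(x) unclass(x)
  y <- list(
    neuron_types = lapply(cfg$neuron_types, strip),
    neuron_type = cfg$neuron_type,
    plasticity = strip(cfg$plasticity),
    std = strip(cfg$std),
    dpi = cfg$dpi,
    virtual_w = cfg$virtual_w,
    w_unit = cfg$w_unit,
    demux_factor = cfg$demux_factor,
    seed = cfg$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Validate a configuration file
#'
#' Parses and validates a YAML device configuration, reporting the first
#' constraint violation.
#'
#' @param path File path.
#' @return `TRUE` (invisibly) if the file is valid; otherwise an error.
#' @export
validate_config_file <- function(path) {
  invisible(inherits(read_chip_config(path), "chip_config"))
}

#' Read an attractor calibration file
#'
#' Builds an [attractor_spec()] from a YAML file of spec fields.  The
#' packaged calibration (`extdata/attractor_calibration.yaml`) holds the
#' default operating point; fields missing from the file fall back to
#' the constructor defaults.
#'
#' @param path File path; defaults to the packaged calibration.
#' @return An [attractor_spec()].
#' @export
read_attractor_spec <- function(path = system.file(
    "extdata", "attractor_calibration.yaml", package = "rollsim")) {
  y <- yaml::read_yaml(path)
  known <- names(formals(attractor_spec))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("read_attractor_spec: unknown field(s): ",
         paste(unknown, collapse = ", "))
  do.call(attractor_spec, y)
}
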