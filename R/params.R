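#' Load a cell parameter set
#'
#' Parameter sets are flat key-value YAML files.  Two presets ship with the
#' package: `"default"` (normal Ca-induced inactivation, `aca = 0.15`) and
#' `"ead"` (reduced Ca-induced inactivation, `aca = 0.09`, which places the
#' cell in the EAD regime at slow pacing).  The presets differ only in `aca`.
#'
#' @param preset `"default"`, `"ead"`, or a path to a YAML file.
#' @param ... named overrides applied on top of the file values, e.g.
#'   `ead_params("default", gkr = 0.03)`.
#' @return A named list of class `ead_params`.
#' @examples
#' p <- ead_params("default")
#' p$aca
#' ead_params("ead")$aca
#' @export
ead_params <- function(preset = "default", ...) {
  path <- if (file.exists(preset)) preset
          else system.file("params", paste0(preset, ".yaml"), package = "eadsim")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown parameter preset or file: ", preset)
  p <- yaml::read_yaml(path)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p <- modifyList(p, dots)
  }
  stopifnot(all(vapply(p, is.numeric, logical(1))))
  structure(p, class = c("ead_params", "list"))
}

#' @export
print.ead_params <- function(x, ...) {
  cat("<ead_params> ", length(x), " parameters; aca = ", x$aca,
      if (x$aca <= 0.1) "  (EAD regime)" else "  (normal)", "\n", sep = "")
  invisible(x)
}

#' Write a parameter set to YAML
#'
#' @param params an `ead_params` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Default resting cell state
#'
#' Returns the canonical initial condition: resting potential near -87 mV,
#' closed/recovered gates, all L-type channels in the deep closed state, no
#' sparks, diastolic Ca of 0.15 uM and SR load of 800 uM.
#'
#' @return A named list (`v`, `nai`, gating variables, `lcc` occupancies,
#'   compartment Ca concentrations, `nb`, `pb`, `dvdt`).
#' @export
cell_state <- function() {
  cpp_default_state()
}

#' Simulation mode descriptor
#'
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param Nb total number of junctional clusters (stochastic mode only).
#' @param seed integer seed for the per-cell spark streams.  Ignored in
#'   deterministic mode.
#' @return list of class `ead_mode`.
#' @export
ead_mode <- function(mode = c("stochastic", "deterministic"), Nb = 4000,
                     seed = 1) {
  mode <- match.arg(mode)
  stopifnot(Nb >= 1, Nb == round(Nb))
  structure(list(mode = mode, Nb = as.integer(Nb), seed = as.numeric(seed)),
            class = "ead_mode")
}

#' @export
print.ead_mode <- function(x, ...) {
  cat("<ead_mode> ", x$mode,
      if (x$mode == "stochastic") paste0(", Nb = ", x$Nb, ", seed = ", x$seed),
      "\n", sep = "")
  invisible(x)
}
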