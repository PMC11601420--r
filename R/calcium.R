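#' Four-compartment Ca state
#'
#' Average free Ca concentration in the cytosol and SR near junctional (J)
#' and non-junctional (NJ) RyR clusters.
#'
#' @param cb,ci cytosolic Ca near J / NJ clusters (uM).
#' @param csrb,csri SR Ca near J / NJ clusters (uM).
#' @return list of class `ca_state`.
#' @export
ca_state <- function(cb = 0.15, ci = 0.15, csrb = 800, csri = 800) {
  stopifnot(cb > 0, ci > 0, csrb > 0, csri > 0)
  structure(list(cb = cb, ci = ci, csrb = csrb, csri = csri),
            class = "ca_state")
}

#' Junctional RyR release flux
#'
#' `Jrb = gb * csrb * pb`: release scales with the sparking fraction and the
#' local SR load.  Referred to the junctional cytosolic volume.
#'
#' @param csrb junctional SR Ca (uM, `> 0`).
#' @param pb spark fraction in `[0, 1]`.
#' @param gb effective RyR cluster conductance (1/ms).
#' @return flux (uM/ms).
#' @export
release_flux_junctional <- function(csrb, pb, gb) {
  stopifnot(csrb > 0, pb >= 0, pb <= 1, gb >= 0)
  gb * csrb * pb
}

#' All compartment fluxes
#'
#' Evaluates the eight fluxes coupling the four Ca compartments and the
#' membrane: junctional and NJ release (`jrb`, `jri`), SERCA uptake (`jupb`,
#' `jupi`, Hill exponent 2), diffusive SR and cytosolic exchange (`jdsr`,
#' `jdc`, linear relaxation), the L-type influx `jca` and the exchanger flux
#' `jnaca` (both supplied by the membrane model).  Sign conventions: release
#' moves SR -> cytosol (nonnegative), uptake cytosol -> SR (nonnegative),
#' `jdsr` is positive when NJ SR feeds the junctional SR, `jdc` positive when
#' junctional cytosol feeds the bulk.  Each flux is expressed per destination
#' compartment volume.
#'
#' @param ca a [ca_state()].
#' @param spark a [spark_state()] (only `pb` is used).
#' @param lcc_flux total L-type Ca flux into the junctional cytosol (uM/ms).
#' @param naca_flux exchanger Ca flux into the junctional cytosol (uM/ms,
#'   negative during forward-mode extrusion).
#' @param params an [ead_params()].
#' @return named numeric vector of the eight fluxes.
#' @export
compute_all_fluxes <- function(ca, spark, lcc_flux, naca_flux, params) {
  stopifnot(inherits(ca, "ca_state"))
  pb <- if (inherits(spark, "spark_state")) spark$pb else as.numeric(spark)
  cpp_ca_fluxes(unclass(ca), pb, lcc_flux, naca_flux, unclass(params))
}

#' One Euler step of the compartment balance equations
#'
#' Updates each compartment by the volume-ratio-weighted sum of its inbound
#' and outbound fluxes, scaled by the instantaneous buffering factor of that
#' compartment.  With membrane fluxes off the update conserves the
#' buffer-weighted total `sum(v_k c_k / beta_k)` exactly up to Euler error.
#'
#' @param ca a [ca_state()].
#' @param fluxes named flux vector from [compute_all_fluxes()].
#' @param params an [ead_params()] (volumes and buffering factors).
#' @param dt timestep (ms, `> 0`).
#' @return updated `ca_state`.
#' @export
step_calcium <- function(ca, fluxes, params, dt) {
  stopifnot(inherits(ca, "ca_state"))
  if (dt <= 0) stop("invalid argument: dt must be positive")
  out <- cpp_ca_step(unclass(ca), fluxes, unclass(params), dt)
  if (any(out <= 0))
    stop("nonpositive concentration after step: timestep/parameters inconsistent")
  ca_state(out[["cb"]], out[["ci"]], out[["csrb"]], out[["csri"]])
}

#' Buffer-weighted total Ca content
#'
#' The quantity conserved by [step_calcium()] when membrane fluxes are zero:
#' `sum_k v_k c_k / beta_k` over the four compartments (arbitrary
#' amount units, since volumes are relative).
#'
#' @param ca a [ca_state()].
#' @param params an [ead_params()].
#' @return scalar total.
#' @export
total_ca_content <- function(ca, params) {
  params$vb * ca$cb / params$buf_cb +
    params$vi * ca$ci / params$buf_ci +
    params$vsrb * ca$csrb / params$buf_csrb +
    params$vsri * ca$csri / params$buf_csri
}
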