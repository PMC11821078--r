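#' Droplet state
#'
#' Volume, solute concentration and time of a water-in-oil droplet. With
#' no solute flux the solute amount `C * V` is conserved along any
#' trajectory, so water loss into the oil concentrates the solute.
#'
#' @param V Droplet volume, nL (positive).
#' @param C Solute concentration, arbitrary units per nL (non-negative).
#' @param t Time, s.
#' @return An object of class `droplet_state`.
#' @export
droplet_state <- function(V, C, t = 0) {
  if (V <= 0) abort_config("droplet volume must be positive")
  if (C < 0) abort_config("concentration must be non-negative")
  structure(list(V = V, C = C, t = t), class = "droplet_state")
}

#' Covering-oil specification
#'
#' @param saturation_fraction Water saturation of the oil in \[0, 1\];
#'   1 means water-saturated oil, which suppresses the concentration
#'   gradient and hence the water efflux entirely.
#' @param transfer_coefficient Water transfer coefficient at zero
#'   saturation, nL/s (for the default area-limited law, nL^(1/3)/s
#'   effectively; units are arbitrary-consistent).
#' @return An object of class `oil_spec`.
#' @export
oil_spec <- function(saturation_fraction = 0, transfer_coefficient = 1e-3) {
  if (saturation_fraction < 0 || saturation_fraction > 1) {
    abort_config("saturation_fraction must lie in [0, 1]")
  }
  if (transfer_coefficient < 0) {
    abort_config("transfer_coefficient must be non-negative")
  }
  structure(list(saturation_fraction = saturation_fraction,
                 transfer_coefficient = transfer_coefficient),
            class = "oil_spec")
}

droplet_rate <- function(V, oil, efflux) {
  g <- switch(efflux, area = V^(2 / 3), constant = 1)
  -oil$transfer_coefficient * (1 - oil$saturation_fraction) * g
}

#' Simulate droplet volume and solute concentration over time
#'
#' Integrates \eqn{dV/dt = -k (1 - s)\, g(V)} with the area-limited
#' efflux law \eqn{g(V) = V^{2/3}} (water leaves through the droplet
#' surface) and computes \eqn{C(t) = C_0 V_0 / V(t)} from solute
#' conservation. It follows that
#' \eqn{dC/dt = -C \,(dV/dt)/V}: the smaller the droplet, the faster its
#' solute concentrates, diverging as \eqn{V \to 0}. Saturated oil
#' (`s = 1`) freezes both V and C. Integration stops, flagged, if the
#' volume reaches `v_floor`.
#'
#' @param initial A [droplet_state()].
#' @param oil An [oil_spec()].
#' @param duration Total simulated time, s.
#' @param dt Output time step, s (positive).
#' @param efflux `"area"` (default) or `"constant"` flux law.
#' @param v_floor Volume floor, nL (default `1e-6 * V0`).
#' @return A data.frame with columns `t`, `V`, `C`; attribute
#'   `terminated` is `TRUE` if the floor was hit.
#' @export
simulate_droplet <- function(initial, oil, duration, dt,
                             efflux = c("area", "constant"),
                             v_floor = NULL) {
  stopifnot(inherits(initial, "droplet_state"), inherits(oil, "oil_spec"))
  efflux <- match.arg(efflux)
  if (dt <= 0) abort_config("dt must be positive")
  if (duration < dt) abort_config("duration must be at least dt")
  if (is.null(v_floor)) v_floor <- 1e-6 * initial$V
  times <- seq(0, duration, by = dt)
  sol <- deSolve::lsodar(
    y = c(V = initial$V), times = times,
    func = function(t, y, parms) list(droplet_rate(y[["V"]], oil, efflux)),
    rootfunc = function(t, y, parms) y[["V"]] - v_floor,
    rtol = 1e-10, atol = 1e-12 * initial$V
  )
  out <- as.data.frame(sol)
  terminated <- nrow(out) < length(times)
  out$C <- initial$C * initial$V / out$V
  out$t <- out$time + initial$t
  out <- out[, c("t", "V", "C")]
  attr(out, "terminated") <- terminated
  out
}

#' Closed-form droplet volume for unsaturated oil
#'
#' For `s = 0` and the area law the ODE integrates to
#' \eqn{V(t) = (V_0^{1/3} - k t / 3)^3} until depletion.
#'
#' @param t Time(s), s.
#' @param V0 Initial volume, nL.
#' @param k Transfer coefficient.
#' @return Volume(s) in nL (0 after depletion).
#' @export
droplet_volume_closed_form <- function(t, V0, k) {
  pmax(V0^(1 / 3) - k * t / 3, 0)^3
}

#' Time for the droplet solute concentration to reach a target
#'
#' Root-finds the first time \eqn{C(t) \ge C_{target}} on the integrated
#' trajectory. Returns `Inf` for saturated oil or a zero transfer
#' coefficient (the target is unreachable).
#'
#' @param initial A [droplet_state()].
#' @param oil An [oil_spec()].
#' @param C_target Target concentration (> initial `C`).
#' @param efflux Efflux law, see [simulate_droplet()].
#' @return Time in seconds (possibly `Inf`).
#' @export
time_to_concentration <- function(initial, oil, C_target,
                                  efflux = c("area", "constant")) {
  stopifnot(inherits(initial, "droplet_state"), inherits(oil, "oil_spec"))
  efflux <- match.arg(efflux)
  if (C_target <= initial$C) abort_config("C_target must exceed the initial concentration")
  if (oil$saturation_fraction >= 1 || oil$transfer_coefficient == 0) {
    return(Inf)
  }
  v_target <- initial$C * initial$V / C_target
  keff <- oil$transfer_coefficient * (1 - oil$saturation_fraction)
  horizon <- 2 * switch(efflux,
    area = 3 * (initial$V^(1 / 3) - v_target^(1 / 3)) / keff,
    constant = (initial$V - v_target) / keff
  )
  sol <- deSolve::lsodar(
    y = c(V = initial$V), times = c(0, horizon),
    func = function(t, y, parms) list(droplet_rate(y[["V"]], oil, efflux)),
    rootfunc = function(t, y, parms) y[["V"]] - v_target,
    rtol = 1e-10, atol = 1e-12 * initial$V
  )
  troot <- attr(sol, "troot")
  if (is.null(troot) || length(troot) == 0) return(Inf)
  troot[1]
}
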