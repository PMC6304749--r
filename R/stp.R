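# Tsodyks-Markram short-term plasticity: running utilization u (facilitation)
# and available resources x (depression), with the four named variants.

.stp_variants <- data.frame(
  variant = c("STD1", "STD2", "STF1", "STF2"),
  tau_dep = c(100, 100, 1, 10),
  tau_fac = c(1, 10, 100, 100),
  stringsAsFactors = FALSE
)

#' Short-term plasticity parameters
#'
#' The four variants differ only in the printed time-constant pairs:
#' depressing synapses use `tau_dep = 100` ms with `tau_fac = 1` (STD1) or
#' 10 ms (STD2); facilitating synapses use `tau_fac = 100` ms with
#' `tau_dep = 1` (STF1) or 10 ms (STF2).  The baseline utilization `U` is
#' not a printed constant; it defaults to 0.5 and is shared across variants
#' so variants differ by time constants alone.  `variant = "none"` is the
#' static-synapse control (efficacy identically 1).
#'
#' @param variant one of `"STD1"`, `"STD2"`, `"STF1"`, `"STF2"`, `"none"`
#'   (case-insensitive), or `"custom"` with explicit time constants.
#' @param U baseline utilization in `(0, 1]`.
#' @param tau_dep,tau_fac override time constants, ms (required for
#'   `"custom"`).
#' @return an object of class `stp_params`.
#' @export
stp_params <- function(variant = "none", U = 0.5,
                       tau_dep = NULL, tau_fac = NULL) {
  variant <- toupper(variant)
  if (variant == "NONE") variant <- "none"
  stopifnot(U > 0, U <= 1)
  if (variant == "none") {
    return(structure(list(variant = "none", U = U, tau_dep = NA_real_,
                          tau_fac = NA_real_), class = "stp_params"))
  }
  if (variant == "CUSTOM") {
    if (is.null(tau_dep) || is.null(tau_fac)) {
      stop("custom STP needs tau_dep and tau_fac")
    }
  } else {
    i <- match(variant, .stp_variants$variant)
    if (is.na(i)) {
      stop("unknown STP variant '", variant, "'; valid: ",
           paste(c(.stp_variants$variant, "none"), collapse = ", "))
    }
    if (is.null(tau_dep)) tau_dep <- .stp_variants$tau_dep[i]
    if (is.null(tau_fac)) tau_fac <- .stp_variants$tau_fac[i]
  }
  stopifnot(tau_dep > 0, tau_fac > 0)
  structure(list(variant = if (variant == "CUSTOM") "custom" else variant,
                 U = U, tau_dep = tau_dep, tau_fac = tau_fac),
            class = "stp_params")
}

#' @rdname stp_params
#' @param name variant name token (`std1|std2|stf1|stf2|none`).
#' @export
stp_variant <- function(name, U = 0.5) stp_params(variant = name, U = U)

#' Per-synapse dynamic state
#'
#' `u` is the post-spike utilization and `x` the post-use resource fraction
#' left by the most recent presynaptic spike; `(0, 1)` is the rested state.
#'
#' @param u running utilization in `[0, 1]`.
#' @param x available resources fraction in `[0, 1]`.
#' @param t_last time of the previous presynaptic spike, s, or `NA`.
#' @return an object of class `stp_state`.
#' @export
stp_state <- function(u = 0, x = 1, t_last = NA_real_) {
  stopifnot(u >= 0, u <= 1, x >= 0, x <= 1)
  structure(list(u = u, x = x, t_last = t_last), class = "stp_state")
}

#' Advance the plasticity state across one presynaptic spike
#'
#' Facilitate-then-depress ordering: with `u- = u exp(-dt/tau_fac)` and
#' `x- = 1 - (1 - x) exp(-dt/tau_dep)`, the spike sets
#' `u' = u- + U (1 - u-)`, transmits with efficacy `u' x-`, and leaves
#' `x' = x- (1 - u')`.  The applied synaptic weight is the nominal weight
#' times `efficacy / U`, so the first spike from rest transmits the nominal
#' weight exactly.
#'
#' @param state an [stp_state()].
#' @param p an [stp_params()].
#' @param delta_t time since the previous presynaptic spike, ms; `Inf` (or
#'   a rested state) for the first spike.
#' @return `list(state, efficacy, applied_factor)`.
#' @export
stp_on_spike <- function(state, p, delta_t = Inf) {
  if (p$variant == "none") {
    return(list(state = state, efficacy = 1, applied_factor = 1))
  }
  if (delta_t <= 0) stop("delta_t must be > 0")
  u_minus <- state$u * exp(-delta_t / p$tau_fac)
  x_minus <- 1 - (1 - state$x) * exp(-delta_t / p$tau_dep)
  u_new <- u_minus + p$U * (1 - u_minus)
  efficacy <- u_new * x_minus
  x_new <- x_minus * (1 - u_new)
  if (u_new < 0 || u_new > 1 || x_new < 0 || x_new > 1) {
    stop("STP invariant violated: u=", u_new, " x=", x_new)
  }
  list(state = stp_state(u_new, x_new), efficacy = efficacy,
       applied_factor = efficacy / p$U)
}

#' Steady-state efficacy under a periodic presynaptic train
#'
#' Closed-form fixed point of [stp_on_spike()] at a regular inter-spike
#' interval `T = 1000 / rate` ms:
#' `u* = U / (1 - (1 - U) exp(-T/tau_fac))` and
#' `x* = (1 - exp(-T/tau_dep)) / (1 - (1 - u*) exp(-T/tau_dep))`.
#'
#' @param p an [stp_params()].
#' @param rate presynaptic firing rate, Hz (`> 0`).
#' @return `list(u, x, efficacy, applied_factor)`.
#' @export
steady_state_efficacy <- function(p, rate) {
  if (rate <= 0) stop("rate must be > 0")
  if (p$variant == "none") {
    return(list(u = NA_real_, x = NA_real_, efficacy = 1, applied_factor = 1))
  }
  T_ms <- 1000 / rate
  ef <- exp(-T_ms / p$tau_fac)
  ed <- exp(-T_ms / p$tau_dep)
  u_star <- p$U / (1 - (1 - p$U) * ef)
  x_star <- (1 - ed) / (1 - (1 - u_star) * ed)
  eff <- u_star * x_star
  list(u = u_star, x = x_star, efficacy = eff, applied_factor = eff / p$U)
}
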