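# Network assembly, Poisson drive, clock-driven integration with delayed
# spike delivery, and the factorial sweep.

#' Simulation configuration
#'
#' @param dt integration step, ms.
#' @param T total simulated time, s.
#' @param burn_in initial transient discarded by the analysis, s
#'   (`burn_in < T`).
#' @param IF external Poisson input frequency, Hz.
#' @param n_trials trials per sweep cell.
#' @param seed run seed.
#' @param N neuron count.
#' @param scale `"full"` reproduces the printed configuration
#'   (N = 3000, T = 2000 s, burn-in 50 s); `"desk"` is the scaled mode used
#'   by tests (N = 300, T = 60 s, burn-in 10 s).  Explicit arguments
#'   override the preset.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.1, T = NULL, burn_in = NULL, IF = 20,
                              n_trials = 12, seed = 1, N = NULL,
                              scale = c("full", "desk")) {
  scale <- match.arg(scale)
  preset <- if (scale == "full") list(T = 2000, burn_in = 50, N = 3000)
            else list(T = 60, burn_in = 10, N = 300)
  if (is.null(T)) T <- preset$T
  if (is.null(burn_in)) burn_in <- preset$burn_in
  if (is.null(N)) N <- preset$N
  stopifnot(dt > 0, T > 0, burn_in >= 0, burn_in < T, IF >= 0, n_trials >= 1)
  structure(list(dt = dt, T = T, burn_in = burn_in, IF = IF,
                 n_trials = n_trials, seed = as.integer(seed),
                 N = as.integer(N), scale = scale),
            class = "simulation_config")
}

#' Homogeneous Poisson spike train
#'
#' @param rate rate, Hz (`>= 0`).
#' @param T duration, s.
#' @param seed optional seed.
#' @return sorted spike times in `[0, T]`, s.
#' @export
poisson_train <- function(rate, T, seed = NULL) {
  stopifnot(rate >= 0, T >= 0)
  if (rate == 0 || T == 0) return(numeric(0))
  with_seed(seed, sort(runif(rpois(1, rate * T), 0, T)))
}

#' Assemble a complete, seed-reproducible network specification
#'
#' Places neurons, samples the fixed-K Gaussian wiring with
#' distance-dependent delays, and attaches the maturation state and STP
#' variant.  Each neuron additionally receives one independent external
#' Poisson source with increment `g_ext` (static, no STP); external drive
#' does not count toward K.
#'
#' @param scenario a [scenario_spec()] or scenario name.
#' @param maturation a [maturation_state()] or label.
#' @param stp an [stp_params()] or variant token.
#' @param seed wiring/placement seed.
#' @param N neuron count (K scales as `round(epsilon * N)`).
#' @param np,sp,dp parameter blocks.
#' @param arrangement neuron placement, `"uniform"` or `"grid"`.
#' @param stp_exc_only restrict STP to excitatory recurrent synapses.
#' @return an object of class `network_spec`.
#' @export
build_network <- function(scenario, maturation = "immature", stp = "none",
                          seed = 1, N = 3000,
                          np = neuron_params(), sp = synapse_params(),
                          dp = delay_params(),
                          arrangement = "uniform", stp_exc_only = FALSE) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (is.character(maturation)) maturation <- maturation_state(maturation)
  if (is.character(stp)) stp <- stp_params(stp)
  cp <- connectivity_params(scenario$epsilon, scenario$sigma_c, N = N)
  with_seed(seed, {
    geom <- lattice_geometry(N = N, arrangement = arrangement)
    synapses <- build_synapse_table(scenario, geom, cp = cp, dp = dp, sp = sp)
  })
  structure(list(scenario = scenario, maturation = maturation, stp = stp,
                 neuron = np, synapse = sp, delay = dp, connectivity = cp,
                 geometry = geom, synapses = synapses, seed = seed,
                 stp_exc_only = stp_exc_only),
            class = "network_spec")
}

#' Run one simulation and record spikes
#'
#' Clock-driven integration at `cfg$dt` with a ring-buffer delay queue
#' (delays rounded up to the next step).  External drive is per-neuron
#' independent Poisson input thinned per step, or an explicit deterministic
#' event list via `ext_events`.  Bit-reproducible for a fixed `cfg$seed`.
#'
#' @param spec a [build_network()] result.
#' @param cfg a [simulation_config()]; `cfg$N` is ignored in favour of the
#'   network's own size.
#' @param ext_events optional `data.frame(time_s, neuron)` of deterministic
#'   external input spikes (replaces the Poisson drive).
#' @param record_v optional neuron id whose membrane trajectory is returned
#'   (in `attr(rec, "v_trace")`, mV, one value per step).
#' @return an object of class `spike_record`: fields `times` (s, event
#'   order), `ids`, `N`, `T`, `dt`, `classes` (logical `is_inhibitory`),
#'   `config`.
#' @export
run_simulation <- function(spec, cfg, ext_events = NULL, record_v = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "simulation_config"))
  N <- spec$geometry$N
  syn <- spec$synapses[order(spec$synapses$source), , drop = FALSE]
  delay_steps <- as.integer(ceiling(syn$delay_ms / cfg$dt - 1e-9))
  n_steps <- as.integer(round(cfg$T * 1000 / cfg$dt))
  is_inh <- seq_len(N) > spec$connectivity$n_exc

  use_poisson <- is.null(ext_events)
  if (use_poisson) {
    ext_step <- integer(0); ext_id <- integer(0)
  } else {
    stopifnot(all(ext_events$neuron >= 1), all(ext_events$neuron <= N))
    o <- order(ext_events$time_s)
    step <- as.integer(ceiling(ext_events$time_s[o] * 1000 / cfg$dt - 1e-9))
    keep <- step < n_steps
    ext_step <- step[keep]
    ext_id <- as.integer(ext_events$neuron[o][keep] - 1L)
  }

  stp_on <- spec$stp$variant != "none"
  par <- list(
    E_leak = spec$neuron$E_leak, tau_m = spec$neuron$tau_m,
    c_m = spec$neuron$c_m, E_exc = spec$synapse$E_exc,
    E_gaba = spec$maturation$E_gaba,
    tau_exc = spec$synapse$tau_exc, tau_inh = spec$synapse$tau_inh,
    V_threshold = spec$neuron$V_threshold, V_reset = spec$neuron$V_reset,
    tau_ref = spec$neuron$tau_ref, g_ext = spec$synapse$g_ext,
    dt = cfg$dt, n_steps = n_steps,
    p_ext = -expm1(-cfg$IF * cfg$dt / 1000),
    use_poisson = use_poisson,
    stp_enabled = stp_on, stp_exc_only = spec$stp_exc_only,
    U = if (stp_on) spec$stp$U else 0.5,
    tau_dep = if (stp_on) spec$stp$tau_dep else 1,
    tau_fac = if (stp_on) spec$stp$tau_fac else 1,
    record_v_id = if (is.null(record_v)) -1L else as.integer(record_v - 1L),
    ext_step = ext_step, ext_id = ext_id,
    init_V = NULL)

  out <- with_seed(cfg$seed, {
    par$init_V <- runif(N, spec$neuron$V_reset, spec$neuron$V_threshold)
    run_lif_engine(N, is_inh,
                   as.integer(syn$source - 1L), as.integer(syn$target - 1L),
                   as.numeric(syn$weight_nS), delay_steps, par)
  })
  rec <- structure(list(times = out$times_ms / 1000, ids = out$ids,
                        N = N, T = cfg$T, dt = cfg$dt, classes = is_inh,
                        config = cfg),
                   class = "spike_record")
  if (!is.null(record_v)) attr(rec, "v_trace") <- out$v_trace
  rec
}

#' @export
print.spike_record <- function(x, ...) {
  cat("spike_record:", length(x$times), "spikes,", x$N, "neurons,",
      x$T, "s\n")
  invisible(x)
}

#' Factorial simulation sweep producing an MSF table
#'
#' One row per (scenario, maturation, stp class, IF, trial).  Trial seeds
#' are derived deterministically from `master_seed` and the cell key, so the
#' sweep is resumable: rows already present in `existing` are skipped and
#' the remainder is identical to a fresh full run.  Per-row failures are
#' recorded (`error` column) and the sweep continues.
#'
#' @param scenarios character vector of scenario names.
#' @param maturations character vector of maturation labels.
#' @param stp_variants character vector of STP tokens, `"none"` for control.
#' @param if_grid numeric vector of input frequencies, Hz.
#' @param cfg a [simulation_config()] template (its `IF` and `seed` are
#'   overridden per row).
#' @param master_seed master seed.
#' @param existing optional previously computed table to resume from.
#' @param U baseline utilization passed to each STP variant.
#' @return an `msf_table` data.frame with columns `scenario`, `maturation`,
#'   `stp_class`, `if_hz`, `trial`, `msf_hz`, `seed`, `error`.
#' @export
sweep_msf <- function(scenarios, maturations, stp_variants, if_grid, cfg,
                      master_seed = cfg$seed, existing = NULL, U = 0.5) {
  stopifnot(length(scenarios) > 0, length(maturations) > 0,
            length(if_grid) > 0)
  if (length(stp_variants) == 0) stp_variants <- "none"
  grid <- expand.grid(scenario = scenarios, maturation = maturations,
                      stp_class = stp_variants, if_hz = if_grid,
                      trial = seq_len(cfg$n_trials),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (!is.null(existing)) {
      hit <- existing$scenario == g$scenario &
        existing$maturation == g$maturation &
        existing$stp_class == g$stp_class &
        existing$if_hz == g$if_hz & existing$trial == g$trial
      if (any(hit)) {
        rows[[i]] <- existing[which(hit)[1], , drop = FALSE]
        next
      }
    }
    seed_i <- derive_seed(master_seed, g$scenario, g$maturation,
                          g$stp_class, g$if_hz, g$trial)
    res <- tryCatch({
      spec <- build_network(g$scenario, g$maturation,
                            stp_params(g$stp_class, U = U),
                            seed = seed_i, N = cfg$N)
      cfg_i <- cfg
      cfg_i$IF <- g$if_hz
      cfg_i$seed <- seed_i
      rec <- run_simulation(spec, cfg_i)
      list(msf = mean_spike_frequency(rec, cfg$burn_in), err = NA_character_)
    }, error = function(e) list(msf = NA_real_, err = conditionMessage(e)))
    rows[[i]] <- data.frame(scenario = g$scenario, maturation = g$maturation,
                            stp_class = g$stp_class, if_hz = g$if_hz,
                            trial = g$trial, msf_hz = res$msf,
                            seed = seed_i, error = res$err,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("msf_table", "data.frame")
  out
}
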