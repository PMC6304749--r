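# Independent oracles used across the suite.  These deliberately share no
# code with the compiled engine: the scalar steppers are plain R loops over
# the reference operations, and the ANOVA oracle is textbook sums of
# squares.

# Scalar LIF oracle: integrate one neuron with deterministic external input
# events (each adding g_ext to g_e at the first grid time >= the event
# time).  Returns the per-step membrane trace (value at the end of each
# step) and spike times in ms ((k+1)*dt for a spike detected in step k).
scalar_lif_oracle <- function(np, sp, ms, dt, n_steps, V0,
                              ext_times_ms = numeric(0), g_ext = sp$g_ext) {
  ev_step <- ceiling(ext_times_ms / dt - 1e-9)
  st <- neuron_state(V = V0)
  v_trace <- numeric(n_steps)
  spike_ms <- numeric(0)
  for (k in seq_len(n_steps) - 1) {
    for (e in which(ev_step == k)) {
      st <- on_presynaptic_spike(st, g_ext, is_inhibitory = FALSE)
    }
    out <- membrane_step(st, np, sp, ms, dt)
    st <- out$state
    if (out$spiked) spike_ms <- c(spike_ms, (k + 1) * dt)
    v_trace[k + 1] <- st$V
  }
  list(v_trace = v_trace, spike_ms = spike_ms)
}

# Two-neuron oracle: a presynaptic spike train (ms) is delivered onto a
# single target neuron through one synapse with the engine's delay
# quantization (ceil to the next step) and Tsodyks-Markram efficacy applied
# at emission time.  Pure R re-derivation of the delivery schedule.
two_neuron_oracle <- function(np, sp, ms, stp, dt, n_steps, V0,
                              pre_spikes_ms, weight, delay_ms,
                              is_inhibitory = FALSE) {
  d_steps <- ceiling(delay_ms / dt - 1e-9)
  st_stp <- stp_state()
  t_prev <- NA_real_
  arrivals <- list()
  for (t_ms in pre_spikes_ms) {
    dtms <- if (is.na(t_prev)) Inf else t_ms - t_prev
    res <- stp_on_spike(st_stp, stp, dtms)
    st_stp <- res$state
    t_prev <- t_ms
    # emission in step k where (k+1)*dt == t_ms -> delivery slot k+1+d
    k <- round(t_ms / dt) - 1
    arrivals[[length(arrivals) + 1]] <-
      c(step = k + 1 + d_steps, w = weight * res$applied_factor)
  }
  arr_step <- vapply(arrivals, `[[`, 0, "step")
  arr_w <- vapply(arrivals, `[[`, 0, "w")
  st <- neuron_state(V = V0)
  v_trace <- numeric(n_steps)
  for (k in seq_len(n_steps) - 1) {
    for (a in which(arr_step == k)) {
      st <- on_presynaptic_spike(st, arr_w[a], is_inhibitory)
    }
    st <- membrane_step(st, np, sp, ms, dt)$state
    v_trace[k + 1] <- st$V
  }
  v_trace
}

# Textbook one-way ANOVA sums of squares.
oneway_anova_oracle <- function(values, groups) {
  g <- split(values, groups)
  grand <- mean(values)
  ss_between <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2, 0))
  ss_within <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  df_b <- length(g) - 1
  df_w <- length(values) - length(g)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(ss_between = ss_between, ss_within = ss_within, df_between = df_b,
       df_within = df_w, statistic = f,
       p_value = pf(f, df_b, df_w, lower.tail = FALSE))
}

# Minimal hand-built network spec for engine micro-tests: N neurons on a
# grid, explicit synapse table, no or explicit external drive.
micro_network <- function(N = 5, synapses = NULL, maturation = "immature",
                          stp = "none", np = neuron_params(),
                          sp = synapse_params(), stp_exc_only = FALSE) {
  geom <- lattice_geometry(N = N, arrangement = "grid")
  if (is.null(synapses)) {
    synapses <- data.frame(source = integer(0), target = integer(0),
                           weight_nS = numeric(0), delay_ms = numeric(0),
                           is_inhibitory = logical(0))
  }
  cp <- connectivity_params(0.2, 0.01, N = N)  # only n_exc/n_inh are used
  structure(list(scenario = scenario_spec("B-4"),
                 maturation = maturation_state(maturation),
                 stp = if (is.character(stp)) stp_params(stp) else stp,
                 neuron = np, synapse = sp, delay = delay_params(),
                 connectivity = cp, geometry = geom, synapses = synapses,
                 seed = 1, stp_exc_only = stp_exc_only),
            class = "network_spec")
}

per_neuron_isi_min <- function(rec) {
  isi <- unlist(lapply(split(rec$times, rec$ids),
                       function(x) if (length(x) > 1) min(diff(sort(x))) else Inf))
  if (length(isi)) min(isi) else Inf
}
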