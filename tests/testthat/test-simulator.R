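test_that("poisson_train: empty, count concentration, exponential ISIs", {
  expect_length(poisson_train(0, 100), 0)
  expect_length(poisson_train(10, 0), 0)
  # mean count over 100 seeds within 3 sigma of rate*T
  counts <- vapply(1:100, function(s) length(poisson_train(5, 40, seed = s)), 0)
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200) / sqrt(100))
  tr <- poisson_train(20, 200, seed = 123)
  expect_false(is.unsorted(tr))
  expect_true(all(tr >= 0 & tr <= 200))
  ks <- suppressWarnings(ks.test(diff(tr), "pexp", rate = 20))
  expect_gt(ks$p.value, 0.01)
})

test_that("build_network is seed-reproducible and fully specified", {
  a <- build_network("A-1", "immature", "none", seed = 4, N = 100)
  b <- build_network("A-1", "immature", "none", seed = 4, N = 100)
  expect_identical(a$synapses, b$synapses)
  expect_identical(a$geometry$positions, b$geometry$positions)
  c2 <- build_network("A-1", "immature", "none", seed = 5, N = 100)
  expect_false(identical(a$synapses, c2$synapses))

  spec <- build_network("B-2", "mature", "STD2", seed = 1, N = 300)
  expect_equal(spec$maturation$E_gaba, -70)
  expect_equal(spec$connectivity$n_exc, 240L)
  expect_equal(spec$connectivity$n_inh, 60L)
  expect_equal(spec$stp$variant, "STD2")
  # full-scale class split
  cp <- connectivity_params(0.1, 0.01, N = 3000)
  expect_equal(cp$n_exc, 2400L)
  expect_equal(cp$n_inh, 600L)
})

test_that("silent network stays silent without drive", {
  spec <- build_network("A-1", "immature", "none", seed = 2, N = 100)
  cfg <- simulation_config(T = 2, burn_in = 1, IF = 0, seed = 3, N = 100,
                           scale = "desk")
  rec <- run_simulation(spec, cfg)
  expect_length(rec$times, 0)
  expect_equal(mean_spike_frequency(rec, 1), 0)
})

test_that("single disconnected neuron matches the scalar oracle exactly", {
  np <- neuron_params(); sp <- synapse_params()
  ms <- maturation_state("immature")
  spec <- micro_network(N = 5, maturation = "immature")
  cfg <- simulation_config(T = 0.5, burn_in = 0.1, IF = 5, seed = 17, N = 5,
                           scale = "desk")
  ev <- data.frame(time_s = seq(0.01, 0.45, by = 0.003), neuron = 1)
  rec <- run_simulation(spec, cfg, ext_events = ev, record_v = 1)

  set.seed(cfg$seed)
  V0 <- runif(5, np$V_reset, np$V_threshold)[1]
  orc <- scalar_lif_oracle(np, sp, ms, dt = 0.1, n_steps = 5000, V0 = V0,
                           ext_times_ms = ev$time_s * 1000)
  eng_ms <- rec$times[rec$ids == 1] * 1000
  expect_equal(eng_ms, orc$spike_ms, tolerance = 1e-9)
  expect_gt(length(orc$spike_ms), 10)
  expect_equal(attr(rec, "v_trace"), orc$v_trace, tolerance = 1e-10)
})

test_that("delayed delivery lands in the step containing t + d", {
  # source 1 -> target 2, delay 1.0 ms; drive source with one strong event
  syn <- data.frame(source = 1, target = 2, weight_nS = 4, delay_ms = 1.0,
                    is_inhibitory = FALSE)
  spec <- micro_network(N = 5, synapses = syn)
  cfg <- simulation_config(T = 0.05, burn_in = 0.01, IF = 0, seed = 23, N = 5,
                           scale = "desk")
  ev <- data.frame(time_s = 0.005, neuron = 1)
  rec <- run_simulation(spec, cfg, ext_events = ev, record_v = 2)
  v <- attr(rec, "v_trace")

  sp_ms <- rec$times[rec$ids == 1] * 1000
  expect_gte(length(sp_ms), 1)
  k_spike <- round(min(sp_ms) / 0.1) - 1     # engine step of first emission
  arrival <- k_spike + 1 + 10                # +1 step offset, +10 delay steps
  # before arrival, target follows pure leak: (v - El) ratio is constant
  El <- neuron_params()$E_leak
  ratios <- diff(v - El) / utils::head(v - El, -1)
  expect_lt(max(abs(ratios[2:(arrival - 1)] - ratios[2])), 1e-12)
  expect_gt(abs(ratios[arrival] - ratios[2]), 1e-6)
})

test_that("engine STP delivery matches the two-neuron oracle", {
  np <- neuron_params(); sp <- synapse_params()
  for (variant in c("STD1", "STF2")) {
    syn <- data.frame(source = 1, target = 2, weight_nS = 40, delay_ms = 0.7,
                      is_inhibitory = FALSE)
    spec <- micro_network(N = 5, synapses = syn, stp = variant)
    cfg <- simulation_config(T = 0.4, burn_in = 0.1, IF = 0, seed = 31, N = 5,
                             scale = "desk")
    ev <- data.frame(time_s = seq(0.02, 0.38, by = 0.004), neuron = 1)
    rec <- run_simulation(spec, cfg, ext_events = ev, record_v = 2)

    set.seed(cfg$seed)
    V0 <- runif(5, np$V_reset, np$V_threshold)
    ms <- maturation_state("immature")
    src <- scalar_lif_oracle(np, sp, ms, 0.1, 4000, V0[1],
                             ext_times_ms = ev$time_s * 1000)
    expect_equal(rec$times[rec$ids == 1] * 1000, src$spike_ms,
                 tolerance = 1e-9)
    v2 <- two_neuron_oracle(np, sp, ms, stp_variant(variant), 0.1, 4000,
                            V0[2], src$spike_ms, weight = 40, delay_ms = 0.7)
    expect_equal(attr(rec, "v_trace"), v2, tolerance = 1e-8)
  }
})

test_that("refractory floor holds across a whole network run", {
  spec <- build_network("B-1", "immature", "none", seed = 6, N = 100)
  cfg <- simulation_config(T = 5, burn_in = 1, IF = 30, seed = 9, N = 100,
                           scale = "desk")
  rec <- run_simulation(spec, cfg)
  expect_gt(length(rec$times), 100)
  expect_gte(per_neuron_isi_min(rec), 5e-3)
  expect_true(all(rec$times >= 0 & rec$times <= 5))
})

test_that("identical (spec, cfg, seed) gives byte-identical records", {
  spec <- build_network("A-2", "mature", "STF1", seed = 12, N = 100)
  cfg <- simulation_config(T = 3, burn_in = 1, IF = 15, seed = 77, N = 100,
                           scale = "desk")
  r1 <- run_simulation(spec, cfg)
  r2 <- run_simulation(spec, cfg)
  expect_identical(r1$times, r2$times)
  expect_identical(r1$ids, r2$ids)
})

test_that("sweep produces the factorial grid, derived seeds, and resumes", {
  cfg <- simulation_config(T = 1.5, burn_in = 0.5, n_trials = 2, seed = 5,
                           N = 50, scale = "desk")
  tab <- sweep_msf(c("A-1", "B-1"), "immature", c("none", "STD1"),
                   c(10, 20), cfg)
  expect_s3_class(tab, "msf_table")
  expect_equal(nrow(tab), 2 * 1 * 2 * 2 * 2)
  expect_true(all(!is.na(tab$msf_hz)))
  expect_true(all(tab$msf_hz >= 0))
  # control-only sweep
  tab0 <- sweep_msf("A-1", "immature", character(0), 10, cfg)
  expect_true(all(tab0$stp_class == "none"))
  # resumability: partial table is completed identically
  part <- tab[tab$scenario == "A-1", ]
  tab2 <- sweep_msf(c("A-1", "B-1"), "immature", c("none", "STD1"),
                    c(10, 20), cfg, existing = part)
  o <- function(d) d[order(d$scenario, d$stp_class, d$if_hz, d$trial), ]
  expect_equal(o(tab2)$msf_hz, o(tab)$msf_hz)
  # full-scale grid cardinality (arithmetic only)
  expect_equal(6 * 2 * 5 * 20 * 12, 14400)
})

test_that("halving dt changes network-mean MSF by < 5% at scaled size", {
  msf_at <- function(dt) {
    mean(vapply(1:3, function(s) {
      spec <- build_network("B-1", "immature", "none", seed = 100 + s,
                            N = 200)
      cfg <- simulation_config(dt = dt, T = 8, burn_in = 2, IF = 20,
                               seed = 200 + s, N = 200, scale = "desk")
      mean_spike_frequency(run_simulation(spec, cfg), 2)
    }, 0))
  }
  m1 <- msf_at(0.1)
  m2 <- msf_at(0.05)
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("derive_seed is stable, keyed, and within 31 bits", {
  s1 <- derive_seed(1, "B-1", "immature", "none", 20, 3)
  s2 <- derive_seed(1, "B-1", "immature", "none", 20, 3)
  s3 <- derive_seed(1, "B-1", "immature", "none", 20, 4)
  expect_identical(s1, s2)
  expect_false(s1 == s3)
  expect_true(s1 >= 1 && s1 < 2^31)
})
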