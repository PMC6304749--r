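test_that("mean spike frequency: empty, regular train, generator truth", {
  empty <- structure(list(times = numeric(0), ids = integer(0), N = 10,
                          T = 100, dt = NA, classes = rep(FALSE, 10),
                          config = NULL), class = "spike_record")
  expect_equal(mean_spike_frequency(empty, 50), 0)
  expect_error(mean_spike_frequency(empty, 100), "burn_in")

  # 1 neuron spiking every 0.1 s over (50, 2000]
  reg <- structure(list(times = seq(50.1, 2000, by = 0.1), ids = 1L, N = 1,
                        T = 2000, dt = NA, classes = FALSE, config = NULL),
                   class = "spike_record")
  expect_equal(mean_spike_frequency(reg, 50), 10, tolerance = 1e-9)

  rec <- gen_spike_record(100, T = 100, rate = 10, seed = 21)
  se <- sqrt(10 / (100 * 100))
  expect_lt(abs(mean_spike_frequency(rec, 0) - 10), 3 * se)
})

test_that("percent change reproduces the worked examples and round-trips", {
  a <- percent_change(25.8, 6)
  expect_equal(a$percent_rounded, 76.7)
  expect_equal(a$direction, "reduction")
  b <- percent_change(65.0, 78.2)
  expect_equal(b$percent_rounded, 20.3)
  expect_equal(b$direction, "increase")
  z <- percent_change(40, 40)
  expect_equal(z$percent, 0)
  expect_equal(z$direction, "none")
  expect_error(percent_change(0, 5), "before")
  # round-trip identity: percent_change(b, b(1 - p/100)) == p
  set.seed(4)
  for (p in c(runif(20, -80, 80), 5, 50)) {
    out <- percent_change(37.3, 37.3 * (1 - p / 100))
    expect_equal(out$percent, abs(p), tolerance = 1e-10)
  }
})

test_that("modulation classification covers the 8-case truth table", {
  truth <- rbind(
    c("STD1", "reduction", "predicted"),
    c("STD2", "reduction", "predicted"),
    c("STD1", "increase", "unpredicted"),
    c("STD2", "increase", "unpredicted"),
    c("STF1", "increase", "predicted"),
    c("STF2", "increase", "predicted"),
    c("STF1", "reduction", "unpredicted"),
    c("STF2", "reduction", "unpredicted"))
  for (i in seq_len(nrow(truth))) {
    expect_identical(classify_modulation(truth[i, 1], truth[i, 2]),
                     truth[i, 3])
  }
  expect_identical(classify_modulation("STF2", "none"), "none")
  expect_error(classify_modulation("control", "reduction"), "control")
})

test_that("band labels follow the caption with lower-band boundaries", {
  expect_identical(band_label(5), "theta")
  expect_identical(band_label(10), "alpha")
  expect_identical(band_label(c(15, 30)), c("beta", "beta"))
  expect_identical(band_label(c(35, 50)), c("low-gamma", "low-gamma"))
  expect_identical(band_label(c(55, 80)), c("high-gamma", "high-gamma"))
  expect_identical(band_label(c(85, 250)), c("epsilon", "epsilon"))
  expect_error(band_label(2), "range")
  expect_error(band_label(251), "range")
})

test_that("gaussian PDF filter keeps normal samples and drops bimodal or degenerate ones", {
  set.seed(77)
  keep <- gaussian_pdf_filter(rnorm(12, 50, 4))
  expect_true(keep$keep)
  # equal mixture of two Gaussians 6 SDs apart
  bimodal <- c(rnorm(6, 20, 1), rnorm(6, 26, 1))
  drop <- gaussian_pdf_filter(bimodal)
  expect_false(drop$keep)
  flat <- gaussian_pdf_filter(rep(5, 12))
  expect_false(flat$keep)
  expect_match(flat$reason, "degenerate")
  expect_error(gaussian_pdf_filter(c(1, 2)), "3 trials")
})

test_that("van Rossum distances: identity, symmetry, closed form, quadrature", {
  mk <- function(trains, T = 1) {
    structure(list(times = unlist(trains),
                   ids = rep(seq_along(trains), lengths(trains)),
                   N = length(trains), T = T, dt = NA,
                   classes = rep(FALSE, length(trains)), config = NULL),
              class = "spike_record")
  }
  tau <- 20 / 1000
  # identical trains -> 0; matrix symmetric with zero diagonal
  rec <- mk(list(c(0.1, 0.3), c(0.1, 0.3), c(0.2)))
  D <- spike_distance_matrix(rec, subsample = NULL, kernel_tau = 20)
  expect_equal(D[1, 2], 0)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), rownames(D)))

  # two single-spike trains at offset delta: D = sqrt(1 - exp(-delta/tau))
  for (delta in c(0.001, 0.01, 0.05)) {
    rec2 <- mk(list(0.2, 0.2 + delta))
    D2 <- spike_distance_matrix(rec2, subsample = NULL, kernel_tau = 20)
    expect_equal(D2[1, 2], sqrt(1 - exp(-delta / tau)), tolerance = 1e-10)
  }

  # multi-spike case against direct quadrature of the filtered difference
  t1 <- c(0.10, 0.13, 0.31); t2 <- c(0.11, 0.25)
  f <- function(t, tr) rowSums(vapply(tr, function(s) {
    ifelse(t >= s, exp(-(t - s) / tau), 0)
  }, numeric(length(t))))
  num <- sqrt(integrate(function(t) (f(t, t1) - f(t, t2))^2, 0, 2,
                        subdivisions = 2000, rel.tol = 1e-10)$value / tau)
  rec3 <- mk(list(t1, t2), T = 2)
  D3 <- spike_distance_matrix(rec3, subsample = NULL, kernel_tau = 20)
  expect_equal(D3[1, 2], num, tolerance = 1e-6)

  # burn-in excludes early spikes
  rec4 <- mk(list(c(0.05, 0.5), c(0.5)))
  D4 <- spike_distance_matrix(rec4, subsample = NULL, kernel_tau = 20,
                              burn_in = 0.1)
  expect_equal(D4[1, 2], 0)
})

test_that("stage mapping: printed reference windows, ties, outside", {
  refs <- stage_reference()
  expect_equal(refs$mean_hz, c(7.86, 54.27))
  expect_equal(refs$sd_hz, c(1.30, 7.22))
  expect_match(stage_map(6.0), "pre-shift")
  expect_match(stage_map(54.27), "shift")
  expect_identical(stage_map(133.8), "outside")
  expect_identical(stage_map(20), "outside")   # between the two windows
  # nearer mean wins when intervals overlap (forced with large k)
  expect_match(stage_map(10, k = 20), "pre-shift")
  expect_match(stage_map(50, k = 20), "shift")
  expect_error(stage_map(-1), "msf")
})

test_that("factorial ANOVA matches the textbook one-way oracle and conserves SS", {
  # 3 x 4 toy table, two factors so the module accepts it; collapse to
  # one-way by keeping the second factor at its margin
  set.seed(10)
  toy <- expand.grid(g = c("a", "b", "c"), r = 1:4)
  toy$y <- c(rnorm(12, rep(c(10, 12, 20), 4), 1))
  hand <- oneway_anova_oracle(toy$y, toy$g)
  fit <- stats::aov(y ~ g, data = toy)
  s <- summary(fit)[[1]]
  expect_equal(s[["Sum Sq"]][1], hand$ss_between, tolerance = 1e-12)
  expect_equal(s[["Sum Sq"]][2], hand$ss_within, tolerance = 1e-12)

  # the module's 2/3-factor decompositions conserve total SS
  tab <- gen_msf_table(noise_sd = 4, seed = 5,
                       maturation_offsets = c(immature = 10))
  res3 <- anova_factorial(tab, c("scenario", "maturation", "stp_class"))
  expect_equal(sum(res3$sumsq), attr(res3, "total_ss"), tolerance = 1e-8)
  expect_equal(sum(res3$df), nrow(tab) - 1)
  expect_true(all(res3$sumsq >= 0))
  # injected large maturation effect is detected overwhelmingly
  p_mat <- res3$p_value[res3$term == "maturation"]
  expect_lt(p_mat, 1e-6)

  res2 <- anova_factorial(tab, c("scenario", "maturation"))
  expect_equal(sum(res2$sumsq), attr(res2, "total_ss"), tolerance = 1e-8)

  # one-level factor errors
  sub <- tab[tab$maturation == "immature", ]
  expect_error(anova_factorial(sub, c("scenario", "maturation")), "levels")
})

test_that("modulation_table pairs STP cells with control and labels them", {
  tab <- rbind(
    data.frame(scenario = "B-2", maturation = "immature", stp_class = "none",
               if_hz = 5, trial = 1:3, msf_hz = c(25.8, 25.8, 25.8)),
    data.frame(scenario = "B-2", maturation = "immature", stp_class = "STF2",
               if_hz = 5, trial = 1:3, msf_hz = c(6, 6, 6)),
    data.frame(scenario = "B-2", maturation = "immature", stp_class = "STD1",
               if_hz = 5, trial = 1:3, msf_hz = c(30, 30, 30)))
  out <- modulation_table(tab)
  stf2 <- out[out$stp_class == "STF2", ]
  expect_equal(stf2$percent_change, 76.7)
  expect_identical(stf2$direction, "reduction")
  expect_identical(stf2$label, "unpredicted")  # facilitation that reduces
  std1 <- out[out$stp_class == "STD1", ]
  expect_identical(std1$direction, "increase")
  expect_identical(std1$label, "unpredicted")
})
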