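# Seed-deterministic generators emulating the statistical structure the
# analysis assumes, so every analysis stage is testable without the
# simulator.  Every generator attaches machine-readable ground truth.

#' Generate a synthetic spike record of independent Poisson trains
#'
#' Constant per-neuron rates, optionally with a single global rate change
#' at `t_change` (piecewise-constant profile).  Ground truth is attached as
#' `attr(rec, "ground_truth")`.
#'
#' @param n_neurons neuron count.
#' @param T duration, s.
#' @param rate firing rate, Hz: scalar or per-neuron vector (`>= 0`).
#' @param seed RNG seed.
#' @param t_change optional changepoint, s.
#' @param rate2 rate(s) after the changepoint.
#' @return a `spike_record`.
#' @export
gen_spike_record <- function(n_neurons, T, rate, seed = NULL,
                             t_change = NULL, rate2 = NULL) {
  rate <- rep_len(rate, n_neurons)
  stopifnot(all(rate >= 0), T > 0)
  segs <- if (is.null(t_change)) {
    list(list(t0 = 0, t1 = T, rate = rate))
  } else {
    stopifnot(t_change > 0, t_change < T, !is.null(rate2))
    list(list(t0 = 0, t1 = t_change, rate = rate),
         list(t0 = t_change, t1 = T, rate = rep_len(rate2, n_neurons)))
  }
  times <- numeric(0); ids <- integer(0)
  with_seed(seed, {
    for (seg in segs) {
      for (i in seq_len(n_neurons)) {
        tt <- poisson_train(seg$rate[i], seg$t1 - seg$t0) + seg$t0
        times <- c(times, tt)
        ids <- c(ids, rep.int(i, length(tt)))
      }
    }
  })
  rec <- structure(list(times = times, ids = ids, N = n_neurons, T = T,
                        dt = NA_real_, classes = rep(FALSE, n_neurons),
                        config = NULL),
                   class = "spike_record")
  attr(rec, "ground_truth") <- list(segments = segs)
  rec
}

#' Generate a synthetic factorial MSF table
#'
#' Gaussian per-trial samples around additive factorial cell means over the
#' full scenario x maturation x STP-class design (12 trials per cell by
#' default), the substrate for ANOVA calibration and power tests.  Ground
#' truth (cell means, offsets, noise SD) is attached as an attribute.
#'
#' @param grand_mean grand mean MSF, Hz.
#' @param scenario_offsets named numeric offsets per scenario (defaults 0
#'   for the six named scenarios).
#' @param maturation_offsets named offsets for `immature`/`mature`.
#' @param stp_offsets named offsets for `none`, `STD1`, `STD2`, `STF1`,
#'   `STF2`.
#' @param noise_sd trial noise SD, Hz.
#' @param n_trials trials per cell.
#' @param if_hz input frequency stamped on the rows (single value).
#' @param seed RNG seed.
#' @return an `msf_table` data.frame.
#' @export
gen_msf_table <- function(grand_mean = 60,
                          scenario_offsets = NULL,
                          maturation_offsets = NULL,
                          stp_offsets = NULL,
                          noise_sd = 5, n_trials = 12, if_hz = 20,
                          seed = NULL) {
  scen <- list_scenarios()
  mat <- c("immature", "mature")
  stp <- c("none", "STD1", "STD2", "STF1", "STF2")
  fill <- function(off, lv) {
    out <- stats::setNames(rep(0, length(lv)), lv)
    if (!is.null(off)) {
      stopifnot(all(names(off) %in% lv))
      out[names(off)] <- off
    }
    out
  }
  so <- fill(scenario_offsets, scen)
  mo <- fill(maturation_offsets, mat)
  po <- fill(stp_offsets, stp)
  grid <- expand.grid(scenario = scen, maturation = mat, stp_class = stp,
                      trial = seq_len(n_trials), stringsAsFactors = FALSE)
  mu <- grand_mean + so[grid$scenario] + mo[grid$maturation] +
    po[grid$stp_class]
  if (any(mu < 0)) stop("a factorial cell mean is negative")
  grid$if_hz <- if_hz
  grid$msf_hz <- with_seed(seed, rnorm(nrow(grid), mean = mu, sd = noise_sd))
  grid <- grid[c("scenario", "maturation", "stp_class", "if_hz", "trial",
                 "msf_hz")]
  attr(grid, "ground_truth") <- list(grand_mean = grand_mean,
                                     scenario_offsets = so,
                                     maturation_offsets = mo,
                                     stp_offsets = po,
                                     noise_sd = noise_sd)
  class(grid) <- c("msf_table", "data.frame")
  grid
}

#' Catalog of the model's printed before/after MSF modulation pairs
#'
#' Bundled fixture table of worked-example (control, with-STP) MSF pairs
#' with the percentage each was printed with.  Rows whose printed
#' percentage disagrees with round-half-even recomputation at one decimal
#' carry `consistent = FALSE` (see the `note` column) and are excluded from
#' exact-match tests.
#'
#' @param scenario,stp_class,if_hz optional filters.
#' @param consistent_only drop the arithmetically inconsistent rows.
#' @return data.frame of modulation pair records (possibly empty).
#' @export
gen_modulation_pairs <- function(scenario = NULL, stp_class = NULL,
                                 if_hz = NULL, consistent_only = FALSE) {
  path <- system.file("extdata", "modulation_catalog.csv",
                      package = "gabanet", mustWork = TRUE)
  cat_df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(scenario)) cat_df <- cat_df[cat_df$scenario %in% scenario, ]
  if (!is.null(stp_class)) cat_df <- cat_df[cat_df$stp_class %in% stp_class, ]
  if (!is.null(if_hz)) cat_df <- cat_df[cat_df$if_hz %in% if_hz, ]
  if (consistent_only) cat_df <- cat_df[cat_df$consistent, ]
  rownames(cat_df) <- NULL
  cat_df
}
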