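# The measurement pipeline: MSF, percent modulation and predicted /
# unpredicted classification, band labels, Gaussian PDF trial filtering,
# van Rossum spike-distance matrices, developmental-stage mapping and
# factorial ANOVA.

#' Network-mean spike frequency after burn-in
#'
#' Total spikes after `burn_in` divided by `N * (T - burn_in)`: the
#' network-average per-neuron firing rate in Hz.  (The per-neuron network
#' mean is used — not the network-summed rate — because the model's
#' reported values, 6-150 Hz, are per-neuron scale.)
#'
#' @param rec a `spike_record`.
#' @param burn_in initial transient to discard, s (`< rec$T`).
#' @return rate, Hz; 0 for an empty record.
#' @export
mean_spike_frequency <- function(rec, burn_in = rec$config$burn_in %||% 0) {
  if (burn_in >= rec$T) stop("burn_in must be smaller than T")
  sum(rec$times > burn_in) / (rec$N * (rec$T - burn_in))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent modulation of MSF by STP
#'
#' `100 * (before - after) / before`, reported as a magnitude with a
#' direction word: `"reduction"` when positive, `"increase"` when negative,
#' `"none"` when the magnitude is below `none_band` (degenerate near-zero
#' changes).  `percent_rounded` applies round-half-even at one decimal,
#' matching how the model's worked examples are printed.
#'
#' @param before control MSF, Hz (`> 0`).
#' @param after MSF with STP, Hz.
#' @param none_band magnitude (percent) below which direction is `"none"`.
#' @return `list(percent, percent_rounded, direction)`; `percent` is the
#'   magnitude.
#' @export
percent_change <- function(before, after, none_band = 1) {
  if (before <= 0) stop("before must be > 0")
  signed <- 100 * (before - after) / before
  direction <- if (abs(signed) < none_band) "none"
               else if (signed > 0) "reduction" else "increase"
  list(percent = abs(signed), percent_rounded = round(abs(signed), 1),
       direction = direction)
}

#' Classify a modulation as predicted or unpredicted
#'
#' Depressing synapses are canonically expected to reduce firing and
#' facilitating synapses to increase it; matches are `"predicted"`,
#' reversals `"unpredicted"`, degenerate `"none"` directions stay `"none"`.
#'
#' @param stp_class `"STD1"`, `"STD2"`, `"STF1"` or `"STF2"` (`"control"`
#'   errors).
#' @param direction `"reduction"`, `"increase"` or `"none"`.
#' @return `"predicted"`, `"unpredicted"` or `"none"`.
#' @export
classify_modulation <- function(stp_class, direction) {
  stp_class <- toupper(stp_class)
  if (stp_class %in% c("CONTROL", "NONE")) {
    stop("modulation is only defined relative to the control condition")
  }
  if (!stp_class %in% c("STD1", "STD2", "STF1", "STF2")) {
    stop("unknown STP class '", stp_class, "'")
  }
  direction <- match.arg(direction, c("reduction", "increase", "none"))
  if (direction == "none") return("none")
  depressing <- substr(stp_class, 1, 3) == "STD"
  if ((depressing && direction == "reduction") ||
      (!depressing && direction == "increase")) "predicted" else "unpredicted"
}

.bands <- data.frame(
  band = c("theta", "alpha", "beta", "low-gamma", "high-gamma", "epsilon"),
  lo = c(3, 7, 12, 30, 50, 80),
  hi = c(7, 12, 30, 50, 80, 250),
  stringsAsFactors = FALSE
)

#' Oscillation-band label for an input frequency
#'
#' theta (3-7], alpha (7-12], beta (12-30], low-gamma (30-50],
#' high-gamma (50-80], epsilon (80-250] Hz.  Shared boundaries belong to
#' the lower band (30 Hz is beta, 80 Hz is high-gamma), matching the
#' model's worked examples.
#'
#' @param IF input frequency, Hz; must lie in `(3, 250]`.
#' @return character vector of band labels.
#' @export
band_label <- function(IF) {
  if (any(IF <= 3 | IF > 250)) {
    stop("IF outside the labelled range (3, 250] Hz")
  }
  idx <- findInterval(IF, .bands$lo, left.open = TRUE,
                      rightmost.closed = FALSE)
  # findInterval with left.open: IF in (lo[i], lo[i+1]] -> i
  .bands$band[idx]
}

#' Gaussian PDF filter for per-trial MSF samples
#'
#' Screens a condition's per-trial MSF sample for departures from the
#' fitted Gaussian: conditions whose sample fails a Shapiro-Wilk normality
#' test at `alpha` are excluded from downstream interpretation, as are
#' degenerate (zero-variance) samples.
#'
#' @param trial_msfs numeric vector of per-trial MSF values, Hz (>= 3).
#' @param alpha rejection level.
#' @return `list(keep, p_value, statistic, mean, sd, reason)`.
#' @export
gaussian_pdf_filter <- function(trial_msfs, alpha = 0.05) {
  if (length(trial_msfs) < 3) stop("need at least 3 trials")
  m <- mean(trial_msfs)
  s <- sd(trial_msfs)
  if (s == 0) {
    return(list(keep = FALSE, p_value = NA_real_, statistic = NA_real_,
                mean = m, sd = 0,
                reason = "degenerate fit: zero variance across trials"))
  }
  sw <- shapiro.test(trial_msfs)
  keep <- sw$p.value >= alpha
  list(keep = keep, p_value = unname(sw$p.value),
       statistic = unname(sw$statistic), mean = m, sd = s,
       reason = if (keep) "consistent with a Gaussian PDF"
                else "normality rejected")
}

#' Pairwise van Rossum spike-train distance matrix
#'
#' Each train is convolved with a causal exponential kernel of time
#' constant `kernel_tau`; the distance is the L2 norm of the difference,
#' normalized so two single-spike trains at offset `delta` are at distance
#' `sqrt(1 - exp(-delta / tau))`.  Computed over a subsample of neurons on
#' `(burn_in, T]`.  The metric choice is a package convention (the kernel
#' metric with a closed-form oracle), not prescribed by the model.
#'
#' @param rec a `spike_record`.
#' @param subsample number of neurons (evenly spaced ids); `NULL` for all.
#' @param kernel_tau kernel time constant, ms.
#' @param burn_in discarded initial transient, s.
#' @return symmetric matrix with zero diagonal; neuron ids as dimnames.
#' @export
spike_distance_matrix <- function(rec, subsample = 100, kernel_tau = 20,
                                  burn_in = 0) {
  ids <- if (is.null(subsample) || subsample >= rec$N) seq_len(rec$N)
         else unique(round(seq(1, rec$N, length.out = subsample)))
  if (length(ids) < 2) stop("need at least 2 neurons")
  tau_s <- kernel_tau / 1000
  trains <- lapply(ids, function(i) {
    sort(rec$times[rec$ids == i & rec$times > burn_in])
  })
  n <- length(ids)
  auto <- vapply(trains, function(tr) vr_cross_sum(tr, tr, tau_s), 0)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- 0.5 * (auto[i] + auto[j] -
                     2 * vr_cross_sum(trains[[i]], trains[[j]], tau_s))
      D[i, j] <- D[j, i] <- sqrt(max(0, d2))
    }
  }
  D
}

#' Reference MSF windows from developing cultures on multi-electrode arrays
#'
#' Mean and SD of the experimentally reported network firing rate before
#' the GABA-A shift (5-10 days in vitro) and during it (11-17 DIV).
#'
#' @return data.frame with columns `window`, `mean_hz`, `sd_hz`.
#' @export
stage_reference <- function() {
  data.frame(window = c("pre-shift (5-10 DIV)", "shift (11-17 DIV)"),
             mean_hz = c(7.86, 54.27), sd_hz = c(1.30, 7.22),
             stringsAsFactors = FALSE)
}

#' Map an MSF value onto a developmental-stage window
#'
#' A value maps to the reference window whose interval `mean +/- k * sd`
#' contains it; when several windows match, the nearer mean wins; values in
#' no interval map to `"outside"`.
#'
#' @param msf MSF value(s), Hz (`>= 0`).
#' @param refs reference table as from [stage_reference()].
#' @param k SD multiplier defining the window half-width.
#' @return character vector of window labels.
#' @export
stage_map <- function(msf, refs = stage_reference(), k = 2) {
  if (any(msf < 0)) stop("msf must be >= 0")
  vapply(msf, function(m) {
    inside <- abs(m - refs$mean_hz) <= k * refs$sd_hz
    if (!any(inside)) return("outside")
    cand <- which(inside)
    refs$window[cand[which.min(abs(m - refs$mean_hz[cand]))]]
  }, character(1))
}

#' Fixed-effects factorial ANOVA on an MSF table
#'
#' Full factorial decomposition (all main effects and interactions) with
#' F tests against the residual, for 2 or 3 crossed factors.  Sequential
#' (Type-I) sums of squares; the sweep produces balanced designs, for which
#' Types I/II/III coincide.
#'
#' @param table a data.frame (e.g. from [sweep_msf()] or
#'   [gen_msf_table()]).
#' @param factors character vector of 2 or 3 factor column names.
#' @param response response column name.
#' @return data.frame with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p_value` (residual row included); total SS in
#'   `attr(, "total_ss")`.
#' @export
anova_factorial <- function(table, factors, response = "msf_hz") {
  stopifnot(length(factors) %in% c(2L, 3L),
            all(factors %in% names(table)), response %in% names(table))
  dat <- table[stats::complete.cases(table[c(factors, response)]), ]
  for (f in factors) {
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) < 2) {
      stop("factor '", f, "' has fewer than 2 levels")
    }
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = " * ")))
  fit <- aov(fml, data = dat)
  s <- summary(fit)[[1]]
  out <- data.frame(term = trimws(rownames(s)), df = s[["Df"]],
                    sumsq = s[["Sum Sq"]], meansq = s[["Mean Sq"]],
                    statistic = s[["F value"]], p_value = s[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total_ss") <- sum((dat[[response]] - mean(dat[[response]]))^2)
  out
}

#' Modulation records for a sweep table
#'
#' Convenience wrapper: averages trials per cell, pairs each STP condition
#' with its control, and returns percent change, direction and the
#' predicted/unpredicted label.
#'
#' @param table an `msf_table` containing a `"none"` (control) stp class.
#' @param pdf_alpha when non-`NULL`, conditions failing the Gaussian PDF
#'   filter at this level (either member of the pair) are marked
#'   `filtered = TRUE`.
#' @return data.frame of modulation records.
#' @export
modulation_table <- function(table, pdf_alpha = NULL) {
  stopifnot("none" %in% table$stp_class)
  key <- c("scenario", "maturation", "if_hz")
  agg <- stats::aggregate(table$msf_hz,
                          by = table[c(key, "stp_class")], FUN = mean)
  names(agg)[ncol(agg)] <- "msf_hz"
  ctrl <- agg[agg$stp_class == "none", ]
  mod <- agg[agg$stp_class != "none", ]
  out <- merge(mod, ctrl[, c(key, "msf_hz")], by = key,
               suffixes = c("_after", "_before"))
  recs <- lapply(seq_len(nrow(out)), function(i) {
    pc <- percent_change(out$msf_hz_before[i], out$msf_hz_after[i])
    filtered <- FALSE
    if (!is.null(pdf_alpha)) {
      for (cls in c("none", out$stp_class[i])) {
        sel <- table$scenario == out$scenario[i] &
          table$maturation == out$maturation[i] &
          table$if_hz == out$if_hz[i] & table$stp_class == cls
        if (sum(sel) >= 3 &&
            !gaussian_pdf_filter(table$msf_hz[sel], pdf_alpha)$keep) {
          filtered <- TRUE
        }
      }
    }
    data.frame(scenario = out$scenario[i], maturation = out$maturation[i],
               stp_class = out$stp_class[i], if_hz = out$if_hz[i],
               msf_before = out$msf_hz_before[i],
               msf_after = out$msf_hz_after[i],
               percent_change = pc$percent_rounded,
               direction = pc$direction,
               label = classify_modulation(out$stp_class[i], pc$direction),
               filtered = filtered, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
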