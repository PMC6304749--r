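# Gaussian distance-dependent wiring on a periodic 1 mm^2 lattice with fixed
# in-degree K, the six named scenarios, and distance-dependent delays.

#' Lattice geometry: neuron positions on a periodic square
#'
#' @param N number of neurons (ignored when `positions` is given).
#' @param L lattice side length, mm.
#' @param positions optional N x 2 matrix of coordinates in `[0, L)`.
#' @param arrangement `"uniform"` for uniform random placement (the model's
#'   stated world; neuron density is uniform), `"grid"` for a deterministic
#'   regular grid (tests).
#' @param periodic logical; apply periodic boundary conditions.
#' @param seed optional RNG seed for the uniform placement.
#' @return an object of class `lattice_geometry` with fields `L`,
#'   `positions`, `periodic`, `N`.
#' @export
lattice_geometry <- function(N = NULL, L = 1, positions = NULL,
                             arrangement = c("uniform", "grid"),
                             periodic = TRUE, seed = NULL) {
  arrangement <- match.arg(arrangement)
  if (is.null(positions)) {
    stopifnot(!is.null(N), N >= 1, L > 0)
    if (arrangement == "uniform") {
      positions <- with_seed(seed, matrix(runif(2 * N, 0, L), ncol = 2))
      # runif's support is open; fold the (measure-zero) endpoint anyway
      positions[positions >= L] <- 0
    } else {
      m <- ceiling(sqrt(N))
      g <- (seq_len(m) - 1) / m * L
      positions <- as.matrix(expand.grid(x = g, y = g))[seq_len(N), ,
                                                        drop = FALSE]
    }
  } else {
    positions <- as.matrix(positions)
    stopifnot(ncol(positions) == 2)
    if (any(positions < 0 | positions >= L)) {
      stop("all coordinates must lie in [0, L)")
    }
  }
  dimnames(positions) <- list(NULL, c("x", "y"))
  structure(list(L = L, positions = positions, periodic = periodic,
                 N = nrow(positions)),
            class = "lattice_geometry")
}

#' Pairwise distance under the minimum-image convention
#'
#' Euclidean distance on the lattice; with periodic boundaries each
#' coordinate difference is wrapped to at most `L/2`, so distances lie in
#' `[0, L * sqrt(2) / 2]`.  Vectorized over rows.
#'
#' @param i_pos,j_pos coordinate pairs (length-2 vectors or n x 2 matrices).
#' @param geom a [lattice_geometry()].
#' @return numeric vector of distances, mm.
#' @export
pair_distance <- function(i_pos, j_pos, geom) {
  a <- matrix(i_pos, ncol = 2)
  b <- matrix(j_pos, ncol = 2)
  if (any(a < 0 | a >= geom$L | b < 0 | b >= geom$L)) {
    stop("coordinates outside the lattice [0, L)")
  }
  dx <- abs(a[, 1] - b[, 1]); dy <- abs(a[, 2] - b[, 2])
  if (geom$periodic) {
    dx <- pmin(dx, geom$L - dx)
    dy <- pmin(dy, geom$L - dy)
  }
  sqrt(dx^2 + dy^2)
}

#' Gaussian connection-probability profile
#'
#' @param r distance, mm (`>= 0`).
#' @param sigma_c lateral spread length, mm (`> 0`).
#' @return `exp(-r^2 / (2 sigma_c^2))`, in `(0, 1]`.
#' @export
gaussian_profile <- function(r, sigma_c) {
  if (any(sigma_c <= 0)) stop("sigma_c must be > 0")
  if (any(r < 0)) stop("r must be >= 0")
  exp(-r^2 / (2 * sigma_c^2))
}

#' Radial density of neighbour distances on the periodic square
#'
#' Probability density of the distance from a fixed point to a uniformly
#' placed neuron under the minimum-image metric:
#' `P(r) = 2 pi r / L^2` for `r <= L/2`,
#' `P(r) = (r / L^2) (2 pi - 8 acos(L / (2 r)))` for `L/2 < r <= L sqrt(2)/2`,
#' and 0 beyond.  Integrates to 1.
#'
#' @param r distance(s), mm (`>= 0`).
#' @param geom a [lattice_geometry()] (only `L` is used).
#' @return density per mm.
#' @export
radial_density <- function(r, geom = lattice_geometry(N = 1, L = 1,
                                                      arrangement = "grid")) {
  if (any(r < 0)) stop("r must be >= 0")
  L <- geom$L
  out <- numeric(length(r))
  near <- r <= L / 2
  out[near] <- 2 * pi * r[near] / L^2
  far <- r > L / 2 & r <= L * sqrt(2) / 2
  out[far] <- (r[far] / L^2) * (2 * pi - 8 * acos(L / (2 * r[far])))
  out
}

#' Distance profile of realized connections
#'
#' `rho(r) = P(r) exp(-r^2 / (2 sigma_c^2))`, the radial density of accepted
#' sources under Gaussian rejection sampling with uniform neuron placement.
#' With `epsilon` supplied the curve is rescaled so that its integral over
#' the full support equals `epsilon` (the model's stated normalization;
#' note the raw curve does not integrate to `epsilon` for the named
#' scenario pairs — `epsilon` enters the model through `K = round(epsilon N)`).
#'
#' @param r distance(s), mm.
#' @param sigma_c lateral spread length, mm.
#' @param geom a [lattice_geometry()].
#' @param epsilon optional target integral.
#' @return density values.
#' @export
rho_profile <- function(r, sigma_c, geom = lattice_geometry(N = 1, L = 1,
                                                            arrangement = "grid"),
                        epsilon = NULL) {
  raw <- function(x) radial_density(x, geom) * gaussian_profile(x, sigma_c)
  out <- raw(r)
  if (!is.null(epsilon)) {
    z <- integrate(raw, 0, geom$L * sqrt(2) / 2, rel.tol = 1e-10)$value
    out <- out * epsilon / z
  }
  out
}

#' Connectivity parameters
#'
#' @param epsilon local density of dendritic arborization, fraction of N
#'   (`0 < epsilon <= 0.21`); fixes the in-degree `K = round(epsilon * N)`.
#' @param sigma_c lateral spread length, fraction of L
#'   (`0 < sigma_c <= 0.10`).
#' @param N neuron count; excitatory/inhibitory split is fixed at 4:1.
#' @return an object of class `connectivity_params` with fields `epsilon`,
#'   `sigma_c`, `K`, `N`, `n_exc`, `n_inh`.
#' @export
connectivity_params <- function(epsilon, sigma_c, N = 3000) {
  stopifnot(epsilon > 0, epsilon <= 0.21, sigma_c > 0, sigma_c <= 0.10,
            N >= 5, N %% 5 == 0)
  n_exc <- as.integer(N * 4 / 5)
  n_inh <- as.integer(N / 5)
  structure(list(epsilon = epsilon, sigma_c = sigma_c,
                 K = as.integer(round(epsilon * N)), N = as.integer(N),
                 n_exc = n_exc, n_inh = n_inh),
            class = "connectivity_params")
}

.scenario_table <- data.frame(
  name = c("A-1", "A-2", "B-1", "B-2", "B-3", "B-4"),
  epsilon_pct = c(1, 1, 9, 10, 19, 20),
  sigma_c_pct = c(9, 10, 1, 1, 1, 1),
  stringsAsFactors = FALSE
)

#' The six named connectivity scenarios
#'
#' A-scenarios share a sparse in-degree (epsilon = 1%) and differ in spatial
#' spread (sigma_c = 9 or 10%); B-scenarios share a narrow spread
#' (sigma_c = 1%) and differ in in-degree (epsilon = 9, 10, 19, 20%).
#'
#' @param name one of `"A-1"`, `"A-2"`, `"B-1"`, `"B-2"`, `"B-3"`, `"B-4"`.
#' @return an object of class `scenario_spec` with fields `name`,
#'   `epsilon_pct`, `sigma_c_pct`, `epsilon`, `sigma_c` (fractions).
#' @export
scenario_spec <- function(name) {
  i <- match(name, .scenario_table$name)
  if (is.na(i)) {
    stop("unknown scenario '", name, "'; valid: ",
         paste(.scenario_table$name, collapse = ", "))
  }
  structure(list(name = name,
                 epsilon_pct = .scenario_table$epsilon_pct[i],
                 sigma_c_pct = .scenario_table$sigma_c_pct[i],
                 epsilon = .scenario_table$epsilon_pct[i] / 100,
                 sigma_c = .scenario_table$sigma_c_pct[i] / 100),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
list_scenarios <- function() .scenario_table$name

#' Propagation delay parameters
#'
#' @param v conduction speed, m/s.
#' @param d_syn fixed synaptic (neurotransmitter release) delay, ms.
#' @return an object of class `delay_params`.
#' @export
delay_params <- function(v = 0.5, d_syn = 0.2) {
  stopifnot(v > 0, d_syn >= 0)
  structure(list(v = v, d_syn = d_syn), class = "delay_params")
}

#' Distance-dependent propagation delay
#'
#' `d = d_syn + r / v`; with `r` in mm and `v` in m/s the quotient is in ms.
#'
#' @param r distance(s), mm (`>= 0`).
#' @param dp a [delay_params()].
#' @return delay(s), ms.
#' @export
compute_delay <- function(r, dp = delay_params()) {
  if (any(r < 0)) stop("r must be >= 0")
  dp$d_syn + r / dp$v
}

#' Sample the fixed-K incoming connections for one neuron
#'
#' Draws exactly `K` distinct presynaptic sources (never the target itself)
#' with probability proportional to the Gaussian profile of their distance
#' to the target.  Implemented as weighted sampling without replacement
#' (exponential-race keys), which is distributionally identical to
#' uniform-proposal rejection sampling in which accepted candidates are
#' removed from the pool.  Weights are rescaled by the nearest candidate so
#' that only truly unreachable candidates underflow to zero; if fewer than
#' `K` candidates have non-zero acceptance weight the sampler stalls with an
#' error (pathologically small `sigma_c`).
#'
#' @param target target neuron id (1-based).
#' @param geom a [lattice_geometry()].
#' @param cp a [connectivity_params()]; `cp$sigma_c` is a fraction of
#'   `geom$L`.
#' @param candidates candidate source ids; default all neurons but the
#'   target.
#' @param K in-degree; default `cp$K`.
#' @return integer vector of `K` source ids.
#' @export
sample_in_connections <- function(target, geom, cp,
                                  candidates = setdiff(seq_len(geom$N), target),
                                  K = cp$K) {
  if (K == 0) return(integer(0))
  candidates <- candidates[candidates != target]
  if (K >= geom$N || K > length(candidates)) {
    stop("K must be smaller than the candidate pool")
  }
  r <- pair_distance(geom$positions[rep(target, length(candidates)), ,
                                    drop = FALSE],
                     geom$positions[candidates, , drop = FALSE], geom)
  sigma <- cp$sigma_c * geom$L
  w <- exp(-(r^2 - min(r^2)) / (2 * sigma^2))
  ok <- w > 0
  if (sum(ok) < K) {
    stop("rejection sampling stalled: only ", sum(ok), " of ",
         length(candidates), " candidates reachable for K = ", K,
         " (sigma_c too small)")
  }
  keys <- rexp(length(candidates)) / w
  candidates[order(keys)[seq_len(K)]]
}

#' Build the full synapse table for a scenario
#'
#' One row per synapse: `source`, `target`, `weight_nS` (`g_exc` for
#' excitatory sources, `g_inh` for inhibitory), `delay_ms`
#' (`d_syn + r / v`), `is_inhibitory`.  Every neuron receives exactly `K`
#' incoming synapses, no self-connections, no duplicate pairs.
#'
#' @param scenario a [scenario_spec()] or scenario name.
#' @param geom a [lattice_geometry()].
#' @param cp a [connectivity_params()]; defaults to the scenario fractions
#'   at `geom$N`.
#' @param dp a [delay_params()].
#' @param sp a [synapse_params()].
#' @return a `data.frame` with `geom$N * cp$K` rows.
#' @export
build_synapse_table <- function(scenario, geom,
                                cp = NULL,
                                dp = delay_params(),
                                sp = synapse_params()) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (is.null(cp)) {
    cp <- connectivity_params(scenario$epsilon, scenario$sigma_c, N = geom$N)
  }
  N <- geom$N
  K <- cp$K
  if (K == 0) {
    return(data.frame(source = integer(0), target = integer(0),
                      weight_nS = numeric(0), delay_ms = numeric(0),
                      is_inhibitory = logical(0)))
  }
  src <- integer(N * K)
  for (tgt in seq_len(N)) {
    src[((tgt - 1) * K + 1):(tgt * K)] <-
      sample_in_connections(tgt, geom, cp)
  }
  tgt <- rep(seq_len(N), each = K)
  r <- pair_distance(geom$positions[tgt, , drop = FALSE],
                     geom$positions[src, , drop = FALSE], geom)
  is_inh <- src > cp$n_exc
  data.frame(source = src, target = tgt,
             weight_nS = ifelse(is_inh, sp$g_inh, sp$g_exc),
             delay_ms = compute_delay(r, dp),
             is_inhibitory = is_inh)
}

#' Continuum sampler of accepted connection distances
#'
#' Validation helper: draws accepted distances by uniform-proposal rejection
#' against the Gaussian profile with a fresh uniformly placed candidate per
#' proposal, so the accepted distances follow exactly
#' `rho(r) = P(r) exp(-r^2 / 2 sigma_c^2)` (normalized).  Used by the
#' distributional acceptance test for the wiring rule.
#'
#' @param n number of accepted distances to return.
#' @param sigma_c lateral spread length, mm.
#' @param L lattice side, mm.
#' @param batch proposals per vectorized round.
#' @param max_rounds stall guard.
#' @return numeric vector of `n` distances, mm.
#' @export
sample_connection_distances <- function(n, sigma_c, L = 1, batch = 2e5,
                                        max_rounds = 1000) {
  geom <- lattice_geometry(N = 1, L = L, positions = matrix(0, 1, 2))
  acc <- numeric(0)
  rounds <- 0
  while (length(acc) < n) {
    rounds <- rounds + 1
    if (rounds > max_rounds) {
      stop("rejection sampling stalled after ", max_rounds, " rounds")
    }
    cand <- matrix(runif(2 * batch, 0, L), ncol = 2)
    r <- pair_distance(matrix(0, batch, 2), cand, geom)
    keep <- runif(batch) < gaussian_profile(r, sigma_c)
    acc <- c(acc, r[keep])
  }
  acc[seq_len(n)]
}
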