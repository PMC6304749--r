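# Plain-text persistence: parameter sets as flat JSON, spike records as
# two-column event text, synapse tables and positions as CSV.

#' Write / read a parameter set as flat JSON
#'
#' Serializes any of the package's parameter objects (`neuron_params`,
#' `synapse_params`, `maturation_state`, `stp_params`, `delay_params`,
#' `connectivity_params`, `simulation_config`) with its class recorded, so
#' `read_params()` restores the object.
#'
#' @param params a parameter object.
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` the
#'   restored object.
#' @export
write_params <- function(params, path) {
  payload <- c(list(.class = class(params)[1]), unclass(params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  structure(payload, class = cls)
}

#' Write / read a spike record as two-column event text
#'
#' Format: comment header lines (`# key: value`) carrying `N`, `T`, `dt`,
#' then whitespace-separated `time_s neuron_id` rows in event order.
#'
#' @param rec a `spike_record`.
#' @param path file path.
#' @export
write_spike_record <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# N: %d", rec$N),
               sprintf("# T: %.10g", rec$T),
               sprintf("# dt: %.10g", if (is.na(rec$dt)) -1 else rec$dt),
               "# columns: time_s neuron_id"), con)
  if (length(rec$times)) {
    writeLines(sprintf("%.9f %d", rec$times, rec$ids), con)
  }
  invisible(path)
}

#' @rdname write_spike_record
#' @export
read_spike_record <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, ": *"), "", m[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, " +"))
    times <- as.numeric(parts[, 1])
    ids <- as.integer(parts[, 2])
  } else {
    times <- numeric(0); ids <- integer(0)
  }
  N <- as.integer(get("N"))
  dt <- get("dt")
  structure(list(times = times, ids = ids, N = N, T = get("T"),
                 dt = if (dt < 0) NA_real_ else dt,
                 classes = rep(FALSE, N), config = NULL),
            class = "spike_record")
}

#' Persist a synapse table or neuron positions as CSV
#'
#' @param x synapse table data.frame or a [lattice_geometry()].
#' @param path file path.
#' @export
write_synapse_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synapse_table
#' @export
read_synapse_table <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_synapse_table
#' @export
write_positions <- function(x, path) {
  stopifnot(inherits(x, "lattice_geometry"))
  df <- data.frame(id = seq_len(x$N), x_mm = x$positions[, 1],
                   y_mm = x$positions[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
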