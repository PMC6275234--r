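#' Plain-text artifact files
#'
#' All simulation artifacts are exchanged as headered whitespace-separated
#' text so that frozen-state replays can be re-run from files alone:
#' \describe{
#'   \item{topology}{columns `source target delay_ms`, one synapse per
#'     line.}
#'   \item{weights}{columns `source target weight`; weights are written
#'     with 17 significant digits for a lossless double round-trip.}
#'   \item{stimulus}{one 1-based neuron index per line; the line number is
#'     the millisecond.}
#'   \item{spikes}{columns `time_ms neuron_id`, time-sorted.}
#' }
#'
#' @param topology,weights,stimulus,spikes the objects to write.
#' @param s a [spike_data()].
#' @param path file path.
#' @param n_exc excitatory population size (topology files record it in a
#'   header comment and `read_topology_file()` recovers it).
#' @name artifact_files
NULL

#' @rdname artifact_files
#' @export
write_topology_file <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_exc %d n_inh %d out_degree %d",
                     topology$n_exc, topology$n_inh, topology$out_degree),
             con)
  writeLines("source target delay_ms", con)
  src <- rep(seq_len(topology$n), topology$out_degree)
  write.table(data.frame(src,
                         as.vector(topology$targets),
                         as.vector(topology$delays)),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname artifact_files
#' @export
read_topology_file <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  n_exc <- as.integer(hdr[3]); n_inh <- as.integer(hdr[5])
  out_degree <- as.integer(hdr[7])
  df <- utils::read.table(path, skip = 1, header = TRUE)
  n <- n_exc + n_inh
  o <- order(df$source)
  df <- df[o, ]
  structure(list(n_exc = n_exc, n_inh = n_inh, n = n,
                 out_degree = out_degree,
                 targets = matrix(as.integer(df$target), n, out_degree,
                                  byrow = TRUE),
                 delays = matrix(as.integer(df$delay_ms), n, out_degree,
                                 byrow = TRUE),
                 seed = NA_integer_),
            class = "spnet_topology")
}

#' @rdname artifact_files
#' @export
write_weight_file <- function(weights, topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("source target weight", con)
  src <- rep(seq_len(topology$n), topology$out_degree)
  writeLines(sprintf("%d %d %.17g", src, as.vector(topology$targets),
                     as.vector(weights)), con)
  invisible(path)
}

#' @rdname artifact_files
#' @export
read_weight_file <- function(path, topology) {
  df <- utils::read.table(path, header = TRUE)
  if (nrow(df) != topology$n * topology$out_degree)
    stop("weight file does not match the topology dimensions")
  df <- df[order(df$source), ]
  matrix(df$weight, topology$n, topology$out_degree, byrow = TRUE)
}

#' @rdname artifact_files
#' @export
write_stimulus_file <- function(stimulus, path) {
  writeLines(as.character(as.integer(stimulus)), path)
  invisible(path)
}

#' @rdname artifact_files
#' @export
read_stimulus_file <- function(path) {
  as.integer(readLines(path))
}

#' @rdname artifact_files
#' @export
write_spike_file <- function(s, path) {
  stopifnot(inherits(s, "spike_data"))
  times <- unlist(s$trains, use.names = FALSE)
  ids <- rep(seq_len(s$n_neurons), lengths(s$trains))
  o <- order(times, ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_ms %.17g n_neurons %d",
                     s$duration, s$n_neurons), con)
  writeLines("time_ms neuron_id", con)
  writeLines(sprintf("%.17g %d", times[o], ids[o]), con)
  invisible(path)
}

#' @rdname artifact_files
#' @export
read_spike_file <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  duration <- as.numeric(hdr[3]); n_neurons <- as.integer(hdr[5])
  df <- utils::read.table(path, skip = 1, header = TRUE)
  spikes_to_data(df$time_ms, df$neuron_id, n_neurons, duration)
}
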