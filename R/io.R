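#' Read and write traces
#'
#' Traces are stored as a plain CSV (`time_ms`, `signal`, `stimulus`)
#' next to a JSON metadata sidecar (`<path>.meta.json`) carrying mode,
#' sampling interval, units, seed and the generating parameters and
#' protocol. The round trip is lossless: numbers are written with
#' shortest round-trippable precision, so samples and `dt` are preserved
#' bit-exactly.
#'
#' @param trace An `ephys_trace`.
#' @param path CSV file path; the sidecar is written at
#'   `paste0(path, ".meta.json")`.
#' @return `write_trace()` the path, invisibly; `read_trace()` an
#'   `ephys_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ephys_trace"))
  # %.17g guarantees a bit-exact double round trip through the text file
  df <- tibble::tibble(time_ms = sprintf("%.17g", trace$time),
                       signal = sprintf("%.17g", trace$signal),
                       stimulus = sprintf("%.17g", trace$stimulus))
  readr::write_csv(df, path)
  md <- trace_metadata(trace)
  side <- list(
    mode = trace_mode(trace),
    dt_ms = trace_dt(trace),
    units = attr(trace, "units", exact = TRUE),
    seed = md$seed,
    noise_sd = md$noise_sd,
    amplitude = md$amplitude %||% md$command,
    protocol = serialize_protocol(md$protocol),
    params = serialize_params(md$params)
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    rlang::abort(paste0("no such trace file: ", path),
                 class = "drgexcite_parse_error")
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    rlang::abort(paste0("missing metadata sidecar: ", sc),
                 class = "drgexcite_parse_error")
  df <- utils::read.csv(path, colClasses = "numeric") # strtod: exact doubles
  need <- c("time_ms", "signal", "stimulus")
  if (!all(need %in% names(df)))
    rlang::abort(
      sprintf("malformed trace file %s: expected columns %s.", path,
              paste(need, collapse = ", ")),
      class = "drgexcite_parse_error")
  md <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(md$units) || is.null(md$units$signal) ||
      is.null(md$units$stimulus))
    rlang::abort(sprintf("sidecar %s lacks a unit declaration.", sc),
                 class = "drgexcite_parse_error")
  expected <- if (identical(md$mode, "current_clamp")) c("mV", "pA") else c("pA", "mV")
  if (!identical(unname(unlist(md$units[c("signal", "stimulus")])), expected))
    rlang::abort(sprintf("sidecar %s declares unexpected units for mode %s.",
                         sc, md$mode),
                 class = "drgexcite_unit_error")
  params <- if (!is.null(md$params)) deserialize_params(md$params)
  protocol <- if (!is.null(md$protocol)) deserialize_protocol(md$protocol)
  new_trace(df$time_ms, df$signal, df$stimulus, dt = as.numeric(md$dt_ms),
            mode = md$mode,
            metadata = list(
              params = params, protocol = protocol,
              amplitude = if (!is.null(md$amplitude)) as.numeric(md$amplitude),
              seed = if (!is.null(md$seed)) as.integer(md$seed),
              noise_sd = if (!is.null(md$noise_sd)) as.numeric(md$noise_sd)))
}

sidecar_path <- function(path) paste0(path, ".meta.json")

serialize_params <- function(p) {
  if (is.null(p)) return(NULL)
  unclass(p)
}

deserialize_params <- function(lst) {
  if (is.null(lst)) return(NULL)
  do.call(neuron_params, lst)
}

serialize_protocol <- function(pr) {
  if (is.null(pr)) return(NULL)
  unclass(pr)
}

deserialize_protocol <- function(lst) {
  if (is.null(lst)) return(NULL)
  new_protocol(lst$kind, unlist(lst$amplitudes), lst$baseline, lst$onset,
               lst$duration, lst$tail, lst$holding_potential)
}
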