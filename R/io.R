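# Trace and configuration serialization. Traces are plain CSV with a fixed
# column order; numbers are written with 12 significant digits, which keeps
# a write/read round trip lossless to well below 1e-9.

.trace_columns <- c("t", "phase_label", "theta", "Q", "V", "Pmus", "Pexo",
                    "Pexo_ref", "Fa", "Fint", "Fplan", "Psup", "Psup_ref",
                    "I")

#' Write a session trace to CSV
#'
#' @param trace a `session_trace`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_session_trace <- function(trace, path) {
  stopifnot(all(.trace_columns %in% names(trace)))
  out <- trace[, .trace_columns]
  for (nm in .trace_columns)
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.12g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session trace from CSV
#'
#' @param path CSV path written by [write_session_trace()].
#' @return a `session_trace` data frame; the sampling frequency is
#'   recovered from the time stamps.
#' @export
read_session_trace <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trace_columns, names(tr))
  if (length(missing))
    stop("not a session trace CSV; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tr <- tr[, .trace_columns]
  if (nrow(tr) > 1L) attr(tr, "fs") <- 1 / stats::median(diff(tr$t))
  class(tr) <- c("session_trace", "data.frame")
  tr
}

#' Read and validate a run configuration
#'
#' YAML configuration with sections `subject` (either `table_id`, or
#' `sample: {seed}`, or explicit fields `alpha_t, mu, delta, delta_unit, R,
#' E, Q0`), `controller` (any [controller_config()] argument), `pneumatics`
#' (any [pneumatic_params()] argument), `sessions` (list with `mode`,
#' `rate`, `duration`, `seed`) and optional `seed`. Every field is bound by
#' the module invariants; violations are errors naming the field.
#'
#' @param path YAML file path.
#' @return list with `subject`, `cfg`, `pneu`, `sessions`, `seed`.
#' @export
read_run_config <- function(path) {
  conf <- yaml::read_yaml(path)
  seed <- if (is.null(conf$seed)) {
    message("config: no seed given, defaulting to 1")
    1L
  } else as.integer(conf$seed)
  sub <- conf$subject
  subject <- if (!is.null(sub$table_id)) {
    subject_from_table(sub$table_id)
  } else if (!is.null(sub$sample)) {
    sample_subject(seed = if (is.null(sub$sample$seed)) seed else
      as.integer(sub$sample$seed))
  } else {
    virtual_subject(
      id = if (is.null(sub$id)) "config" else sub$id,
      tm = transmission_model(sub$alpha_t, sub$mu, sub$delta,
                              if (is.null(sub$delta_unit)) "cmH2O/N" else
                                sub$delta_unit),
      lung = lung_params(sub$R, sub$E),
      breath = breath_pattern(Q0 = if (is.null(sub$Q0)) 0.5 else sub$Q0))
  }
  cfg <- do.call(controller_config,
                 if (is.null(conf$controller)) list() else conf$controller)
  pneu <- do.call(pneumatic_params,
                  if (is.null(conf$pneumatics)) list() else conf$pneumatics)
  sessions <- lapply(conf$sessions, function(s) {
    session_spec(mode = s$mode,
                 rate = if (is.null(s$rate)) 20 else s$rate,
                 duration = if (is.null(s$duration)) 180 else s$duration,
                 seed = if (is.null(s$seed)) seed else s$seed)
  })
  list(subject = subject, cfg = cfg, pneu = pneu, sessions = sessions,
       seed = seed, hash = substr(jsonlite::base64_enc(
         serialize_config_text(conf)), 1, 16))
}

serialize_config_text <- function(conf) {
  charToRaw(paste(utils::capture.output(utils::str(conf)), collapse = "\n"))
}

#' Write an identification or metrics result as JSON
#'
#' @param x a `lung_id`, `metrics_report` or any list-like result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_result_json <- function(x, path) {
  keep <- Filter(function(e) is.numeric(e) || is.character(e),
                 unclass(x)[!names(unclass(x)) %in%
                              c("fitted.values", "residuals", "call")])
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
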