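# Serialization: JSON and YAML carry the full nested parameter set (strict
# schema, lossless); CSV is a flat one-row-per-parameter audit export.

params_to_plain <- function(x) {
  if (is_uq(x)) {
    list(mean = x$mean, sd = x$sd, low = x$low, high = x$high,
         family = x$family, sample = x$sample)
  } else if (is.list(x)) {
    lapply(unclass(x), params_to_plain)
  } else if (is.numeric(x) && length(x) > 1L && !is.null(names(x))) {
    as.list(x)  # keep band/sub-model names as mapping keys
  } else x
}

#' Write a parameter set
#'
#' `"json"` and `"yaml"` write the complete nested schema and round-trip
#' losslessly through [read_params()]; `"csv"` writes the flat audit table of
#' [params_to_table()] (export only). The format is inferred from the file
#' extension when not given.
#'
#' @param params a `cea_params` object.
#' @param path destination file.
#' @param format `"json"`, `"yaml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path, format = c("auto", "json", "yaml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  plain <- params_to_plain(params)
  switch(format,
    json = jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                                na = "null", null = "null", pretty = TRUE),
    yaml = yaml::write_yaml(plain, path, precision = 15L),
    csv  = utils::write.csv(params_to_table(params), path, row.names = FALSE))
  invisible(path)
}

#' Read a parameter set
#'
#' Parses a JSON or YAML parameter file against the strict model schema:
#' every field of the schema must be present and no unknown field is allowed
#' (a typo in a sixty-parameter model must fail loudly, not silently).
#'
#' @param path file written by [write_params()] (or hand-authored to the same
#'   schema).
#' @param format `"json"` or `"yaml"`; inferred from the extension by default.
#' @return A validated `cea_params` object.
#' @export
read_params <- function(path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("parameter file not found: ", path)
  plain <- switch(format,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = yaml::read_yaml(path),
    stop("cannot read format '", format, "'; use json or yaml"))
  params <- plain_to_params(plain)
  v <- validate_params(params)
  if (length(v))
    stop("invalid parameter file ", path, ":\n  ", paste(v, collapse = "\n  "))
  params
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         json = "json", yaml = "yaml", yml = "yaml", csv = "csv",
         stop("cannot infer parameter format from extension of: ", path))
}

num_or_na <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) NA_real_ else as.numeric(x)
}

# Rebuild a cea_params from parsed JSON/YAML, checking it field-for-field
# against the schema implied by the built-in fixture.
plain_to_params <- function(plain) {
  skel <- default_params()
  uq_fields <- c("mean", "sd", "low", "high", "family", "sample")

  walk <- function(sk, got, where) {
    if (is_uq(sk)) {
      if (!is.list(got))
        stop("field ", where, ": expected an uncertain-quantity mapping",
             call. = FALSE)
      extra <- setdiff(names(got), uq_fields)
      if (length(extra))
        stop("field ", where, ": unknown key(s) ", paste(extra, collapse = ", "),
             call. = FALSE)
      if (is.null(got$mean) || is.null(got$family))
        stop("field ", where, ": 'mean' and 'family' are required", call. = FALSE)
      return(uq(num_or_na(got$mean), num_or_na(got$sd), num_or_na(got$low),
                num_or_na(got$high), family = got$family,
                sample = if (is.null(got$sample)) NULL else isTRUE(got$sample)))
    }
    if (is.list(sk)) {
      if (!is.list(got))
        stop("field ", where, ": expected a mapping", call. = FALSE)
      extra <- setdiff(names(got), names(sk))
      if (length(extra))
        stop("field ", where, ": unknown key(s) ", paste(extra, collapse = ", "),
             call. = FALSE)
      missing <- setdiff(names(sk), names(got))
      if (length(missing))
        stop("field ", where, ": missing required key(s) ",
             paste(missing, collapse = ", "), call. = FALSE)
      out <- lapply(names(sk), function(nm)
        walk(sk[[nm]], got[[nm]], paste(where, nm, sep = "/")))
      names(out) <- names(sk)
      return(out)
    }
    if (is.numeric(sk) && length(sk) > 1L) {  # named vector (bands, AF rows)
      gv <- unlist(got)
      if (!setequal(names(gv), names(sk)))
        stop("field ", where, ": expected entries ",
             paste(names(sk), collapse = ", "), call. = FALSE)
      return(as.numeric(gv[names(sk)]) |> stats::setNames(names(sk)))
    }
    if (is.logical(sk)) return(isTRUE(got))
    if (is.integer(sk)) return(as.integer(got))
    as.numeric(got)
  }

  out <- walk(unclass(skel), plain, "")
  names(out) <- names(unclass(skel))
  class(out) <- "cea_params"
  out
}
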