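# Localization response tables: one row per trial with target and
# perceived (response) direction in interaural-polar coordinates.

#' Construct a response set
#'
#' @param trials data.frame with columns `target_lateral`, `target_polar`,
#'   `response_lateral`, `response_polar` (degrees).
#' @param listener_id character identifier.
#' @return object of class `response_set`.
#' @export
response_set <- function(trials, listener_id = "unknown") {
  need <- c("target_lateral", "target_polar", "response_lateral", "response_polar")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  trials <- as.data.frame(trials)[need]
  if (nrow(trials) > 0) {
    validate_angles(trials$target_lateral, trials$target_polar, "targets")
    validate_angles(trials$response_lateral, trials$response_polar, "responses")
  }
  structure(list(listener_id = listener_id, trials = trials),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("Response set '%s': %d trials\n", x$listener_id, nrow(x$trials)))
  invisible(x)
}

#' Read a response table from CSV
#'
#' Expects the header
#' `listener_id,target_lateral,target_polar,response_lateral,response_polar`.
#' Angles are validated; violations are reported with the offending row
#' index. An empty table (header only) yields a 0-trial response set.
#'
#' @param path CSV file path.
#' @return a [response_set()].
#' @export
read_responses_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("listener_id", "target_lateral", "target_polar",
            "response_lateral", "response_polar")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  id <- if (nrow(df) > 0) as.character(df$listener_id[1]) else "unknown"
  response_set(df[setdiff(need, "listener_id")], id)
}

#' Write a response table to CSV
#'
#' @param rs a [response_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_responses_csv <- function(rs, path) {
  stopifnot(inherits(rs, "response_set"))
  df <- cbind(listener_id = rep(rs$listener_id, nrow(rs$trials)), rs$trials)
  if (nrow(df) == 0)
    df <- df[0, c("listener_id", "target_lateral", "target_polar",
                  "response_lateral", "response_polar")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
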