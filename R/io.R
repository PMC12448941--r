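#' Write a tab-separated table
#'
#' Fixed column order as given, header row, floats at 6 significant
#' digits; TSV rather than CSV so locale decimal conventions can never
#' corrupt the numbers.
#'
#' @param rows data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  fmt <- rows
  for (j in seq_along(fmt))
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]]))
      fmt[[j]] <- signif(fmt[[j]], 6)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a tab-separated table with schema validation
#'
#' @param path TSV path.
#' @param required character vector of columns that must be present.
#' @return data.frame.
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(tab))
    if (length(miss) > 0L)
      stop("table ", path, " is missing columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Save / load a recording session
#'
#' Bit-exact round trip of the internal signal container (samples,
#' sampling rate and channel metadata) via R serialization.
#'
#' @param session a [recording_session()] or [bipolar_session()].
#' @param path file path (conventionally `.rds`).
#' @return `write_session`: the path, invisibly. `read_session`: the
#'   session.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, c("recording_session", "bipolar_session")))
  saveRDS(session, path, version = 2)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read session container ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (!inherits(obj, c("recording_session", "bipolar_session")))
    stop(path, " does not contain a recording or bipolar session",
         call. = FALSE)
  obj
}

#' Join functional and structural pathway tables
#'
#' Merges a transmission-feature table (per subject/hemisphere/pathway)
#' with a structural tract-metric table on the shared keys, producing the
#' observation rows consumed by [tf_coupling()].
#'
#' @param functional data.frame with `subject`, `hemisphere`, `pathway`
#'   and the transmission features (`peak_gain`, `pf_ratio`, `omega_p`).
#' @param structural data.frame with the same keys and `fa`, `ad`,
#'   `n_per_area`, `length`.
#' @return Joined data.frame (inner join on the keys).
#' @export
join_observations <- function(functional, structural) {
  keys <- c("subject", "hemisphere", "pathway")
  for (k in keys) {
    if (!k %in% names(functional) || !k %in% names(structural))
      stop("both tables need key column `", k, "`", call. = FALSE)
  }
  merge(functional, structural, by = keys)
}
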