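#' Multichannel depth-electrode recording session
#'
#' Container for a block of simultaneously sampled LFP channels together
#' with the per-channel metadata needed downstream (lead/contact identity
#' and anatomical region label). All channels share one sampling rate and
#' one length; contact indices must be unique within a lead.
#'
#' @param samples numeric matrix, channels x time, in signal units (uV).
#' @param fs sampling rate in Hz.
#' @param channels data.frame with one row per channel and columns
#'   `subject`, `hemisphere`, `lead`, `region`, `contact` (integer contact
#'   index along the lead shaft, proximal to distal).
#'
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(samples, fs, channels) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric channels x time matrix", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive sampling rate in Hz", call. = FALSE)
  required <- c("subject", "hemisphere", "lead", "region", "contact")
  if (!is.data.frame(channels) || !all(required %in% names(channels)))
    stop("`channels` must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (nrow(channels) != nrow(samples))
    stop("one metadata row per channel is required (got ", nrow(channels),
         " rows for ", nrow(samples), " channels)", call. = FALSE)
  dup <- stats::aggregate(contact ~ lead, data = channels,
                          FUN = function(x) anyDuplicated(x) > 0)
  if (any(dup$contact))
    stop("contact indices must be unique within a lead", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channels = as.data.frame(channels, stringsAsFactors = FALSE)),
    class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat("<recording_session> ", nrow(x$samples), " channels x ",
      ncol(x$samples), " samples @ ", x$fs, " Hz (",
      round(ncol(x$samples) / x$fs, 2), " s)\n", sep = "")
  leads <- split(x$channels, x$channels$lead)
  for (ld in leads) {
    cat("  lead ", ld$lead[1], " [", ld$region[1], ", ",
        ld$hemisphere[1], "]: ", nrow(ld), " contacts\n", sep = "")
  }
  invisible(x)
}

#' Bipolar-referenced session
#'
#' Result of the adjacent-contact bipolar montage: each derived channel is
#' the sample-wise difference of two neighbouring contacts on one lead.
#'
#' @param samples numeric matrix, derived channels x time.
#' @param fs sampling rate in Hz.
#' @param pairs data.frame with columns `subject`, `hemisphere`, `lead`,
#'   `region`, `contact_a`, `contact_b` describing each derived channel.
#'
#' @return An object of class `bipolar_session`.
#' @export
bipolar_session <- function(samples, fs, pairs) {
  if (!is.matrix(samples)) stop("`samples` must be a matrix", call. = FALSE)
  required <- c("subject", "hemisphere", "lead", "region",
                "contact_a", "contact_b")
  if (!all(required %in% names(pairs)))
    stop("`pairs` must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  if (nrow(pairs) != nrow(samples))
    stop("one pair row per derived channel is required", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs),
                 pairs = as.data.frame(pairs, stringsAsFactors = FALSE)),
            class = "bipolar_session")
}

#' @export
print.bipolar_session <- function(x, ...) {
  cat("<bipolar_session> ", nrow(x$samples), " bipolar channels x ",
      ncol(x$samples), " samples @ ", x$fs, " Hz\n", sep = "")
  lab <- paste0(x$pairs$lead, ":", x$pairs$contact_a, "-", x$pairs$contact_b,
                " (", x$pairs$region, ")")
  cat(" ", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

# internal: apply a function channel-wise, preserving the container
map_channels <- function(session, f) {
  out <- t(apply(session$samples, 1L, f))
  if (ncol(session$samples) == 1L) out <- t(out)
  session$samples <- out
  session
}
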