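## ---------------------------------------------------------------------------
## Plain-text signal exchange format: one delimited file per recording
## (one column per channel, header row) plus a JSON sidecar carrying the
## sampling rate, channel metadata and the session layout.
## ---------------------------------------------------------------------------

#' Write a recording as delimited text plus a JSON sidecar
#'
#' @param rec an [optical_recording()] or [eeg_recording()].
#' @param path output path for the data file (tab-separated, header row);
#'   the sidecar is written next to it as `<path>.json`.
#' @param layout optional [session_layout()] stored in the sidecar.
#' @param seed optional integer recorded in the sidecar for provenance.
#' @return invisibly, the sidecar list.
#' @export
write_recording <- function(rec, path, layout = NULL, seed = NULL) {
  df <- as.data.frame(t(rec$samples))
  names(df) <- if (inherits(rec, "optical_recording"))
    sprintf("pair%02d_%dnm", rec$pair, rec$wavelengths) else rec$channel_names
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(
    kind = class(rec)[1], rate = rec$rate, t0 = rec$t0,
    n_samples = ncol(rec$samples), channels = names(df), seed = seed
  )
  if (inherits(rec, "optical_recording")) {
    side$wavelengths <- rec$wavelengths
    side$pair <- rec$pair
    side$distance_mm <- rec$distance_mm
  }
  if (!is.null(layout))
    side$layout <- as.data.frame(layout)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(side)
}

#' Read a recording written by [write_recording()]
#'
#' @param path path to the data file; the sidecar `<path>.json` must
#'   exist.
#' @return an [optical_recording()] or [eeg_recording()]; any layout in
#'   the sidecar is attached as attribute `layout`.
#' @export
read_recording <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- t(as.matrix(utils::read.table(path, sep = "\t", header = TRUE)))
  rec <- if (identical(side$kind, "optical_recording")) {
    optical_recording(mat, rate = side$rate, wavelengths = side$wavelengths,
                      pair = side$pair, distance_mm = side$distance_mm,
                      t0 = side$t0)
  } else {
    eeg_recording(mat, rate = side$rate, channel_names = side$channels,
                  t0 = side$t0)
  }
  if (!is.null(side$layout)) {
    lay <- side$layout
    class(lay) <- c("session_layout", "data.frame")
    attr(rec, "layout") <- lay
  }
  rec
}
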