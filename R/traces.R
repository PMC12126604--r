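#' Build a MANT-ATP acquisition time grid
#'
#' Images are taken frequently during the initial rapid phase of the chase and
#' more sparsely afterwards. The default protocol acquires every 5 s for the
#' first 90 s and every 10 s thereafter up to 390 s.
#'
#' @param step_early frame interval (s) for the early phase.
#' @param early_end end of the early phase (s).
#' @param step_late frame interval (s) for the late phase.
#' @param total_end end of acquisition (s); must exceed `early_end`.
#' @return Numeric vector of acquisition times starting at 0, strictly
#'   increasing, with no duplicate at the phase junction.
#' @examples
#' length(mant_timegrid()) # 49 frames
#' @export
mant_timegrid <- function(step_early = 5, early_end = 90,
                          step_late = 10, total_end = 390) {
  if (!(step_early > 0 && step_early <= early_end))
    stop_invalid("invalid parameters: need 0 < step_early <= early_end")
  if (step_late <= 0)
    stop_invalid("invalid parameters: step_late must be positive")
  if (total_end <= early_end)
    stop_invalid("invalid parameters: total_end must exceed early_end")
  early <- seq(0, early_end, by = step_early)
  late <- seq(early_end + step_late, total_end, by = step_late)
  c(early, late)
}

#' Construct a normalised fluorescence decay trace
#'
#' Background-subtracts each frame, averages the three sampled regions of the
#' fibre, and normalises to the first (time 0) frame so the trace starts at 1.
#'
#' @param roi_means matrix or data.frame with one row per frame and three
#'   columns of mean ROI intensities (arbitrary fluorescence units).
#' @param background numeric vector of per-frame background intensity.
#' @param times numeric vector of acquisition times (s), starting at 0 and
#'   strictly increasing.
#' @param fibre_id identifier for the fibre.
#' @return A `decay_trace` object: list with `fibre_id`, `times`,
#'   `normalised` (unitless, `normalised[1] == 1`), and the raw inputs.
#' @export
normalise_trace <- function(roi_means, background, times, fibre_id = "fibre") {
  roi_means <- as.matrix(roi_means)
  if (ncol(roi_means) != 3L)
    stop_invalid("shape error: expected 3 ROI columns, got %d", ncol(roi_means))
  n <- nrow(roi_means)
  if (length(background) != n || length(times) != n)
    stop_invalid("shape error: roi_means (%d frames), background (%d), times (%d) must agree",
                 n, length(background), length(times))
  check_times(times)
  signal <- rowMeans(roi_means) - background
  if (!is.finite(signal[1]) || signal[1] <= 0)
    stop_invalid("degenerate trace: background-subtracted signal at time 0 is not positive")
  new_decay_trace(fibre_id, times, signal / signal[1],
                  roi_means = roi_means, background = background)
}

#' Create a decay trace from already-normalised values
#'
#' @param times acquisition times (s), starting at 0, strictly increasing.
#' @param normalised unitless fluorescence, `normalised[1]` must be 1.
#' @param fibre_id identifier.
#' @return A `decay_trace` object.
#' @export
decay_trace <- function(times, normalised, fibre_id = "fibre") {
  check_times(times)
  if (length(normalised) != length(times))
    stop_invalid("shape error: times and normalised differ in length")
  if (abs(normalised[1] - 1) > 1e-12)
    stop_invalid("degenerate trace: normalised[1] must equal 1")
  new_decay_trace(fibre_id, times, normalised)
}

new_decay_trace <- function(fibre_id, times, normalised,
                            roi_means = NULL, background = NULL) {
  structure(list(fibre_id = as.character(fibre_id),
                 times = as.numeric(times),
                 normalised = as.numeric(normalised),
                 roi_means = roi_means, background = background),
            class = "decay_trace")
}

check_times <- function(times) {
  if (length(times) < 2L || any(!is.finite(times)))
    stop_invalid("times must be finite with at least 2 frames")
  if (abs(times[1]) > 1e-12)
    stop_invalid("times must start at 0")
  if (any(diff(times) <= 0))
    stop_invalid("times must be strictly increasing")
  invisible(times)
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("<decay_trace> fibre '%s': %d frames over %.0f s, final level %.3f\n",
              x$fibre_id, length(x$times), max(x$times),
              x$normalised[length(x$normalised)]))
  invisible(x)
}

#' Read per-frame ROI intensity traces from CSV
#'
#' Expects columns `fibre_id, time_s, roi1, roi2, roi3, background`, one row
#' per frame, and returns one normalised [decay_trace] per fibre.
#'
#' @param path path to the CSV file.
#' @return Named list of `decay_trace` objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fibre_id", "time_s", "roi1", "roi2", "roi3", "background")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("trace CSV missing columns: %s", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$fibre_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    normalise_trace(d[, c("roi1", "roi2", "roi3")], d$background, d$time_s,
                    fibre_id = d$fibre_id[1])
  })
  out[order(names(out))]
}

#' Write a list of decay traces to CSV
#'
#' Inverse of [read_traces()]; only traces carrying raw ROI/background frames
#' can be written.
#'
#' @param traces list of `decay_trace` objects with raw ROI data.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    if (is.null(tr$roi_means))
      stop_invalid("trace '%s' has no raw ROI frames to write", tr$fibre_id)
    data.frame(fibre_id = tr$fibre_id, time_s = tr$times,
               roi1 = tr$roi_means[, 1], roi2 = tr$roi_means[, 2],
               roi3 = tr$roi_means[, 3], background = tr$background)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
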