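#' Band-pass filter specification
#'
#' The 4–38 Hz band covers the mu (8–12 Hz) and beta (16–31 Hz) rhythms
#' that carry the motor-imagery signal. The filter is a Butterworth
#' band-pass of the given order, applied forward–backward (zero phase) by
#' default so ERD latencies are not shifted.
#'
#' @param low_cut,high_cut Band edges in Hz.
#' @param order Butterworth prototype order.
#' @param zero_phase Apply forward–backward (`signal::filtfilt`)? If
#'   `FALSE`, a single causal pass is used.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 4, high_cut = 38, order = 4,
                        zero_phase = TRUE) {
  if (low_cut <= 0 || low_cut >= high_cut)
    stop("need 0 < low_cut < high_cut", call. = FALSE)
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Band-pass filter a multi-channel signal
#'
#' @param x Channels x samples numeric matrix (or a vector, treated as one
#'   channel).
#' @param sampling_rate Sampling frequency in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, sampling_rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, nrow = 1)
  nyq <- sampling_rate / 2
  if (spec$high_cut >= nyq)
    stop("`high_cut` must be below the Nyquist frequency", call. = FALSE)
  if (ncol(x) <= 3 * spec$order)
    stop("signal too short for stable filtering", call. = FALSE)
  bf <- signal::butter(spec$order,
                       c(spec$low_cut, spec$high_cut) / nyq,
                       type = "pass")
  out <- x
  for (ch in seq_len(nrow(x))) {
    out[ch, ] <- if (spec$zero_phase)
      as.numeric(signal::filtfilt(bf, x[ch, ]))
    else
      as.numeric(signal::filter(bf, x[ch, ]))
  }
  if (vec_in) out <- drop(out)
  out
}

#' Extract the post-cue analysis epoch from a trial
#'
#' Takes the half-open sample range
#' `[cue_index + round(w1 * fs), cue_index + round(w2 * fs))` (0-based),
#' i.e. exactly `round((w2 - w1) * fs)` samples; with the default 0.5–2.5 s
#' window at 250 Hz this is the 500-sample segment used by all
#' classifiers.
#'
#' @param trial A `labeled_trial`.
#' @param window Numeric pair `(start, end)` in seconds after the cue.
#' @return Channels x samples matrix (3 x 500 with defaults).
#' @export
extract_epoch <- function(trial, window = c(0.5, 2.5)) {
  stopifnot(inherits(trial, "labeled_trial"))
  if (length(window) != 2 || window[1] >= window[2])
    stop("`window` must be (start, end) with start < end", call. = FALSE)
  fs <- trial$sampling_rate
  a <- trial$cue_index + round(window[1] * fs)   # 0-based inclusive
  b <- trial$cue_index + round(window[2] * fs)   # 0-based exclusive
  if (a < 0 || b > ncol(trial$data))
    stop(sprintf("epoch window [%g, %g] s exceeds trial bounds (label %s)",
                 window[1], window[2], trial$label), call. = FALSE)
  trial$data[, (a + 1L):b, drop = FALSE]
}

#' Build a filtered, epoched data set from raw trials
#'
#' Each full trial is band-pass filtered first and epoched afterwards, so
#' filter edge transients fall outside the 2 s analysis window. Labels are
#' carried through in trial order.
#'
#' @param trialset A `trial_set`.
#' @param spec A [filter_spec()].
#' @param window Epoch window in seconds after the cue.
#' @return An `epoch_set`: list with `data` (trials x channels x samples
#'   array), `labels` (integer codes, 0 = left / 1 = right),
#'   `sampling_rate` and `window`.
#' @export
build_epochset <- function(trialset, spec = filter_spec(),
                           window = c(0.5, 2.5)) {
  stopifnot(inherits(trialset, "trial_set"))
  n <- length(trialset$trials)
  if (n == 0) stop("empty trial set", call. = FALSE)
  fs <- trialset$trials[[1]]$sampling_rate
  len <- round((window[2] - window[1]) * fs)
  data <- array(0, dim = c(n, nrow(trialset$trials[[1]]$data), len))
  labels <- integer(n)
  for (i in seq_len(n)) {
    tr <- trialset$trials[[i]]
    filt <- tr
    filt$data <- tryCatch(
      bandpass_filter(tr$data, fs, spec),
      error = function(e) stop(sprintf("trial %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    data[i, , ] <- extract_epoch(filt, window)
    labels[i] <- label_codes(tr$label)
  }
  structure(list(data = data, labels = labels, sampling_rate = fs,
                 window = as.numeric(window)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples, %g Hz, window %g-%g s\n",
              d[1], d[2], d[3], x$sampling_rate, x$window[1], x$window[2]))
  invisible(x)
}

#' Write / read an epoch archive
#'
#' Single-file archive with the epoch stack, label codes, sampling rate
#' and window, using R native serialization.
#'
#' @param x An `epoch_set`.
#' @param path File path.
#' @export
write_epochset <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  saveRDS(list(schema = "micaps-epochs-v1", epochs = x$data,
               labels = x$labels, sampling_rate = x$sampling_rate,
               window = x$window), path)
  invisible(path)
}

#' @rdname write_epochset
#' @export
read_epochset <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "micaps-epochs-v1"))
    stop("not a micaps epoch archive", call. = FALSE)
  structure(list(data = obj$epochs, labels = obj$labels,
                 sampling_rate = obj$sampling_rate, window = obj$window),
            class = "epoch_set")
}

#' Ingest recordings through a pluggable reader
#'
#' Hook for real recordings (e.g. cue-annotated GDF files in the
#' three-electrode, 250 Hz layout): `reader` is any function that maps a
#' file path to a `trial_set` with channels ordered C3, Cz, C4. The
#' returned set is validated and passed through unchanged.
#'
#' @param path Recording file path.
#' @param reader Function `path -> trial_set`.
#' @return A validated `trial_set`.
#' @export
ingest_recording <- function(path, reader) {
  ts <- reader(path)
  if (!inherits(ts, "trial_set"))
    stop("reader must return a trial_set", call. = FALSE)
  fs <- unique(vapply(ts$trials, `[[`, numeric(1), "sampling_rate"))
  if (length(fs) != 1)
    stop("all trials must share one sampling rate", call. = FALSE)
  for (tr in ts$trials) {
    if (nrow(tr$data) != 3)
      stop("trials must have exactly 3 channels (C3, Cz, C4)", call. = FALSE)
    if (!is.null(rownames(tr$data)) &&
        !identical(rownames(tr$data), c("C3", "Cz", "C4")))
      stop("channel order must be C3, Cz, C4; reorder at the source",
           call. = FALSE)
  }
  ts
}
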