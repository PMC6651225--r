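#' Configuration for the synthetic motor-imagery trial generator
#'
#' Describes a simulated cue-based motor-imagery recording on the three
#' sensorimotor electrodes C3, Cz, C4. Each trial is Gaussian background
#' noise plus mu (~10 Hz) and beta (~22 Hz) oscillations on every channel.
#' During the imagery window the oscillation amplitude on the channel
#' contralateral to the imagined hand (left hand -> C4, right hand -> C3)
#' is attenuated by the factor `1 - erd_depth` — the event-related
#' desynchronization (ERD) that carries the class information. Cz is never
#' attenuated.
#'
#' @param sampling_rate Sampling frequency in Hz.
#' @param trial_duration Trial length in seconds.
#' @param cue_time Cue onset in seconds from trial start.
#' @param mu_freq,beta_freq Oscillation frequencies in Hz.
#' @param mu_amp,beta_amp Oscillation amplitudes (arbitrary units).
#' @param noise_sd Standard deviation of the white Gaussian background.
#' @param erd_depth Attenuation fraction d in \[0, 1\]: the contralateral
#'   oscillation amplitude inside the ERD window is `(1 - d)` times its
#'   baseline amplitude. `0` disables the effect (null data), `1` removes
#'   the oscillation entirely.
#' @param erd_window Numeric pair `(start, end)` in seconds relative to the
#'   cue during which the attenuation is applied. The default 0.3–2.8 s
#'   fully covers the 0.5–2.5 s analysis epoch.
#' @param seed Optional integer seed used by [synthesize_trial()] when no
#'   explicit seed is passed.
#'
#' @return An object of class `synth_config`.
#' @seealso [synthesize_trial()], [synthesize_dataset()]
#' @export
#' @examples
#' cfg <- synth_config(erd_depth = 0.8, noise_sd = 0.3)
#' trial <- synthesize_trial(cfg, "left", seed = 1)
#' dim(trial$data)
synth_config <- function(sampling_rate = 250,
                         trial_duration = 8,
                         cue_time = 3,
                         mu_freq = 10,
                         beta_freq = 22,
                         mu_amp = 1,
                         beta_amp = 1,
                         noise_sd = 0.5,
                         erd_depth = 0.8,
                         erd_window = c(0.3, 2.8),
                         seed = NULL) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be positive", call. = FALSE)
  if (!is.numeric(erd_depth) || erd_depth < 0 || erd_depth > 1)
    stop("`erd_depth` must lie in [0, 1]", call. = FALSE)
  if (length(erd_window) != 2 || erd_window[1] >= erd_window[2])
    stop("`erd_window` must be (start, end) with start < end", call. = FALSE)
  if (cue_time + erd_window[2] > trial_duration)
    stop("`cue_time` + `erd_window` end must not exceed `trial_duration`",
         call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(
    list(sampling_rate = sampling_rate, n_channels = 3L,
         channel_names = c("C3", "Cz", "C4"),
         trial_duration = trial_duration, cue_time = cue_time,
         mu_freq = mu_freq, beta_freq = beta_freq,
         mu_amp = mu_amp, beta_amp = beta_amp,
         noise_sd = noise_sd, erd_depth = erd_depth,
         erd_window = as.numeric(erd_window), seed = seed),
    class = "synth_config")
}

#' Generate one labeled synthetic motor-imagery trial
#'
#' Draws the oscillation phases and the noise from the current RNG state
#' (or from `seed` when given) and evaluates the signal model
#' `x_c(t) = noise(t) + mu_amp * g_c(t) * sin(2*pi*mu_freq*t + phi)
#'         + beta_amp * g_c(t) * sin(2*pi*beta_freq*t + psi)`,
#' where the gain `g_c(t)` equals `1 - erd_depth` on the contralateral
#' channel inside the ERD window and 1 everywhere else. Phases `phi`,
#' `psi` are drawn once per trial and shared across channels.
#'
#' @param cfg A [synth_config()].
#' @param label `"left"` or `"right"` (the imagined hand).
#' @param seed Optional integer seed; defaults to `cfg$seed`. When `NULL`,
#'   the current RNG state is used.
#' @return A `labeled_trial`: list with `data` (3 x n_samples matrix, rows
#'   C3, Cz, C4), `label`, `cue_index` (0-based sample offset of the cue),
#'   and `sampling_rate`.
#' @export
synthesize_trial <- function(cfg, label, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(label) != 1 || !label %in% c("left", "right"))
    stop("`label` must be \"left\" or \"right\"", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  fs <- cfg$sampling_rate
  n <- round(cfg$trial_duration * fs)
  t <- (seq_len(n) - 1) / fs

  ## draw order is label-independent so that matched seeds give matched
  ## noise/phases across labels
  phi <- stats::runif(1, 0, 2 * pi)
  psi <- stats::runif(1, 0, 2 * pi)
  noise <- matrix(stats::rnorm(3L * n, sd = cfg$noise_sd), nrow = 3L)

  mu <- sin(2 * pi * cfg$mu_freq * t + phi)
  beta <- sin(2 * pi * cfg$beta_freq * t + psi)
  osc <- cfg$mu_amp * mu + cfg$beta_amp * beta

  ## attenuation gain on the contralateral channel
  w0 <- cfg$cue_time + cfg$erd_window[1]
  w1 <- cfg$cue_time + cfg$erd_window[2]
  in_win <- t >= w0 & t < w1
  gain <- rep(1, n)
  gain[in_win] <- 1 - cfg$erd_depth

  contra <- if (label == "left") 3L else 1L  # left hand -> C4, right -> C3
  data <- noise
  for (ch in 1:3) {
    g <- if (ch == contra) gain else 1
    data[ch, ] <- data[ch, ] + g * osc
  }
  rownames(data) <- cfg$channel_names

  structure(
    list(data = data, label = label,
         cue_index = as.integer(round(cfg$cue_time * fs)),
         sampling_rate = fs),
    class = "labeled_trial")
}

#' Generate a balanced labeled trial set
#'
#' Produces `2 * n_per_class` trials (alternating left/right) with
#' per-trial sub-seeds derived deterministically from `seed`, so the whole
#' set is reproducible while trials stay mutually independent.
#'
#' @param cfg A [synth_config()].
#' @param n_per_class Number of trials per class (>= 1).
#' @param seed Integer seed for the whole set.
#' @return A `trial_set`: list with `trials` (list of `labeled_trial`) and
#'   `metadata` (the generating config).
#' @export
synthesize_dataset <- function(cfg, n_per_class, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop("`n_per_class` must be >= 1", call. = FALSE)
  n_per_class <- as.integer(n_per_class)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_class)
  labels <- rep(c("left", "right"), n_per_class)
  trials <- vector("list", 2L * n_per_class)
  for (i in seq_along(trials))
    trials[[i]] <- synthesize_trial(cfg, labels[i], seed = sub_seeds[i])
  structure(list(trials = trials, metadata = cfg), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  labs <- vapply(x$trials, `[[`, character(1), "label")
  cat(sprintf("<trial_set> %d trials (%d left / %d right), %g Hz, %d channels\n",
              length(x$trials), sum(labs == "left"), sum(labs == "right"),
              x$trials[[1]]$sampling_rate, nrow(x$trials[[1]]$data)))
  invisible(x)
}

#' Integrated band power of one channel over a time window
#'
#' Computes the periodogram of the (rectangular-windowed) channel segment
#' and sums the one-sided ordinates whose frequencies fall inside `band`
#' (inclusive). With this scaling the value is the band's contribution to
#' the signal's mean square, so a unit-amplitude in-band sinusoid gives
#' approximately 0.5. Used as the spectral oracle throughout the package's
#' simulation checks.
#'
#' @param trial A `labeled_trial`.
#' @param channel Channel index 1..3 (C3, Cz, C4) or channel name.
#' @param band Numeric pair `(low, high)` in Hz, inside (0, fs/2).
#' @param window Numeric pair `(start, end)` in seconds from trial start.
#' @return Band power (amplitude squared units).
#' @export
band_power <- function(trial, channel, band, window) {
  stopifnot(inherits(trial, "labeled_trial"))
  fs <- trial$sampling_rate
  if (is.character(channel))
    channel <- match(channel, rownames(trial$data))
  if (is.na(channel) || channel < 1 || channel > nrow(trial$data))
    stop("unknown channel", call. = FALSE)
  if (length(band) != 2 || band[1] >= band[2] ||
      band[1] <= 0 || band[2] >= fs / 2)
    stop("`band` must be (low, high) inside (0, fs/2)", call. = FALSE)
  if (length(window) != 2 || window[1] >= window[2])
    stop("`window` must be (start, end) seconds with start < end", call. = FALSE)
  i0 <- round(window[1] * fs) + 1L
  i1 <- round(window[2] * fs)
  if (i0 < 1 || i1 > ncol(trial$data))
    stop("`window` exceeds trial bounds", call. = FALSE)
  x <- trial$data[channel, i0:i1]
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2            # two-sided, sums to mean square
  k <- 0:(n %/% 2)                           # one-sided bin indices
  freq <- k * fs / n
  ord <- p[k + 1L]
  dbl <- k > 0 & (2 * k != n)                # double all but DC / Nyquist
  ord[dbl] <- 2 * ord[dbl]
  sum(ord[freq >= band[1] & freq <= band[2]])
}

## labels as integer codes used in archives and training: 0 = left, 1 = right
label_codes <- function(labels) {
  code <- match(labels, c("left", "right")) - 1L
  if (anyNA(code)) stop("labels must be \"left\"/\"right\"", call. = FALSE)
  code
}

#' Write / read a trial archive
#'
#' Serializes a `trial_set` to a single archive file holding the stacked
#' trial data (trials x channels x samples), integer label codes
#' (0 = left, 1 = right), per-trial cue indices, and the sampling rate and
#' channel names, using R native serialization.
#'
#' @param x A `trial_set`.
#' @param path Output file path.
#' @return `write_trialset` returns `path` invisibly; `read_trialset`
#'   returns a `trial_set`.
#' @export
write_trialset <- function(x, path) {
  stopifnot(inherits(x, "trial_set"))
  n <- length(x$trials)
  ns <- ncol(x$trials[[1]]$data)
  data <- array(0, dim = c(n, 3L, ns))
  for (i in seq_len(n)) data[i, , ] <- x$trials[[i]]$data
  obj <- list(
    schema = "micaps-trials-v1",
    data = data,
    labels = label_codes(vapply(x$trials, `[[`, character(1), "label")),
    cue_index = vapply(x$trials, `[[`, integer(1), "cue_index"),
    sampling_rate = x$trials[[1]]$sampling_rate,
    channel_names = c("C3", "Cz", "C4"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "micaps-trials-v1"))
    stop("not a micaps trial archive", call. = FALSE)
  if (!identical(obj$channel_names, c("C3", "Cz", "C4")))
    stop("archive channel order must be C3, Cz, C4", call. = FALSE)
  n <- dim(obj$data)[1]
  trials <- vector("list", n)
  labs <- c("left", "right")[obj$labels + 1L]
  for (i in seq_len(n)) {
    d <- obj$data[i, , ]
    rownames(d) <- obj$channel_names
    trials[[i]] <- structure(
      list(data = d, label = labs[i], cue_index = obj$cue_index[i],
           sampling_rate = obj$sampling_rate),
      class = "labeled_trial")
  }
  structure(list(trials = trials, metadata = list(source = path)),
            class = "trial_set")
}
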