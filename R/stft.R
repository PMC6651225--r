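#' Short-time Fourier transform configuration
#'
#' With the defaults (window 128, overlap 100, hence hop 28) a 500-sample
#' epoch yields `floor((500 - 128) / 28) + 1 = 14` frames and 65 one-sided
#' frequency bins per channel — the 3 x 65 x 14 magnitude array from which
#' the network's 14 x 14 images are cropped. Frames start at sample
#' offsets 0, hop, 2*hop, ...; no boundary padding is applied and a
#' trailing partial frame is dropped.
#'
#' @param window_len Analysis window length in samples.
#' @param overlap Overlap between consecutive windows in samples.
#' @param fft_len DFT length (defaults to `window_len`).
#' @param window_fn Taper: `"hann"` (periodic) or `"rect"`.
#' @return Object of class `stft_config`.
#' @export
stft_config <- function(window_len = 128, overlap = 100,
                        fft_len = window_len, window_fn = c("hann", "rect")) {
  window_fn <- match.arg(window_fn)
  if (overlap < 0 || overlap >= window_len)
    stop("need 0 <= overlap < window_len", call. = FALSE)
  if (fft_len < window_len)
    stop("`fft_len` must be >= `window_len`", call. = FALSE)
  structure(list(window_len = as.integer(window_len),
                 overlap = as.integer(overlap),
                 hop = as.integer(window_len - overlap),
                 fft_len = as.integer(fft_len),
                 window_fn = window_fn),
            class = "stft_config")
}

stft_taper <- function(cfg) {
  n <- cfg$window_len
  switch(cfg$window_fn,
         hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n),  # periodic Hann
         rect = rep(1, n))
}

#' Magnitude spectrogram of a multi-channel epoch
#'
#' @param epoch Channels x samples matrix (3 x 500 with package defaults).
#' @param fs Sampling frequency in Hz.
#' @param cfg An [stft_config()].
#' @return A `spectrogram` object: list with `values` (channels x
#'   freq_bins x frames non-negative magnitudes), `freq_axis` (Hz per
#'   bin, spacing `fs / fft_len`) and `time_axis` (seconds at frame
#'   centers).
#' @export
compute_stft <- function(epoch, fs, cfg = stft_config()) {
  stopifnot(inherits(cfg, "stft_config"))
  if (is.null(dim(epoch))) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  if (n < cfg$window_len)
    stop("epoch shorter than the analysis window", call. = FALSE)
  n_frames <- (n - cfg$window_len) %/% cfg$hop + 1L
  n_bins <- cfg$fft_len %/% 2L + 1L
  taper <- stft_taper(cfg)
  starts <- (seq_len(n_frames) - 1L) * cfg$hop          # 0-based
  vals <- array(0, dim = c(nrow(epoch), n_bins, n_frames))
  for (ch in seq_len(nrow(epoch))) {
    frames <- matrix(0, cfg$fft_len, n_frames)
    for (f in seq_len(n_frames))
      frames[seq_len(cfg$window_len), f] <-
        epoch[ch, (starts[f] + 1L):(starts[f] + cfg$window_len)] * taper
    vals[ch, , ] <- Mod(stats::mvfft(frames))[seq_len(n_bins), , drop = FALSE]
  }
  structure(list(values = vals,
                 freq_axis = (seq_len(n_bins) - 1L) * fs / cfg$fft_len,
                 time_axis = (starts + (cfg$window_len - 1) / 2) / fs,
                 config = cfg),
            class = "spectrogram")
}

#' Crop a spectrogram to the mu + beta band
#'
#' Keeps a contiguous block of frequency rows (low to high). The default
#' rows 5..18 (1-based; bin frequencies `(k-1) * fs / 128` for k in 5..18,
#' i.e. about 7.81–33.20 Hz at 250 Hz) are the 14 bins covering the mu
#' (8–12 Hz) and beta (16–31 Hz) rhythms, turning a 3 x 65 x 14 array into
#' the 3 x 14 x 14 network input.
#'
#' @param spec A `spectrogram` from [compute_stft()].
#' @param bins Integer vector of contiguous ascending 1-based row indices.
#' @return List with `values` (channels x length(bins) x frames), `band`
#'   (Hz range actually selected) and the cropped `freq_axis`.
#' @export
select_mu_beta <- function(spec, bins = 5:18) {
  stopifnot(inherits(spec, "spectrogram"))
  n_bins <- dim(spec$values)[2]
  if (any(bins < 1) || any(bins > n_bins))
    stop("`bins` outside the spectrogram's frequency rows", call. = FALSE)
  if (!identical(as.integer(bins), seq.int(bins[1], bins[length(bins)])))
    stop("`bins` must be contiguous and ascending", call. = FALSE)
  n_frames <- dim(spec$values)[3]
  if (length(bins) != n_frames)
    stop(sprintf("band must select %d rows to form a square image, got %d",
                 n_frames, length(bins)), call. = FALSE)
  list(values = spec$values[, bins, , drop = FALSE],
       band = range(spec$freq_axis[bins]),
       freq_axis = spec$freq_axis[bins])
}

#' Min–max normalize a cropped spectrogram into a network image
#'
#' Scales the whole 3-channel tensor jointly to \[0, 1\]; a constant
#' tensor maps to all zeros. The \[0, 1\] range matches the logistic
#' output of the reconstruction decoder.
#'
#' @param cropped Output of [select_mu_beta()] (or a bare numeric array).
#' @return An `mi_image`: array of dim 3 x 14 x 14 in \[0, 1\] with a
#'   `band` attribute.
#' @export
normalize_image <- function(cropped) {
  band <- NULL
  vals <- cropped
  if (is.list(cropped)) {
    vals <- cropped$values
    band <- cropped$band
  }
  if (!all(is.finite(vals)))
    stop("non-finite values in image input", call. = FALSE)
  rng <- range(vals)
  out <- if (rng[2] > rng[1]) (vals - rng[1]) / (rng[2] - rng[1])
         else array(0, dim = dim(vals))
  structure(out, band = band, class = "mi_image")
}

#' Convert an epoch set to a stack of time–frequency images
#'
#' Runs [compute_stft()], [select_mu_beta()] and [normalize_image()] over
#' every epoch.
#'
#' @param epochset An `epoch_set`.
#' @param cfg An [stft_config()].
#' @param bins Frequency rows passed to [select_mu_beta()].
#' @return An `image_set`: list with `data` (trials x channels x freq x
#'   time array in \[0, 1\]), `labels`, `band`, and the STFT settings.
#' @export
epochs_to_images <- function(epochset, cfg = stft_config(), bins = 5:18) {
  stopifnot(inherits(epochset, "epoch_set"))
  n <- dim(epochset$data)[1]
  first <- normalize_image(select_mu_beta(
    compute_stft(epochset$data[1, , ], epochset$sampling_rate, cfg), bins))
  data <- array(0, dim = c(n, dim(first)))
  data[1, , , ] <- first
  if (n > 1) for (i in 2:n) {
    data[i, , , ] <- normalize_image(select_mu_beta(
      compute_stft(epochset$data[i, , ], epochset$sampling_rate, cfg), bins))
  }
  structure(list(data = data, labels = epochset$labels,
                 band = attr(first, "band"), stft = cfg, bins = bins),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_set> %d images of %d x %d x %d, band %.2f-%.2f Hz\n",
              d[1], d[2], d[3], d[4], x$band[1], x$band[2]))
  invisible(x)
}

#' Write / read an image archive
#'
#' @param x An `image_set`.
#' @param path File path.
#' @export
write_imageset <- function(x, path) {
  stopifnot(inherits(x, "image_set"))
  saveRDS(list(schema = "micaps-images-v1", images = x$data,
               labels = x$labels, band = x$band,
               stft = unclass(x$stft), bins = x$bins), path)
  invisible(path)
}

#' @rdname write_imageset
#' @export
read_imageset <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "micaps-images-v1"))
    stop("not a micaps image archive", call. = FALSE)
  structure(list(data = obj$images, labels = obj$labels, band = obj$band,
                 stft = structure(obj$stft, class = "stft_config"),
                 bins = obj$bins),
            class = "image_set")
}

## internal: image set -> (pixels x n) matrix in the conv layout
## per-image layout is (freq, time, channel) column-major
imageset_matrix <- function(x) {
  d <- dim(x$data)                       # n x C x H x W
  n <- d[1]
  out <- matrix(0, d[2] * d[3] * d[4], n)
  for (i in seq_len(n))
    out[, i] <- as.vector(aperm(array(x$data[i, , , ], d[2:4]), c(2, 3, 1)))
  out
}
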