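#' Analysis frame specification
#'
#' @param frame_ms frame length in milliseconds (default 30).
#' @param hop_ms hop between frames in milliseconds (default 10).
#' @param window `"hamming"` or `"hann"`.
#' @return list of class `cogscreen_framespec`.
#' @export
frame_spec <- function(frame_ms = 30, hop_ms = 10, window = c("hamming", "hann")) {
  window <- match.arg(window)
  if (hop_ms <= 0 || hop_ms > frame_ms) abort_domain("need 0 < hop_ms <= frame_ms")
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms, window = window),
            class = "cogscreen_framespec")
}

window_vector <- function(n, type) {
  k <- seq_len(n) - 1
  switch(type,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)))
}

# frame a signal into a (frame_len x n_frames) matrix
frame_signal <- function(x, rate, spec, windowed = TRUE) {
  flen <- round(spec$frame_ms / 1000 * rate)
  hop <- round(spec$hop_ms / 1000 * rate)
  if (flen > length(x)) abort_domain("frame longer than clip")
  n_frames <- floor((length(x) - flen) / hop) + 1
  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1) * hop, `+`)
  frames <- matrix(x[idx], nrow = flen)
  if (windowed) frames <- frames * window_vector(flen, spec$window)
  frames
}

#' Silence removal by energy thresholding
#'
#' Keeps frames whose short-time energy is within `threshold_db` of the
#' clip's peak frame energy, merges them into contiguous speech segments,
#' drops segments shorter than `min_segment_ms`, and concatenates the rest.
#' An entirely silent clip yields an empty, flagged clip.
#'
#' @param clip an [audio_clip()].
#' @param threshold_db dB below peak frame energy that still counts as
#'   speech (default 40).
#' @param min_segment_ms minimum kept segment length (default 100).
#' @param spec a [frame_spec()].
#' @return an [audio_clip()]; attribute `silent` is `TRUE` when nothing
#'   survived.
#' @export
remove_silence <- function(clip, threshold_db = 40, min_segment_ms = 100,
                           spec = frame_spec()) {
  x <- clip$samples
  if (!length(x)) abort_domain("clip is empty")
  flen <- round(spec$frame_ms / 1000 * clip$rate_hz)
  hop <- round(spec$hop_ms / 1000 * clip$rate_hz)
  if (length(x) < flen) flen <- length(x)
  starts <- seq(1, max(1, length(x) - flen + 1), by = hop)
  energy <- vapply(starts, function(s) sum(x[s:(s + flen - 1)]^2), numeric(1))
  peak <- max(energy)
  if (peak <= 0) {
    out <- audio_clip(numeric(0), clip$rate_hz)
    attr(out, "silent") <- TRUE
    return(out)
  }
  keep <- 10 * log10(energy / peak) > -threshold_db
  # contiguous runs of kept frames -> sample segments
  r <- rle(keep)
  ends <- cumsum(r$lengths); begins <- ends - r$lengths + 1
  segs <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    s0 <- starts[begins[k]]
    s1 <- min(length(x), starts[ends[k]] + flen - 1)
    if ((s1 - s0 + 1) / clip$rate_hz * 1000 >= min_segment_ms)
      segs[[length(segs) + 1]] <- x[s0:s1]
  }
  if (!length(segs)) {
    out <- audio_clip(numeric(0), clip$rate_hz)
    attr(out, "silent") <- TRUE
    return(out)
  }
  out <- audio_clip(unlist(segs), clip$rate_hz)
  attr(out, "silent") <- FALSE
  out
}

## ---- pitch --------------------------------------------------------------

# sub-sample refinement of a discrete peak by parabolic interpolation
parabolic_offset <- function(vals, i) {
  if (i <= 1 || i >= length(vals)) return(0)
  denom <- vals[i - 1] - 2 * vals[i] + vals[i + 1]
  if (denom == 0) return(0)
  d <- 0.5 * (vals[i - 1] - vals[i + 1]) / denom
  max(-0.5, min(0.5, d))
}

# linear interpolation of a magnitude spectrum at arbitrary frequencies
spec_at <- function(mag, freqs, f) {
  stats::approx(freqs, mag, xout = f, rule = 2, ties = "ordered")$y
}

#' Per-frame fundamental frequency estimation
#'
#' Five classic estimators over the 50-400 Hz search range: normalized
#' correlation function (`ncf`), pitch estimation filter / harmonic comb
#' (`pef`), cepstrum pitch determination (`cep`), log-harmonic summation
#' (`lhs`) and summation of residual harmonics (`srh`, on the LPC residual
#' spectrum). Frames whose periodicity confidence falls below the
#' method's threshold (or whose energy is negligible) are flagged unvoiced
#' and excluded from aggregates.
#'
#' @param clip an [audio_clip()].
#' @param method one of `"ncf"`, `"pef"`, `"cep"`, `"lhs"`, `"srh"`.
#' @param spec a [frame_spec()].
#' @param f_min,f_max search range in Hz.
#' @return tibble with columns `frame`, `t_s`, `f0_hz`, `voiced`,
#'   `confidence`.
#' @export
pitch <- function(clip, method = c("ncf", "pef", "cep", "lhs", "srh"),
                  spec = frame_spec(), f_min = 50, f_max = 400) {
  method <- match.arg(method)
  if (!length(clip$samples)) abort_domain("clip is empty")
  rate <- clip$rate_hz
  frames <- frame_signal(clip$samples, rate, spec, windowed = (method != "ncf"))
  n_frames <- ncol(frames)
  flen <- nrow(frames)
  rms <- sqrt(colMeans(frames^2))
  energy_gate <- rms > max(rms) * 0.05

  lag_min <- max(2L, floor(rate / f_max))
  lag_max <- min(flen - 1L, ceiling(rate / f_min))
  nfft <- 2^ceiling(log2(flen * 8))   # fine grid keeps harmonic sampling unbiased
  freqs <- seq(0, rate / 2, length.out = nfft / 2 + 1)
  cand <- seq(f_min, f_max, by = 0.5)

  # harmonic comb score on a magnitude spectrum, evaluated for all candidates
  comb_score <- function(mag, candidates, harmonics = 1:5, weights = 1 / harmonics) {
    s <- numeric(length(candidates))
    for (j in seq_along(harmonics))
      s <- s + weights[j] * spec_at(mag, freqs, harmonics[j] * candidates)
    s
  }

  f0 <- numeric(n_frames); conf <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    fr <- frames[, k]
    if (method == "ncf") {
      # normalized correlation: FFT autocorrelation with per-lag energy terms
      fz <- c(fr, numeric(flen))
      ac <- Re(stats::fft(Mod(stats::fft(fz))^2, inverse = TRUE))[1:flen] / (2 * flen)
      cs <- cumsum(fr^2)
      if (cs[flen] <= 0) { f0[k] <- NA; conf[k] <- 0; next }
      lags <- lag_min:lag_max
      e1 <- cs[flen - lags]
      e2 <- cs[flen] - cs[lags]
      ncf_vals <- ac[lags + 1] / sqrt(pmax(e1 * e2, 1e-30))
      mx <- max(ncf_vals)
      # octave guard: smallest local maximum within 1% of the global peak
      nlen <- length(ncf_vals)
      is_peak <- c(FALSE, ncf_vals[2:(nlen - 1)] > ncf_vals[1:(nlen - 2)] &
                     ncf_vals[2:(nlen - 1)] >= ncf_vals[3:nlen], FALSE)
      peak_idx <- which(is_peak & ncf_vals >= 0.99 * mx)
      i <- if (length(peak_idx)) peak_idx[1] else which.max(ncf_vals)
      f0[k] <- rate / (lags[i] + parabolic_offset(ncf_vals, i))
      conf[k] <- ncf_vals[i]
    } else {
      mag <- Mod(stats::fft(c(fr, numeric(nfft - flen))))[1:(nfft / 2 + 1)]
      if (method == "cep") {
        lm <- log(pmax(mag, 1e-3 * max(mag, 1e-30)))
        ceps <- Re(stats::fft(c(lm, rev(lm[-c(1, length(lm))])),
                              inverse = TRUE)) / nfft
        qlo <- max(2L, floor(rate / f_max))
        qhi <- min(length(ceps) - 1L, ceiling(rate / f_min))
        seg <- ceps[(qlo:qhi) + 1]
        i <- which.max(seg)
        coarse <- rate / (qlo + i - 1)
        # refine the cepstral candidate on the spectral comb (the hard floor
        # and harmonic truncation bias the raw quefrency peak by 1-2%)
        local <- cand[abs(cand - coarse) <= 0.1 * coarse]
        if (length(local)) {
          ls <- comb_score(mag, local)
          f0[k] <- local[which.max(ls)]
        } else f0[k] <- coarse
        s <- stats::sd(seg)
        conf[k] <- if (s > 0) (seg[i] - mean(seg)) / s / 6 else 0
      } else {
        if (method == "srh") {
          a <- tryCatch(stats::ar.yw(c(fr), aic = FALSE, order.max = 12,
                                     demean = TRUE),
                        error = function(e) NULL)
          if (!is.null(a) && length(a$ar)) {
            res <- stats::filter(c(fr), c(1, -a$ar), method = "convolution", sides = 1)
            res[is.na(res)] <- 0
            mag <- Mod(stats::fft(c(as.numeric(res),
                                    numeric(nfft - flen))))[1:(nfft / 2 + 1)]
          }
        }
        score <- switch(method,
          pef = comb_score(mag, cand),
          lhs = {
            floor_m <- 1e-3 * max(mag, 1e-30)
            s <- numeric(length(cand))
            for (h in 1:3) s <- s + log(spec_at(mag, freqs, h * cand) + floor_m)
            s
          },
          srh = {
            s <- spec_at(mag, freqs, cand)
            for (h in 2:5)
              s <- s + spec_at(mag, freqs, h * cand) -
                spec_at(mag, freqs, (h - 0.5) * cand)
            s
          })
        i <- which.max(score)
        f0[k] <- cand[i]
        s <- stats::sd(score)
        conf[k] <- if (s > 0) (score[i] - mean(score)) / s / 6 else 0
      }
    }
  }
  thr <- switch(method, ncf = 0.45, cep = 0.35, pef = 0.4, lhs = 0.25, srh = 0.4)
  voiced <- energy_gate & is.finite(f0) & conf > thr
  hop <- round(spec$hop_ms / 1000 * rate)
  tibble::tibble(frame = seq_len(n_frames),
                 t_s = ((seq_len(n_frames) - 1) * hop + flen / 2) / rate,
                 f0_hz = f0, voiced = voiced, confidence = pmin(1, pmax(0, conf)))
}

## ---- cepstral coefficients ----------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, nfft, rate, f_min = 0, f_max = rate / 2) {
  mels <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_filters + 2)
  hz <- mel_to_hz(mels)
  freqs <- seq(0, rate / 2, length.out = nfft / 2 + 1)
  fb <- matrix(0, n_filters, length(freqs))
  for (i in seq_len(n_filters)) {
    lo <- hz[i]; cf <- hz[i + 1]; hi <- hz[i + 2]
    up <- (freqs - lo) / (cf - lo)
    down <- (hi - freqs) / (hi - cf)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

erb_of <- function(f) 24.7 * (4.37 * f / 1000 + 1)
hz_to_erbscale <- function(f) 21.4 * log10(1 + 0.00437 * f)
erbscale_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

# 4th-order gammatone magnitude responses on the FFT grid, ERB-spaced centers
gammatone_filterbank <- function(n_filters, nfft, rate, f_min = 50, f_max = rate / 2) {
  centers <- erbscale_to_hz(seq(hz_to_erbscale(f_min), hz_to_erbscale(f_max),
                                length.out = n_filters))
  freqs <- seq(0, rate / 2, length.out = nfft / 2 + 1)
  fb <- matrix(0, n_filters, length(freqs))
  for (i in seq_len(n_filters)) {
    b <- 1.019 * erb_of(centers[i])
    fb[i, ] <- (1 + ((freqs - centers[i]) / b)^2)^(-2)  # |H|^2 of order-4 gammatone
  }
  fb
}

# orthonormal DCT-II matrix (n_out x n_in)
dct_matrix <- function(n_out, n_in) {
  m <- outer(0:(n_out - 1), 0:(n_in - 1),
             function(k, n) cos(pi * k * (2 * n + 1) / (2 * n_in)))
  m <- m * sqrt(2 / n_in)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

cepstral_coeffs <- function(clip, n_coeffs, spec, fb_builder, n_filters) {
  frames <- frame_signal(clip$samples, clip$rate_hz, spec)
  flen <- nrow(frames)
  nfft <- 2^ceiling(log2(flen))
  if (nfft < flen) nfft <- nfft * 2
  if (n_coeffs > n_filters) abort_domain("n_coeffs must not exceed the filter count")
  fb <- fb_builder(n_filters, nfft, clip$rate_hz)
  pad <- rbind(frames, matrix(0, nfft - flen, ncol(frames)))
  mag <- Mod(stats::mvfft(pad))[1:(nfft / 2 + 1), , drop = FALSE]
  fbe <- log(fb %*% mag + 1e-12)
  dct_matrix(n_coeffs, n_filters) %*% fbe
}

#' Mel-frequency and gammatone cepstral coefficients
#'
#' Magnitude spectrum, triangular mel (or 4th-order gammatone, ERB-spaced)
#' filter bank, log compression, then an orthonormal DCT-II; coefficient 0
#' is retained. Output is an `n_coeffs x n_frames` matrix.
#'
#' @param clip an [audio_clip()].
#' @param n_coeffs number of cepstral coefficients (default 13).
#' @param spec a [frame_spec()].
#' @param n_filters filter count (26 mel, 32 gammatone).
#' @return numeric matrix `n_coeffs x n_frames`.
#' @export
mfcc <- function(clip, n_coeffs = 13L, spec = frame_spec(), n_filters = 26L) {
  cepstral_coeffs(clip, n_coeffs, spec, mel_filterbank, n_filters)
}

#' @rdname mfcc
#' @export
gtcc <- function(clip, n_coeffs = 13L, spec = frame_spec(), n_filters = 32L) {
  cepstral_coeffs(clip, n_coeffs, spec, gammatone_filterbank, n_filters)
}

## ---- spectral descriptors -----------------------------------------------

#' Ten per-frame spectral descriptors
#'
#' slope (linear-regression slope of magnitude vs frequency), skewness and
#' kurtosis (standardized moments about the centroid), centroid
#' (power-weighted mean frequency), spread (power-weighted standard
#' deviation), decrease (spectral envelope steepness), flux (L2 change
#' between consecutive frames), rolloff (frequency containing
#' `rolloff_pct` of total magnitude), flatness (geometric over arithmetic
#' mean) and normalized Shannon entropy of the power distribution.
#' All-zero frames give `NA` descriptors.
#'
#' @param clip an [audio_clip()].
#' @param spec a [frame_spec()].
#' @param rolloff_pct accumulated-magnitude fraction for rolloff (0.85).
#' @return tibble with one row per frame and the 10 descriptor columns.
#' @export
spectral_descriptors <- function(clip, spec = frame_spec(), rolloff_pct = 0.85) {
  frames <- frame_signal(clip$samples, clip$rate_hz, spec)
  flen <- nrow(frames)
  nfft <- 2^ceiling(log2(flen))
  pad <- rbind(frames, matrix(0, nfft - flen, ncol(frames)))
  mag <- Mod(stats::mvfft(pad))[1:(nfft / 2 + 1), , drop = FALSE]
  freqs <- seq(0, clip$rate_hz / 2, length.out = nfft / 2 + 1)
  n_frames <- ncol(mag)
  out <- matrix(NA_real_, n_frames, 10)
  colnames(out) <- c("slope", "skewness", "centroid", "spread", "decrease",
                     "kurtosis", "flux", "rolloff", "flatness", "entropy")
  prev <- NULL
  for (k in seq_len(n_frames)) {
    m <- mag[, k]
    tot <- sum(m)
    if (tot <= 0) { prev <- m; next }
    # moment descriptors use the power distribution, which localizes a
    # tone's mass and keeps window-leakage skirts from inflating the spread
    pw <- m^2
    ptot <- sum(pw)
    centroid <- sum(freqs * pw) / ptot
    spread <- sqrt(sum((freqs - centroid)^2 * pw) / ptot)
    skew <- if (spread > 0) sum((freqs - centroid)^3 * pw) / ptot / spread^3 else 0
    kurt <- if (spread > 0) sum((freqs - centroid)^4 * pw) / ptot / spread^4 else 0
    slope <- {
      fc <- freqs - mean(freqs)
      sum(fc * (m - mean(m))) / sum(fc^2)
    }
    decrease <- {
      kk <- 2:length(m)
      denom <- sum(m[kk])
      if (denom > 0) sum((m[kk] - m[1]) / (kk - 1)) / denom else 0
    }
    flux <- if (is.null(prev)) 0 else sqrt(sum((m - prev)^2))
    rolloff <- freqs[which(cumsum(m) >= rolloff_pct * tot)[1]]
    flatness <- exp(mean(log(m + 1e-12))) / (mean(m) + 1e-12)
    p <- m^2 / sum(m^2)
    entropy <- -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p))
    out[k, ] <- c(slope, skew, centroid, spread, decrease, kurt, flux,
                  rolloff, flatness, entropy)
    prev <- m
  }
  tibble::as_tibble(out)
}

## ---- wavelet scattering --------------------------------------------------

#' Wavelet scattering configuration
#'
#' @param invariance_s time-invariance scale in seconds (default 0.5).
#' @param q1 wavelets per octave, first filter bank (default 8).
#' @param q2 wavelets per octave, second filter bank (default 1).
#' @param n_windows number of scattering (averaging) windows (default 8).
#' @param log_transform apply `log(x + eps)` to the coefficients.
#' @param eps log floor (default 1e-10).
#' @return list of class `cogscreen_wstconfig`.
#' @export
wst_config <- function(invariance_s = 0.5, q1 = 8L, q2 = 1L, n_windows = 8L,
                       log_transform = TRUE, eps = 1e-10) {
  if (invariance_s <= 0 || q1 <= 0 || q2 <= 0 || n_windows <= 0)
    abort_domain("wst parameters must be positive")
  structure(list(invariance_s = invariance_s, q1 = as.integer(q1),
                 q2 = as.integer(q2), n_windows = as.integer(n_windows),
                 log_transform = log_transform, eps = eps),
            class = "cogscreen_wstconfig")
}

# analytic Morlet-style filterbank on the positive FFT frequencies
morlet_bank <- function(n, rate, q, f_min, f_max) {
  freqs <- (0:(n - 1)) / n * rate
  step <- 2^(1 / q)
  centers <- f_max / step^(0:floor(log(f_max / f_min) / log(step)))
  centers <- centers[centers >= f_min]
  lapply(centers, function(fc) {
    sigma <- fc * (step - 1) / (2 * sqrt(2 * log(2)))
    h <- exp(-(freqs - fc)^2 / (2 * sigma^2))
    h[freqs > rate / 2] <- 0  # analytic: positive frequencies only
    list(fc = fc, h = h)
  })
}

#' Wavelet scattering features
#'
#' Order-0/1/2 scattering of a mono clip with analytic Morlet-style
#' filterbanks (`q1` and `q2` wavelets per octave), a lowpass at the
#' configured invariance scale, averaging into `n_windows` equal time
#' windows and an optional log transform. Second-order paths keep the
#' standard frequency-decreasing condition (second center below the first).
#'
#' @param clip an [audio_clip()] at least as long as the invariance window.
#' @param config a [wst_config()].
#' @return matrix of scattering coefficients, `n_paths x n_windows`, with
#'   row names identifying each path.
#' @export
wst_features <- function(clip, config = wst_config()) {
  x <- clip$samples
  rate <- clip$rate_hz
  if (length(x) < config$invariance_s * rate)
    abort_domain("clip shorter than the invariance window")
  n <- length(x)
  X <- stats::fft(x)
  f_lp <- 1 / config$invariance_s  # lowpass cutoff tied to invariance scale
  freqs <- (0:(n - 1)) / n * rate
  fsym <- pmin(freqs, rate - freqs)
  phi <- exp(-(fsym / f_lp)^2 / 2)

  lowpass_windows <- function(sig_fft) {
    sm <- Re(stats::fft(sig_fft * phi, inverse = TRUE)) / n
    bounds <- round(seq(0, n, length.out = config$n_windows + 1))
    vapply(seq_len(config$n_windows), function(w)
      mean(sm[(bounds[w] + 1):bounds[w + 1]]), numeric(1))
  }

  bank1 <- morlet_bank(n, rate, config$q1, f_min = max(2 * f_lp, 25), f_max = rate / 2 * 0.9)
  rows <- list(S0 = lowpass_windows(X))
  for (b1 in bank1) {
    u1 <- Mod(stats::fft(X * b1$h, inverse = TRUE)) / n  # modulus of analytic band
    U1 <- stats::fft(u1)
    rows[[sprintf("S1_%.0f", b1$fc)]] <- lowpass_windows(U1)
    bank2 <- morlet_bank(n, rate, config$q2, f_min = max(2 * f_lp, 25),
                         f_max = b1$fc / 2)
    for (b2 in bank2) {
      u2 <- Mod(stats::fft(U1 * b2$h, inverse = TRUE)) / n
      rows[[sprintf("S2_%.0f_%.0f", b1$fc, b2$fc)]] <- lowpass_windows(stats::fft(u2))
    }
  }
  out <- do.call(rbind, rows)
  if (config$log_transform) out <- log(pmax(out, 0) + config$eps)
  out
}

## ---- sequence assembly ---------------------------------------------------

#' Assemble a per-frame speech feature sequence
#'
#' Concatenates the configured per-frame features and z-scores each column
#' over the sequence. The `"e3"` preset uses pitch (1 column, NCF), 13
#' MFCCs, 13 GTCCs and spectral skewness (1 column) for 28 columns total.
#'
#' @param clip an [audio_clip()] with silence already removed.
#' @param preset `"e3"` or `"full"`.
#' @param spec a [frame_spec()].
#' @param zscore z-score columns over the sequence (default TRUE).
#' @return matrix `n_frames x n_columns` with named columns; attribute
#'   `zscored` records the flag.
#' @export
assemble_speech_sequence <- function(clip, preset = c("e3", "full"),
                                     spec = frame_spec(), zscore = TRUE) {
  preset <- match.arg(preset)
  if (!length(clip$samples)) abort_domain("empty voiced content")
  p <- pitch(clip, "ncf", spec)
  f0 <- ifelse(p$voiced, p$f0_hz, 0)
  m <- t(mfcc(clip, 13L, spec))
  g <- t(gtcc(clip, 13L, spec))
  sd10 <- spectral_descriptors(clip, spec)
  cols <- cbind(pitch = f0, m, g, skewness = sd10$skewness)
  colnames(cols) <- c("pitch", paste0("mfcc_", 1:13), paste0("gtcc_", 1:13), "skewness")
  if (preset == "full") {
    extra <- as.matrix(sd10[, setdiff(names(sd10), "skewness")])
    cols <- cbind(cols, extra)
  }
  cols[!is.finite(cols)] <- 0
  if (zscore) {
    mu <- colMeans(cols); sdv <- apply(cols, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    cols <- sweep(sweep(cols, 2, mu), 2, sdv, `/`)
  }
  attr(cols, "zscored") <- zscore
  cols
}
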