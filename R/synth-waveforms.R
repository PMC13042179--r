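# Synthetic waveform generation: RR tachogram, ECG, PPG, RESP channels.
#
# The RR model is additive: base period from the heart-rate target, an LF
# (~0.1 Hz) and an HF (~0.25 Hz) sinusoidal modulation, stationary jitter
# whose autocorrelation encodes the irregularity level, and a sparse positive
# "ectopic" jump process for skewness. Amplitudes are calibrated analytically
# against the archetype targets (in expectation) and cached.

.calib_cache <- new.env(parent = emptyenv())

# Solve the modulation amplitudes for an archetype. The NN artifact filter
# used downstream (300-2000 ms, 30% successive-change rule) removes
# beat-to-beat excursions, so large SDNN targets are carried by slow LF
# modulation; the HF amplitude is capped by the pNN50 headroom; jump size is
# capped at a fraction of the base period so jumps survive filtering.
rr_calibration <- function(arch) {
  key <- paste(arch$id, arch$hr_mean, arch$sdnn_target, arch$pnn50_target,
               arch$lfhf_target, arch$rr_skew_target, arch$rr_irregularity,
               sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])

  base <- 60000 / arch$hr_mean
  s <- arch$sdnn_target
  q <- arch$pnn50_target

  if (!is.finite(s) || s <= 0) {
    cal <- list(base = base, sigma_w = 0, phi = 0, p_jump = 0, theta = 0,
                a_lf = 0, a_hf = 0, f_lf = 0.1)
    .calib_cache[[key]] <- cal
    return(cal)
  }

  # White-jitter SD from the pNN50 target: successive differences of white
  # jitter are N(0, 2*sigma^2); choose sigma so P(|diff| > 50 ms) = q%.
  if (q <= 1) {
    sigma_w <- min(0.8 * s, 12)
  } else {
    z <- stats::qnorm(1 - q / 200)
    sigma_w <- 50 / (sqrt(2) * max(z, 0.05))
  }
  sigma_w <- min(sigma_w, 0.95 * s, 0.18 * base)

  # Jitter autocorrelation from the irregularity level: high = white
  # (entropic), low = heavily smoothed (predictable dynamics).
  phi <- switch(arch$rr_irregularity, high = 0, mid = 0.6, low = 0.92)

  # Positive exponential jumps for right-skew, prob p per beat, capped so the
  # artifact filter keeps most jump beats.
  gam <- arch$rr_skew_target
  p_jump <- 0.05
  theta <- 0
  if (is.finite(gam) && gam > 0.3) {
    theta <- (gam * s^3 / (6 * p_jump))^(1 / 3)
    theta <- min(theta, 0.25 * base)
  }
  var_jump <- p_jump * theta^2 * (2 - p_jump)

  # Remaining variance into the sinusoids; HF amplitude capped by the pNN50
  # headroom (HF beats are ~4 s apart at rest, so HF modulation moves
  # successive intervals appreciably), remainder into LF.
  v_rem <- s^2 - sigma_w^2 - var_jump
  if (v_rem < 0) {
    # infeasible combination: shrink jumps, then jitter
    warning(sprintf("archetype %s: targets infeasible jointly; best effort", arch$id))
    theta <- theta * 0.5
    var_jump <- p_jump * theta^2 * (2 - p_jump)
    v_rem <- max(0, s^2 - sigma_w^2 - var_jump)
  }
  R <- max(arch$lfhf_target, 1e-6)
  a_hf <- sqrt(2 * v_rem / (1 + R))
  hf_cap <- if (q >= 40) 90 else if (q >= 15) 35 else if (q >= 1) 15 else 8
  a_hf <- min(a_hf, hf_cap)
  a_lf2 <- max(0, 2 * v_rem - a_hf^2)
  a_lf <- sqrt(a_lf2)
  # Cap LF so intervals stay positive and inside the plausible band.
  a_lf <- min(a_lf, 0.55 * base)
  # Slow the LF modulation enough that its beat-to-beat step stays clear of
  # the 50 ms pNN50 threshold when the archetype targets a low pNN50; large
  # SDNN then lives in slow oscillation, as it must to survive NN filtering.
  f_lf <- 0.1
  if (q < 40 && a_lf > 0) {
    step_cap <- if (q >= 1) 30 else 20  # ms
    ratio <- min(1, step_cap / (2 * a_lf))
    f_max <- asin(ratio) / (pi * base / 1000)
    f_lf <- max(0.01, min(0.1, f_max))
  }

  cal <- list(base = base, sigma_w = sigma_w, phi = phi, p_jump = p_jump,
              theta = theta, a_lf = a_lf, a_hf = a_hf, f_lf = f_lf)
  .calib_cache[[key]] <- cal
  cal
}

#' Generate an RR interval sequence for an archetype
#'
#' Deterministic under `seed`. The sum of intervals always covers
#' `duration_s`, and every interval exceeds 250 ms.
#'
#' @param archetype an [archetype_spec()].
#' @param duration_s segment length in seconds (>= 60).
#' @param seed integer seed.
#' @return numeric vector of RR intervals in milliseconds.
#' @export
generate_rr_series <- function(archetype, duration_s, seed) {
  stopifnot(inherits(archetype, "archetype_spec"))
  if (duration_s < 60) stop("duration_s must be >= 60 s")
  cal <- rr_calibration(archetype)
  base <- cal$base
  n <- ceiling(duration_s * 1000 / (base * 0.6)) + 20L

  with_seed(seed, {
    t_nom <- (seq_len(n) - 1L) * base / 1000  # nominal beat times, s
    lf <- cal$a_lf * sin(2 * pi * cal$f_lf * t_nom)
    phase <- stats::runif(1, 0, 2 * pi)
    hf <- cal$a_hf * sin(2 * pi * 0.25 * t_nom + phase)
    if (cal$sigma_w > 0) {
      innov_sd <- cal$sigma_w * sqrt(1 - cal$phi^2)
      eps <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                      cal$phi, method = "recursive"))
    } else eps <- numeric(n)
    jumps <- numeric(n)
    if (cal$p_jump > 0 && cal$theta > 0) {
      hit <- stats::runif(n) < cal$p_jump
      jumps[hit] <- stats::rexp(sum(hit), rate = 1 / cal$theta)
    }
    rr <- base + lf + hf + eps + jumps
    rr <- pmax(rr, max(250, 0.3 * base))
    keep <- cumsum(rr) <= duration_s * 1000 + base
    m <- max(which(keep))
    rr <- rr[seq_len(min(m + 1L, n))]  # include one beat past the horizon
    rr
  })
}

# Gaussian-sum PQRST template evaluated at offsets (seconds) from the R peak.
pqrst_template <- function(dt) {
  # (amplitude, centre s, width s) for P, Q, R, S, T
  a <- c(0.12, -0.10, 1.00, -0.15, 0.30)
  mu <- c(-0.20, -0.035, 0.000, 0.030, 0.250)
  s <- c(0.045, 0.012, 0.011, 0.013, 0.070)
  out <- numeric(length(dt))
  for (k in 1:5) out <- out + a[k] * exp(-((dt - mu[k])^2) / (2 * s[k]^2))
  out
}

#' Synthesize a single-lead ECG channel from an RR sequence
#'
#' One Gaussian-sum PQRST complex is stamped at each cumulative beat time.
#' R-wave amplitude is modulated by the respiratory phase (the mechanism the
#' ECG-derived respiration extractor relies on), and baseline wander plus
#' white noise are added at a configurable SNR.
#'
#' @param rr RR intervals, ms.
#' @param fs sampling rate, Hz (>= 100).
#' @param resp_phase optional numeric vector in \[-1, 1\] sampled at `fs`
#'   (recycled/truncated to the signal length); `NULL` = 0.25 Hz sinusoid.
#' @param seed integer seed (noise draws).
#' @param r_mod_depth fractional respiratory modulation of R amplitude.
#' @param snr_db additive white-noise SNR in dB; `Inf` disables noise.
#' @param wander_amp baseline-wander amplitude (relative units); frequency
#'   content < 0.3 Hz.
#' @return list with `x` (samples), `fs`, `units`, and attribute-carried
#'   ground-truth beat times (`beat_times_s`).
#' @export
synthesize_ecg <- function(rr, fs, resp_phase = NULL, seed = 1L,
                           r_mod_depth = 0.1, snr_db = 20, wander_amp = 0.05) {
  if (fs < 100) stop("fs below Nyquist requirement for QRS content (>= 100 Hz)")
  t_beats <- cumsum(rr) / 1000          # R-peak times, s (first beat at rr[1])
  dur <- sum(rr) / 1000 + 0.5
  n <- floor(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  if (is.null(resp_phase)) {
    rp <- sin(2 * pi * 0.25 * tt)
  } else {
    rp <- rep_len(resp_phase, n)
  }
  x <- numeric(n)
  half <- 0.42
  amps <- numeric(length(t_beats))
  for (k in seq_along(t_beats)) {
    tk <- t_beats[k]
    i0 <- max(1L, floor((tk - half) * fs) + 1L)
    i1 <- min(n, ceiling((tk + half) * fs) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    ph <- rp[min(n, max(1L, round(tk * fs) + 1L))]
    ak <- 1 + r_mod_depth * ph
    amps[k] <- ak
    x[idx] <- x[idx] + ak * pqrst_template(tt[idx] - tk)
  }
  with_seed(seed, {
    if (wander_amp > 0) {
      ph2 <- stats::runif(2, 0, 2 * pi)
      x <- x + wander_amp * (sin(2 * pi * 0.18 * tt + ph2[1]) +
                             0.6 * sin(2 * pi * 0.28 * tt + ph2[2]))
    }
    if (is.finite(snr_db)) {
      p_sig <- mean(x^2)
      x <- x + stats::rnorm(n, 0, sqrt(p_sig / 10^(snr_db / 10)))
    }
  })
  structure(list(x = x, fs = fs, units = "mV"),
            beat_times_s = t_beats, r_amps = amps)
}

# Single PPG pulse template on relative phase u in [0, 1):
# half-cosine upstroke to the systolic peak at u = rise_frac, exponential
# decay, and a Gaussian dicrotic bump that creates notch + diastolic wave.
ppg_pulse_template <- function(u, rise_frac, notch_prom) {
  y <- numeric(length(u))
  r <- rise_frac
  up <- u <= r & u >= 0
  y[up] <- 0.5 * (1 - cos(pi * u[up] / r))
  dn <- u > r
  k <- log(12) / (1 - r)
  y[dn] <- exp(-k * (u[dn] - r))
  if (notch_prom > 0) {
    un <- r + 0.45 * (1 - r)
    # diastolic wave rises gently: keep its upstroke well below the systolic
    # slope so delineators see one pulse per beat
    y <- y + notch_prom * exp(-((u - un)^2) / (2 * (0.14 * (1 - r))^2)) * as.numeric(u > r)
  }
  y
}

#' Synthesize a PPG channel from an RR sequence
#'
#' One pulse per beat, delayed by the pulse-arrival time; per-beat AC
#' amplitudes are drawn from a skew-controllable (standardized gamma)
#' distribution so their sample skewness approaches `ac_skew_target` in
#' expectation.
#'
#' @param rr RR intervals, ms.
#' @param morph list with `rise_frac`, `notch_prom` (in \[0,1)), `pat_ms`.
#' @param fs sampling rate, Hz (>= 25).
#' @param seed integer seed.
#' @param ac_skew_target target skewness of per-beat AC amplitudes.
#' @param ac_mean,ac_cv mean and coefficient of variation of AC amplitudes.
#' @param snr_db additive white-noise SNR in dB; `Inf` disables noise.
#' @return list with `x`, `fs`, `units`; ground truth in attributes
#'   (`onset_times_s`, `ac_amps`).
#' @export
synthesize_ppg <- function(rr, morph, fs, seed = 1L, ac_skew_target = 0,
                           ac_mean = 0.37, ac_cv = 0.10, snr_db = 25) {
  if (fs < 25) stop("fs must be >= 25 Hz for PPG synthesis")
  if (morph$notch_prom < 0 || morph$notch_prom >= 1) {
    stop("notch prominence must lie in [0, 1)")
  }
  nb <- length(rr)
  t_beats <- cumsum(rr) / 1000
  onset <- t_beats + morph$pat_ms / 1000
  dur <- sum(rr) / 1000 + morph$pat_ms / 1000 + 1.5
  n <- floor(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  amps <- with_seed(derive_seed(seed, 11L), {
    g <- ac_skew_target
    if (abs(g) < 0.05) {
      z <- stats::rnorm(nb)
    } else {
      shape <- (2 / abs(g))^2
      z <- (stats::rgamma(nb, shape = shape, rate = 1) - shape) / sqrt(shape)
      if (g < 0) z <- -z
    }
    pmax(0.05 * ac_mean, ac_mean * (1 + ac_cv * z))
  })
  x <- numeric(n)
  for (k in seq_len(nb)) {
    t0 <- onset[k]
    Tk <- rr[k] / 1000
    i0 <- max(1L, floor(t0 * fs) + 1L)
    i1 <- min(n, ceiling((t0 + Tk) * fs))
    if (i0 > i1) next
    idx <- i0:i1
    u <- (tt[idx] - t0) / Tk
    x[idx] <- x[idx] + amps[k] * ppg_pulse_template(u, morph$rise_frac, morph$notch_prom)
  }
  x <- x + 1.0  # DC baseline
  with_seed(derive_seed(seed, 12L), {
    if (is.finite(snr_db)) {
      p_sig <- stats::var(x)
      x <- x + stats::rnorm(n, 0, sqrt(p_sig / 10^(snr_db / 10)))
    }
  })
  structure(list(x = x, fs = fs, units = "au"),
            onset_times_s = onset, ac_amps = amps)
}

#' Synthesize a respiratory impedance channel
#'
#' Quasi-sinusoidal breathing with per-cycle jittered periods; the mean cycle
#' rate stays within 5% of `resp_rate`.
#'
#' @param resp_rate breaths/min, in (4, 60).
#' @param fs sampling rate, Hz.
#' @param duration_s length in seconds.
#' @param seed integer seed.
#' @param jitter fractional SD of cycle periods (0 = perfectly periodic).
#' @return list with `x`, `fs`, `units`; per-cycle period truth in attributes.
#' @export
synthesize_resp <- function(resp_rate, fs, duration_s, seed = 1L, jitter = 0.05) {
  if (resp_rate <= 4 || resp_rate >= 60) stop("resp_rate must be in (4, 60) breaths/min")
  T0 <- 60 / resp_rate
  n_cyc <- ceiling(duration_s / T0) + 3L
  periods <- with_seed(seed, {
    p <- T0 * (1 + jitter * stats::rnorm(n_cyc))
    pmax(p, 0.4 * T0)
  })
  if (jitter > 0) periods <- periods * (T0 / mean(periods))  # hold mean rate
  ends <- cumsum(periods)
  n <- floor(duration_s * fs)
  tt <- (seq_len(n) - 1L) / fs
  cyc <- findInterval(tt, c(0, ends), rightmost.closed = FALSE)
  cyc <- pmin(cyc, n_cyc)
  start <- c(0, ends)[cyc]
  phase <- (tt - start) / periods[cyc]
  x <- -cos(2 * pi * phase)  # trough at cycle start, peak mid-cycle
  structure(list(x = x, fs = fs, units = "au"), cycle_periods_s = periods)
}
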