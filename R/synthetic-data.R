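# Synthetic EEG-like sessions with known directed coupling. The generator is
# the package's validation instrument: every downstream claim (GC recovery,
# class separability, robustness) is tested against structure planted here.

#' Specify a stationary VAR process with known directed coupling
#'
#' Defines a vector-autoregressive ground truth used both to plant directed
#' connectivity in synthetic EEG sessions and to benchmark Granger-causality
#' recovery. Stationarity is enforced at construction via the spectral radius
#' of the companion matrix.
#'
#' @param n_channels Number of channels C.
#' @param lag_order Autoregressive order P of the process.
#' @param coupling Data frame with columns `source`, `target`, `lag`,
#'   `coefficient` describing nonzero autoregressive terms
#'   (`target_t += coefficient * source_{t-lag}`). Own-lag terms
#'   (`source == target`) are allowed. `NULL` means no coupling.
#' @param innovation_sd Innovation standard deviation, recycled to C channels.
#' @param seed Integer seed; realisations are pure functions of (spec, seed).
#' @return An object of class `var_spec`.
#' @examples
#' sp <- var_spec(2, 1, coupling = data.frame(
#'   source = 1, target = 2, lag = 1, coefficient = 0.9))
#' x <- simulate_var(sp, 500)
#' @export
var_spec <- function(n_channels, lag_order, coupling = NULL,
                     innovation_sd = 1, seed = 1L) {
  n_channels <- check_positive_int(n_channels, "n_channels")
  lag_order <- check_positive_int(lag_order, "lag_order")
  innovation_sd <- rep_len(innovation_sd, n_channels)
  if (any(innovation_sd <= 0)) abort("`innovation_sd` must be positive.")
  if (is.null(coupling)) {
    coupling <- tibble::tibble(source = integer(), target = integer(),
                               lag = integer(), coefficient = double())
  }
  coupling <- tibble::as_tibble(coupling)
  needed <- c("source", "target", "lag", "coefficient")
  if (!all(needed %in% names(coupling))) {
    abort("`coupling` needs columns source, target, lag, coefficient.")
  }
  if (nrow(coupling) > 0) {
    if (any(coupling$source < 1 | coupling$source > n_channels |
            coupling$target < 1 | coupling$target > n_channels)) {
      abort("`coupling` channel indices out of range.")
    }
    if (any(coupling$lag < 1 | coupling$lag > lag_order)) {
      abort("`coupling` lags must lie in 1..lag_order.")
    }
  }
  spec <- structure(
    list(n_channels = n_channels, lag_order = lag_order, coupling = coupling,
         innovation_sd = innovation_sd, seed = as.integer(seed)),
    class = "var_spec"
  )
  rho <- companion_spectral_radius(spec)
  if (rho >= 1) {
    abort(sprintf(
      "VAR specification is non-stationary: companion spectral radius %.3f >= 1.",
      rho))
  }
  spec
}

# Coefficient array [C x C x P] from a var_spec.
var_coef_array <- function(spec) {
  C <- spec$n_channels
  P <- spec$lag_order
  A <- array(0, dim = c(C, C, P))
  cp <- spec$coupling
  for (k in seq_len(nrow(cp))) {
    A[cp$target[k], cp$source[k], cp$lag[k]] <-
      A[cp$target[k], cp$source[k], cp$lag[k]] + cp$coefficient[k]
  }
  A
}

companion_spectral_radius <- function(spec) {
  C <- spec$n_channels
  P <- spec$lag_order
  A <- var_coef_array(spec)
  comp <- matrix(0, C * P, C * P)
  for (p in seq_len(P)) comp[1:C, ((p - 1) * C + 1):(p * C)] <- A[, , p]
  if (P > 1) {
    comp[(C + 1):(C * P), 1:(C * (P - 1))] <- diag(C * (P - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a realisation of a VAR specification
#'
#' Draws Gaussian innovations, runs the autoregressive recursion, and discards
#' a burn-in of `10 * lag_order` samples so the emitted stretch is past the
#' startup transient. Identical (spec, seed) gives bit-identical output.
#'
#' @param spec A [var_spec()].
#' @param n_samples Number of post-burn-in samples to return; must exceed
#'   `10 * lag_order`.
#' @param seed Optional override of `spec$seed`.
#' @return Numeric matrix `[n_samples x C]`.
#' @export
simulate_var <- function(spec, n_samples, seed = NULL) {
  stopifnot(inherits(spec, "var_spec"))
  n_samples <- check_positive_int(n_samples, "n_samples")
  if (n_samples <= 10 * spec$lag_order) {
    abort("`n_samples` must exceed 10 * lag_order.")
  }
  burn <- 10L * spec$lag_order
  C <- spec$n_channels
  seed <- seed %||% spec$seed
  innov <- local_seed(seed, {
    matrix(rnorm((n_samples + burn) * C), n_samples + burn, C) *
      rep(spec$innovation_sd, each = n_samples + burn)
  })
  x <- cpp_var_recursion(var_coef_array(spec), innov)
  x[(burn + 1):(burn + n_samples), , drop = FALSE]
}

#' Specify a synthetic multi-subject EEG session
#'
#' Emulates the structure of stimulus-locked EEG emotion datasets: every
#' subject watches the same ordered set of videos; each trial carries a
#' pre-stimulus baseline followed by the emotion period; the recording is cut
#' into 1 s windows and the average of the baseline windows is subtracted from
#' each emotion window. Class identity modulates both the per-channel band
#' amplitudes and (optionally) the directed VAR coupling, so that spatial and
#' temporal branches both carry class information.
#'
#' Defaults mirror a 32-subject, 40-video protocol with 63 s trials (3 s
#' baseline + 60 s emotion) sampled at 128 Hz.
#'
#' @param n_subjects,n_trials_per_subject Session dimensions; video IDs
#'   `1..n_trials_per_subject` are shared across subjects.
#' @param trial_duration_s,baseline_duration_s Whole-second durations; the
#'   trial must be longer than its baseline.
#' @param sampling_rate_hz Sampling rate; each emitted window has
#'   `sampling_rate_hz` samples.
#' @param n_channels Channel count (used when profiles/connectivity are
#'   defaulted).
#' @param n_classes Number of emotion classes; video `v` is assigned class
#'   `((v - 1) %% n_classes) + 1`, identically for every subject.
#' @param class_band_powers List of length `n_classes`; element k is a list
#'   with `freqs_hz` (vector) and `amps` (`[n_channels x length(freqs_hz)]`
#'   matrix) giving that class's oscillation profile. `NULL` uses
#'   [default_class_profiles()].
#' @param class_connectivity List of length `n_classes` of [var_spec()]s (or
#'   `NULL` for none) planting class-specific directed coupling.
#' @param noise_sd Additive white measurement-noise SD.
#' @param seed Integer seed.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(n_subjects = 32, n_trials_per_subject = 40,
                         trial_duration_s = 63, baseline_duration_s = 3,
                         sampling_rate_hz = 128, n_channels = 32,
                         n_classes = 2, class_band_powers = NULL,
                         class_connectivity = NULL, noise_sd = 0.2,
                         seed = 1L) {
  n_subjects <- check_positive_int(n_subjects, "n_subjects")
  n_trials_per_subject <- check_positive_int(n_trials_per_subject,
                                             "n_trials_per_subject")
  trial_duration_s <- check_positive_int(trial_duration_s, "trial_duration_s")
  baseline_duration_s <- check_positive_int(baseline_duration_s,
                                            "baseline_duration_s")
  sampling_rate_hz <- check_positive_int(sampling_rate_hz, "sampling_rate_hz")
  n_channels <- check_positive_int(n_channels, "n_channels")
  n_classes <- check_positive_int(n_classes, "n_classes")
  if (trial_duration_s <= baseline_duration_s) {
    abort("`trial_duration_s` must exceed `baseline_duration_s`.")
  }
  if (is.null(class_band_powers)) {
    class_band_powers <- default_class_profiles(n_classes, n_channels,
                                                sampling_rate_hz)
  }
  if (length(class_band_powers) < n_classes) {
    abort("`n_classes` exceeds the number of band-power profiles supplied.")
  }
  if (!is.null(class_connectivity)) {
    if (length(class_connectivity) < n_classes) {
      abort("`n_classes` exceeds the number of connectivity specs supplied.")
    }
    for (cs in class_connectivity) {
      if (!is.null(cs)) {
        stopifnot(inherits(cs, "var_spec"))
        if (cs$n_channels != n_channels) {
          abort("class_connectivity channel count must match `n_channels`.")
        }
      }
    }
  }
  structure(
    list(n_subjects = n_subjects,
         n_trials_per_subject = n_trials_per_subject,
         trial_duration_s = trial_duration_s,
         baseline_duration_s = baseline_duration_s,
         sampling_rate_hz = sampling_rate_hz,
         n_channels = n_channels, n_classes = n_classes,
         class_band_powers = class_band_powers,
         class_connectivity = class_connectivity,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "session_spec"
  )
}

#' Default class-dependent oscillation profiles
#'
#' Builds `n_classes` clearly distinct spectral profiles: each class
#' concentrates its oscillatory power at class-specific frequencies on a
#' class-specific subset of channels, so classes are separable from both
#' spectral content and its spatial distribution.
#'
#' @inheritParams session_spec
#' @return List of per-class profiles (`freqs_hz`, `amps`).
#' @export
default_class_profiles <- function(n_classes, n_channels,
                                   sampling_rate_hz = 128) {
  nyq <- sampling_rate_hz / 2
  base_freqs <- c(6, 10, 14, 20, 26, 32)
  base_freqs <- base_freqs[base_freqs < 0.9 * nyq]
  lapply(seq_len(n_classes), function(k) {
    f1 <- base_freqs[((k - 1) %% length(base_freqs)) + 1]
    f2 <- base_freqs[(k %% length(base_freqs)) + 1]
    # class k strong on its own channel block, weak elsewhere
    block <- ((seq_len(n_channels) + k) %% n_classes) == 0
    amps <- cbind(ifelse(block, 2.0, 0.3), ifelse(block, 0.4, 1.2))
    list(freqs_hz = c(f1, f2), amps = amps)
  })
}

#' Simulate a labelled synthetic EEG session
#'
#' For every subject x trial, synthesises a continuous multichannel signal
#' (class oscillations with random phases + class VAR coupling + white noise),
#' cuts it into 1 s windows, averages the baseline windows into a per-channel
#' window template, subtracts that template from every emotion window, and
#' emits the emotion windows as labelled segments.
#'
#' @param spec A [session_spec()].
#' @return An object of class `eeg_session`: list with `segments`
#'   (`[N x L x C]` array), `meta` (tibble: segment_id, subject, video,
#'   session, class, window), and the generating `spec`.
#' @export
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  fs <- spec$sampling_rate_hz
  L <- fs
  C <- spec$n_channels
  n_win <- spec$trial_duration_s
  n_base <- spec$baseline_duration_s
  n_emo <- n_win - n_base
  n_trials <- spec$n_subjects * spec$n_trials_per_subject
  n_seg <- n_trials * n_emo

  segments <- array(0, dim = c(n_seg, L, C))
  meta <- vector("list", n_trials)
  video_class <- ((seq_len(spec$n_trials_per_subject) - 1) %%
                    spec$n_classes) + 1

  local_seed(spec$seed, {
    seg_at <- 0L
    row_at <- 0L
    tt <- seq_len(n_win * fs) / fs
    # class oscillations are stimulus-evoked: present only after the
    # pre-stimulus baseline, so baseline subtraction removes tonic offsets
    # without cancelling the class signal
    evoked <- rep(c(0, 1), c(n_base * fs, (n_win - n_base) * fs))
    for (subject in seq_len(spec$n_subjects)) {
      for (video in seq_len(spec$n_trials_per_subject)) {
        cls <- video_class[video]
        prof <- spec$class_band_powers[[cls]]
        sig <- matrix(0, n_win * fs, C)
        for (b in seq_along(prof$freqs_hz)) {
          phases <- runif(C, 0, 2 * pi)
          amps <- rep_len(prof$amps[, b], C)
          sig <- sig + sin(outer(2 * pi * prof$freqs_hz[b] * tt, phases, "+")) *
            rep(amps, each = n_win * fs) * evoked
        }
        conn <- if (is.null(spec$class_connectivity)) NULL else
          spec$class_connectivity[[cls]]
        if (!is.null(conn)) {
          sub_seed <- sample.int(.Machine$integer.max, 1)
          sig <- sig + simulate_var(conn, n_win * fs, seed = sub_seed)
        }
        if (spec$noise_sd > 0) {
          sig <- sig + matrix(rnorm(length(sig), sd = spec$noise_sd),
                              nrow(sig), ncol(sig))
        }
        # window, baseline-average, subtract
        win <- array(sig, dim = c(fs, n_win, C))  # [L x window x C]
        baseline <- apply(win[, seq_len(n_base), , drop = FALSE], c(1, 3), mean)
        for (w in seq_len(n_emo)) {
          seg_at <- seg_at + 1L
          segments[seg_at, , ] <- win[, n_base + w, ] - baseline
        }
        row_at <- row_at + 1L
        meta[[row_at]] <- tibble::tibble(
          subject = subject, video = video, session = 1L, class = cls,
          window = seq_len(n_emo))
      }
    }
  })
  meta <- dplyr::bind_rows(meta)
  meta <- dplyr::mutate(meta, segment_id = dplyr::row_number(),
                        .before = 1)
  structure(list(segments = segments, meta = meta, spec = spec),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf(
    "<eeg_session> %d segments of %d samples x %d channels (%d subjects, %d videos, %d classes)\n",
    d[1], d[2], d[3], x$spec$n_subjects, x$spec$n_trials_per_subject,
    x$spec$n_classes))
  invisible(x)
}

#' Sum-of-sinusoids test signal
#'
#' Fixture generator for the frequency-domain denoiser: a mixture of known
#' tones plus white noise.
#'
#' @param freqs_hz,amps Equal-length vectors of tone frequencies and
#'   amplitudes; all frequencies must be below `fs_hz / 2`.
#' @param n_samples Signal length.
#' @param fs_hz Sampling rate.
#' @param noise_sd White-noise SD (0 for the clean mixture).
#' @param seed Integer seed for the noise.
#' @return Numeric vector of length `n_samples`.
#' @export
tonal_signal <- function(freqs_hz, amps, n_samples, fs_hz,
                         noise_sd = 0, seed = 1L) {
  if (length(freqs_hz) != length(amps)) {
    abort("`freqs_hz` and `amps` must have equal length.")
  }
  if (any(freqs_hz >= fs_hz / 2)) {
    abort("All frequencies must be below the Nyquist rate fs_hz / 2.")
  }
  n_samples <- check_positive_int(n_samples, "n_samples")
  tt <- seq_len(n_samples) / fs_hz
  x <- rep(0, n_samples)
  for (b in seq_along(freqs_hz)) {
    x <- x + amps[b] * sin(2 * pi * freqs_hz[b] * tt)
  }
  if (noise_sd > 0) {
    x <- x + local_seed(seed, rnorm(n_samples, sd = noise_sd))
  }
  x
}

#' Write / read a session as plain-text files
#'
#' `write_session()` stores `meta.csv` plus `segments.csv` (one row per
#' segment, the `[L x C]` array flattened column-major) and a small
#' `shape.csv`; `read_session()` inverts it.
#'
#' @param session An `eeg_session`.
#' @param dir Output directory (created if needed).
#' @return `write_session()` the directory invisibly; `read_session()` an
#'   `eeg_session` (without the generating spec).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "eeg_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(session$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  d <- dim(session$segments)
  write.csv(data.frame(n = d[1], len = d[2], channels = d[3]),
            file.path(dir, "shape.csv"), row.names = FALSE)
  flat <- matrix(session$segments, nrow = d[1])
  utils::write.table(flat, file.path(dir, "segments.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- tibble::as_tibble(read.csv(file.path(dir, "meta.csv")))
  d <- read.csv(file.path(dir, "shape.csv"))
  flat <- as.matrix(read.csv(file.path(dir, "segments.csv"), header = FALSE))
  segments <- array(flat, dim = c(d$n, d$len, d$channels))
  structure(list(segments = segments, meta = meta, spec = NULL),
            class = "eeg_session")
}
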