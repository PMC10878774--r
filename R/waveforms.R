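#' Construct a pulse train from a segment table
#'
#' A pulse train is an ordered sequence of piecewise-constant electric-field
#' segments: each segment has a strictly positive duration (seconds) and a
#' signed field amplitude (V/m, zero for delays between pulses). All of the
#' protocol constructors ([make_monopolar_train()], [make_hf_bipolar_train()],
#' [preset_train()]) reduce to this representation, and the simulator consumes
#' nothing else, so arbitrary user-defined rectangular protocols can be
#' supplied directly.
#'
#' @param segments data.frame with numeric columns `duration` (s, > 0) and
#'   `field` (V/m, finite; sign encodes polarity).
#' @param name label used in outputs and trajectory metadata.
#' @param electrode_gap optional electrode spacing in metres (e.g. `2e-3` for
#'   a 2 mm cuvette), used to relate applied voltage and field.
#' @param source_voltage optional generator voltage in volts. When both
#'   `electrode_gap` and `source_voltage` are given, every non-zero segment
#'   amplitude must equal `source_voltage / electrode_gap`.
#' @return An object of class `pulse_train`.
#' @seealso [on_time()], [field_at()], [train_duration()], [write_train()]
#' @export
pulse_train <- function(segments, name = "custom", electrode_gap = NULL,
                        source_voltage = NULL) {
  if (!is.data.frame(segments) ||
      !all(c("duration", "field") %in% names(segments))) {
    stop("`segments` must be a data.frame with columns `duration` and `field`")
  }
  segments <- data.frame(duration = as.numeric(segments$duration),
                         field = as.numeric(segments$field))
  if (nrow(segments) > 0) {
    if (any(!is.finite(segments$duration)) || any(segments$duration <= 0)) {
      stop("segment durations must be finite and strictly positive")
    }
    if (any(!is.finite(segments$field))) {
      stop("segment fields must be finite")
    }
  }
  if (!is.null(electrode_gap) && electrode_gap <= 0) {
    stop("`electrode_gap` must be positive")
  }
  if (!is.null(electrode_gap) && !is.null(source_voltage)) {
    active <- abs(segments$field) > 0
    expected <- abs(source_voltage) / electrode_gap
    if (any(active) &&
        any(abs(abs(segments$field[active]) - expected) > 1e-9 * max(expected, 1))) {
      stop("non-zero segment amplitudes are inconsistent with ",
           "source_voltage / electrode_gap")
    }
  }
  structure(
    list(name = as.character(name), segments = segments,
         electrode_gap = electrode_gap, source_voltage = source_voltage),
    class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  n_active <- sum(x$segments$field != 0)
  cat(sprintf("<pulse_train> %s: %d segments (%d active), duration %.6g s, on-time %.6g s\n",
              x$name, nrow(x$segments), n_active,
              train_duration(x), on_time(x)))
  if (nrow(x$segments) > 0) {
    cat(sprintf("  peak |field| %.4g V/m (%.3g kV/cm)\n",
                max(abs(x$segments$field)), max(abs(x$segments$field)) / 1e5))
  }
  invisible(x)
}

#' @export
as.data.frame.pulse_train <- function(x, ...) x$segments

#' Monopolar rectangular pulse train
#'
#' Builds `n_pulses` identical rectangular pulses delivered at a fixed
#' repetition frequency: active segments of `pulse_duration` separated by
#' zero-field gaps of `1/repetition_frequency - pulse_duration`. No gap is
#' appended after the final pulse, so the train duration is
#' `(n_pulses - 1)/repetition_frequency + pulse_duration`.
#'
#' @param n_pulses number of pulses (positive integer).
#' @param pulse_duration pulse width in seconds.
#' @param repetition_frequency pulse repetition frequency in Hz; the period
#'   `1/repetition_frequency` must not be shorter than `pulse_duration`
#'   (checked when `n_pulses > 1`).
#' @param field signed field amplitude in V/m.
#' @param name train label.
#' @param electrode_gap,source_voltage see [pulse_train()].
#' @return A `pulse_train`.
#' @examples
#' on_time(make_monopolar_train(8, 100e-6, 1, 1.2e5)) # 800 us
#' @export
make_monopolar_train <- function(n_pulses, pulse_duration, repetition_frequency,
                                 field, name = "monopolar",
                                 electrode_gap = NULL, source_voltage = NULL) {
  stopifnot(n_pulses >= 1, n_pulses == round(n_pulses),
            pulse_duration > 0, repetition_frequency > 0)
  gap <- 1 / repetition_frequency - pulse_duration
  if (n_pulses > 1 && gap < 0) {
    stop("invalid protocol: pulse period 1/repetition_frequency (",
         format(1 / repetition_frequency), " s) is shorter than the pulse duration (",
         format(pulse_duration), " s)")
  }
  pulse <- data.frame(duration = pulse_duration, field = field)
  if (n_pulses == 1 || gap == 0) {
    segs <- pulse[rep(1, n_pulses), , drop = FALSE]
  } else {
    unit <- rbind(pulse, data.frame(duration = gap, field = 0))
    segs <- unit[rep(seq_len(2), n_pulses), , drop = FALSE]
    segs <- segs[-nrow(segs), , drop = FALSE] # trim trailing gap
  }
  rownames(segs) <- NULL
  pulse_train(segs, name = name, electrode_gap = electrode_gap,
              source_voltage = source_voltage)
}

#' High-frequency bipolar burst train
#'
#' Builds bursts of short bipolar pulses. One bipolar pulse is the four-phase
#' unit `+field` for `phase_duration`, zero for `interphase_delay`, `-field`
#' for `phase_duration`, zero for `interpulse_delay`; a burst concatenates
#' `pulses_per_burst` such units with the trailing interpulse delay of the
#' last unit trimmed. Burst starts are spaced `1/burst_repetition_frequency`
#' apart (start-to-start), and no delay follows the last burst.
#'
#' With the default 2 us phases and delays, each 50-pulse burst carries
#' 200 us of on-time in 398 us.
#'
#' @param n_bursts number of bursts.
#' @param pulses_per_burst bipolar pulses per burst.
#' @param phase_duration duration of each polarity phase (s).
#' @param interphase_delay zero-field delay between the + and - phase (s).
#' @param interpulse_delay zero-field delay between bipolar pulses (s).
#' @param burst_repetition_frequency burst repetition frequency (Hz).
#' @param field phase amplitude in V/m (positive; the negative phase is
#'   generated internally).
#' @param name train label.
#' @param electrode_gap,source_voltage see [pulse_train()].
#' @return A `pulse_train`.
#' @examples
#' on_time(make_hf_bipolar_train(1, 50, 2e-6, 2e-6, 2e-6, 1, 1.4e5)) # 200 us
#' @export
make_hf_bipolar_train <- function(n_bursts, pulses_per_burst,
                                  phase_duration = 2e-6,
                                  interphase_delay = 2e-6,
                                  interpulse_delay = 2e-6,
                                  burst_repetition_frequency = 1,
                                  field,
                                  name = "hf_bipolar",
                                  electrode_gap = NULL, source_voltage = NULL) {
  stopifnot(n_bursts >= 1, n_bursts == round(n_bursts),
            pulses_per_burst >= 1, pulses_per_burst == round(pulses_per_burst),
            phase_duration > 0, interphase_delay >= 0, interpulse_delay >= 0,
            burst_repetition_frequency > 0)
  unit <- data.frame(
    duration = c(phase_duration, interphase_delay, phase_duration, interpulse_delay),
    field = c(field, 0, -field, 0))
  unit <- unit[unit$duration > 0, , drop = FALSE]
  burst <- unit[rep(seq_len(nrow(unit)), pulses_per_burst), , drop = FALSE]
  if (interpulse_delay > 0) {
    burst <- burst[-nrow(burst), , drop = FALSE] # trim trailing interpulse delay
  }
  burst_duration <- sum(burst$duration)
  period <- 1 / burst_repetition_frequency
  if (n_bursts > 1 && burst_duration > period) {
    stop("invalid protocol: burst duration (", format(burst_duration),
         " s) exceeds the burst period (", format(period), " s)")
  }
  if (n_bursts == 1) {
    segs <- burst
  } else {
    unit_b <- rbind(burst, data.frame(duration = period - burst_duration, field = 0))
    unit_b <- unit_b[unit_b$duration > 0, , drop = FALSE]
    segs <- unit_b[rep(seq_len(nrow(unit_b)), n_bursts), , drop = FALSE]
    n_tail <- nrow(unit_b) - nrow(burst)
    if (n_tail > 0) segs <- segs[seq_len(nrow(segs) - n_tail), , drop = FALSE]
  }
  rownames(segs) <- NULL
  pulse_train(segs, name = name, electrode_gap = electrode_gap,
              source_voltage = source_voltage)
}

#' Total pulse on-time of a train
#'
#' The on-time is the summed duration of all segments whose field is non-zero
#' (the time the applied voltage differs from zero), regardless of polarity.
#'
#' @param train a `pulse_train`.
#' @return On-time in seconds.
#' @export
on_time <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  sum(train$segments$duration[train$segments$field != 0])
}

#' Total duration of a train
#'
#' @param train a `pulse_train`.
#' @return Duration in seconds (sum of all segment durations).
#' @export
train_duration <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  sum(train$segments$duration)
}

#' Field value at a given time
#'
#' Segments occupy half-open intervals `[start, end)`, so the value at a
#' segment boundary belongs to the following segment; times at or beyond the
#' train end return 0.
#'
#' @param train a `pulse_train`.
#' @param t time(s) in seconds since train start; must be `>= 0`.
#' @return Signed field in V/m, vectorised over `t`.
#' @export
field_at <- function(train, t) {
  stopifnot(inherits(train, "pulse_train"))
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  if (nrow(train$segments) == 0) return(rep(0, length(t)))
  bounds <- c(0, cumsum(train$segments$duration))
  idx <- findInterval(t, bounds)
  out <- rep(0, length(t))
  inside <- idx >= 1 & idx <= nrow(train$segments) & t < bounds[length(bounds)]
  out[inside] <- train$segments$field[idx[inside]]
  out
}

#' Convert an applied voltage to a field over a parallel-plate gap
#'
#' For cells in a cuvette between parallel plate electrodes the nominal field
#' is voltage over electrode spacing; e.g. 280 V over a 2 mm gap gives
#' 1.4e5 V/m (1.4 kV/cm).
#'
#' @param voltage applied voltage in volts.
#' @param gap electrode spacing in metres; must be positive.
#' @return Field in V/m.
#' @export
field_from_voltage <- function(voltage, gap) {
  if (any(!is.finite(gap)) || any(gap <= 0)) stop("`gap` must be positive")
  voltage / gap
}

#' Named preset pulse protocols
#'
#' The five study protocols, each at its per-protocol optimal field strength
#' (overridable via `field`):
#' \describe{
#'   \item{`hf_50x50`}{50 bursts at 1 Hz of 50 bipolar pulses (2 us phases,
#'     2 us delays), 1.4 kV/cm, 2 mm gap (280 V).}
#'   \item{`mono_8x100us`}{8 x 100 us monopolar pulses at 1 Hz, 1.2 kV/cm,
#'     2 mm gap (240 V).}
#'   \item{`mono_8x5ms`}{8 x 5 ms monopolar pulses at 1 Hz, 0.6 kV/cm,
#'     2 mm gap (120 V).}
#'   \item{`ns_1x200`}{a single 200 ns pulse, 12.6 kV/cm.}
#'   \item{`ns_25x400`}{25 x 400 ns pulses at 10 Hz, 3.9 kV/cm.}
#' }
#'
#' @param name one of [preset_names()].
#' @param field optional field override in V/m (replaces the optimal field).
#' @return A `pulse_train`.
#' @export
preset_train <- function(name, field = NULL) {
  name <- match.arg(name, preset_names())
  gap2mm <- 2e-3
  switch(name,
    hf_50x50 = {
      E <- if (is.null(field)) 1.4e5 else field
      make_hf_bipolar_train(50, 50, 2e-6, 2e-6, 2e-6, 1, E, name = "hf_50x50",
                            electrode_gap = gap2mm,
                            source_voltage = if (is.null(field)) 280 else E * gap2mm)
    },
    mono_8x100us = {
      E <- if (is.null(field)) 1.2e5 else field
      make_monopolar_train(8, 100e-6, 1, E, name = "mono_8x100us",
                           electrode_gap = gap2mm,
                           source_voltage = if (is.null(field)) 240 else E * gap2mm)
    },
    mono_8x5ms = {
      E <- if (is.null(field)) 0.6e5 else field
      make_monopolar_train(8, 5e-3, 1, E, name = "mono_8x5ms",
                           electrode_gap = gap2mm,
                           source_voltage = if (is.null(field)) 120 else E * gap2mm)
    },
    ns_1x200 = {
      E <- if (is.null(field)) 12.6e5 else field
      make_monopolar_train(1, 200e-9, 1, E, name = "ns_1x200")
    },
    ns_25x400 = {
      E <- if (is.null(field)) 3.9e5 else field
      make_monopolar_train(25, 400e-9, 10, E, name = "ns_25x400")
    })
}

#' @rdname preset_train
#' @export
preset_names <- function() {
  c("hf_50x50", "mono_8x100us", "mono_8x5ms", "ns_1x200", "ns_25x400")
}

#' Serialize a pulse train to a plain-text segment table
#'
#' Writes/reads a tab-separated table with columns `duration_s` and
#' `field_V_per_m`, one row per segment.
#'
#' @param train a `pulse_train`.
#' @param path file path.
#' @export
write_train <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  tab <- data.frame(duration_s = train$segments$duration,
                    field_V_per_m = train$segments$field)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_train
#' @param name label for the reconstructed train.
#' @export
read_train <- function(path, name = "custom") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("duration_s", "field_V_per_m") %in% names(tab))) {
    stop("segment table must have columns duration_s and field_V_per_m")
  }
  pulse_train(data.frame(duration = tab$duration_s, field = tab$field_V_per_m),
              name = name)
}
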