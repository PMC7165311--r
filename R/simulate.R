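#' Simulate a six-phase fall recording
#'
#' Synthesizes a lower-back triaxial accelerometer recording from a
#' \code{\link{fall_protocol}}, together with ground-truth phase
#' annotations. The kinematic model is a single-angle rigid-trunk
#' approximation: the sensor sits near the trunk's center of mass, and in a
#' static posture with trunk pitch \eqn{\theta} (0 = upright, 90 =
#' horizontal forward bend) gravity reads \eqn{z = \cos\theta},
#' \eqn{x = \sin\theta}, \eqn{y = 0} (units of g). Phase kinds:
#' \describe{
#'   \item{steps}{upright gravity plus a vertical sinusoid at the step
#'     frequency with the step amplitude, and a mediolateral sway of a
#'     quarter of that amplitude at half the step frequency.}
#'   \item{fall_impact}{the total acceleration magnitude decays linearly to
#'     0 over the freefall duration (the sensor approaches free fall); then
#'     a half-sine impact transient raises the magnitude to
#'     \code{impact_peak_g} along the end-posture direction over the impact
#'     duration; the remainder of the phase reads the static posture at
#'     \code{end_pitch_deg}.}
#'   \item{rest}{the static gravity reading at \code{pitch_deg}.}
#'   \item{raise / stand}{pitch follows a smooth cosine ramp from
#'     \code{start_pitch_deg} to \code{end_pitch_deg}, with a 4 Hz movement
#'     transient on the vertical axis whose amplitude decays linearly to 0
#'     by the phase end.}
#' }
#' Each phase spans \code{round(duration_s * rate)} samples (half-up
#' rounding); i.i.d. Gaussian noise of sd \code{noise_sd_g} is added per
#' axis and sample; optional clipping emulates the device range. Noise is
#' drawn from per-phase substreams derived deterministically from the
#' protocol seed, so the same protocol and seed reproduce the signal
#' bit-for-bit.
#'
#' @param protocol a \code{\link{fall_protocol}}.
#' @return An object of class \code{fall_simulation}: a list with
#'   \code{signal} (an \code{\link{accsignal}}) and \code{annotations}
#'   (see \code{\link{phase_annotations}}) that tile the signal exactly.
#' @examples
#' sim <- simulate_fall(default_protocol())
#' sim$signal
#' sim$annotations
#' @export
simulate_fall <- function(protocol) {
  stopifnot(inherits(protocol, "fall_protocol"))
  rate <- protocol$sampling_rate_hz
  np <- length(protocol$phases)

  segments <- lapply(protocol$phases, simulate_phase, rate = rate)
  counts <- vapply(segments, nrow, integer(1L))
  data <- do.call(rbind, c(segments, list(matrix(numeric(0), 0L, 3L))))

  if (np > 0L && nrow(data) > 0L && protocol$noise_sd_g > 0) {
    with_preserved_rng({
      set.seed(protocol$seed)
      phase_seeds <- sample.int(.Machine$integer.max, np)
      noise <- do.call(rbind, lapply(seq_len(np), function(k) {
        if (counts[k] == 0L) return(matrix(numeric(0), 0L, 3L))
        set.seed(phase_seeds[k])
        matrix(stats::rnorm(3L * counts[k], sd = protocol$noise_sd_g),
               ncol = 3L)
      }))
      data <- data + noise
    })
  }
  if (!is.null(protocol$clip_range_g)) {
    c_ <- protocol$clip_range_g
    data <- pmin(pmax(data, -c_), c_)
  }

  ends <- cumsum(counts)
  starts <- c(0L, ends[-length(ends)])
  keep <- counts > 0L
  ann <- if (np > 0L && any(keep)) {
    phase_annotations(
      vapply(protocol$phases, `[[`, integer(1L), "label")[keep],
      starts[keep], ends[keep])
  } else {
    phase_annotations(integer(0), integer(0), integer(0))
  }

  colnames(data) <- c("x", "y", "z")
  structure(list(signal = new_accsignal(data, rate),
                 annotations = ann,
                 protocol = protocol),
            class = "fall_simulation")
}

#' @export
print.fall_simulation <- function(x, ...) {
  cat("Simulated fall recording\n")
  print(x$signal)
  cat(sprintf("  %d phase annotation(s): %s\n", nrow(x$annotations),
              paste(x$annotations$label, collapse = " ")))
  invisible(x)
}

#' @export
plot.fall_simulation <- function(x, ...) {
  plot(x$signal, main = "Simulated fall recording", ...)
  invisible(x)
}

# deterministic round-half-away-from-zero sample count
phase_sample_count <- function(duration_s, rate) {
  as.integer(floor(duration_s * rate + 0.5))
}

gravity_static <- function(pitch_deg) {
  th <- pitch_deg * pi / 180
  c(x = sin(th), y = 0, z = cos(th))
}

simulate_phase <- function(ph, rate) {
  n <- phase_sample_count(ph$duration_s, rate)
  m <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  if (n == 0L) return(m)
  t_ <- (seq_len(n) - 1) / rate
  p <- ph$params
  kind <- phase_kind(ph$label)

  if (kind == "steps") {
    a <- p$step_amplitude_g
    f <- p$step_frequency_hz
    m[, "z"] <- 1 + a * sin(2 * pi * f * t_)
    m[, "y"] <- (a / 4) * sin(2 * pi * (f / 2) * t_)
  } else if (kind == "rest") {
    g0 <- gravity_static(p$pitch_deg)
    m[, "x"] <- g0["x"]; m[, "z"] <- g0["z"]
  } else if (kind == "fall_impact") {
    n_ff <- min(n, phase_sample_count(p$freefall_duration_s, rate))
    n_imp <- min(n - n_ff, phase_sample_count(p$impact_duration_s, rate))
    u <- gravity_static(p$end_pitch_deg)
    if (n_ff > 0L) {
      # magnitude decays from 1 toward free fall, upright orientation
      mag <- 1 - (seq_len(n_ff) - 1) / n_ff
      m[seq_len(n_ff), "z"] <- mag
    }
    if (n_imp > 0L) {
      tau <- (seq_len(n_imp) - 1) / n_imp
      mag <- 1 + (p$impact_peak_g - 1) * sin(pi * tau)
      idx <- n_ff + seq_len(n_imp)
      m[idx, "x"] <- mag * u["x"]
      m[idx, "z"] <- mag * u["z"]
    }
    if (n_ff + n_imp < n) {
      idx <- (n_ff + n_imp + 1L):n
      m[idx, "x"] <- u["x"]; m[idx, "z"] <- u["z"]
    }
  } else {  # raise / stand
    uu <- if (n == 1L) 1 else (seq_len(n) - 1) / (n - 1)
    th <- (p$start_pitch_deg +
             (p$end_pitch_deg - p$start_pitch_deg) * (1 - cos(pi * uu)) / 2) *
      pi / 180
    m[, "x"] <- sin(th)
    m[, "z"] <- cos(th) +
      p$transient_amplitude_g * (1 - uu) * sin(2 * pi * 4 * t_)
  }
  m
}
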