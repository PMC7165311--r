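#' Phase specification
#'
#' One entry of a simulation protocol: a fall-event phase with its duration
#' and kinematic parameters. The phase label fixes the movement kind and the
#' parameters it requires:
#' \describe{
#'   \item{1 (steps)}{prefall walking: \code{step_frequency_hz},
#'     \code{step_amplitude_g}.}
#'   \item{2 (fall_impact)}{stumble, fall and impact:
#'     \code{freefall_duration_s}, \code{impact_peak_g},
#'     \code{impact_duration_s}, \code{end_pitch_deg}.}
#'   \item{3, 5 (rest)}{static posture: \code{pitch_deg}.}
#'   \item{4 (raise)}{raising the upper body: \code{start_pitch_deg},
#'     \code{end_pitch_deg}, \code{transient_amplitude_g}.}
#'   \item{6 (stand)}{straightening up into standing: same parameters as
#'     raise.}
#' }
#' Trunk pitch is in degrees, 0 = upright, 90 = horizontal forward bend,
#' restricted to [-180, 180].
#'
#' @param label integer phase code in 1..6.
#' @param duration_s non-negative phase duration in seconds.
#' @param ... the kinematic parameters required by the phase kind.
#' @return an object of class \code{phase_spec}.
#' @export
phase_spec <- function(label, duration_s, ...) {
  params <- list(...)
  validate_phase_spec(structure(
    list(label = as.integer(label), duration_s = as.numeric(duration_s),
         params = params),
    class = "phase_spec"))
}

phase_kind <- function(label) {
  switch(label, "steps", "fall_impact", "rest", "raise", "rest", "stand")
}

phase_required_params <- function(kind) {
  switch(kind,
    steps = c("step_frequency_hz", "step_amplitude_g"),
    fall_impact = c("freefall_duration_s", "impact_peak_g",
                    "impact_duration_s", "end_pitch_deg"),
    rest = "pitch_deg",
    raise = ,
    stand = c("start_pitch_deg", "end_pitch_deg", "transient_amplitude_g"))
}

validate_phase_spec <- function(ph) {
  if (!ph$label %in% 1:6) stop("unknown phase label: ", ph$label)
  if (!is.finite(ph$duration_s) || ph$duration_s < 0)
    stop("phase duration must be a non-negative number")
  kind <- phase_kind(ph$label)
  need <- phase_required_params(kind)
  miss <- setdiff(need, names(ph$params))
  if (length(miss))
    stop("phase ", ph$label, " (", kind, ") is missing parameter(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(ph$params), need)
  if (length(extra))
    stop("phase ", ph$label, " (", kind, ") has unknown parameter(s): ",
         paste(extra, collapse = ", "))
  for (p in need) {
    v <- ph$params[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("phase parameter ", p, " must be a single finite number")
  }
  for (p in grep("pitch_deg$", need, value = TRUE)) {
    if (abs(ph$params[[p]]) > 180)
      stop("pitch angles must lie in [-180, 180] degrees")
  }
  for (p in setdiff(need, c("end_pitch_deg", "start_pitch_deg", "pitch_deg"))) {
    if (ph$params[[p]] < 0)
      stop("phase parameter ", p, " must be non-negative")
  }
  ph
}

#' Simulation protocol
#'
#' An ordered list of fall-event phases plus the sensor settings used to
#' synthesize a recording: sampling rate, per-axis Gaussian noise, an
#' optional symmetric clipping range emulating the dynamic range of a
#' consumer accelerometer (e.g. 2 for a +/-2 g device) and the random seed.
#'
#' @param phases list of \code{\link{phase_spec}} objects, in order.
#' @param sampling_rate_hz positive sampling rate (default 100 Hz).
#' @param noise_sd_g non-negative noise standard deviation in g.
#' @param clip_range_g optional positive number c: samples are clipped to
#'   [-c, c]. \code{NULL} (default) disables clipping.
#' @param seed integer seed for the noise generator.
#' @return an object of class \code{fall_protocol}.
#' @seealso \code{\link{default_protocol}}, \code{\link{simulate_fall}}
#' @export
fall_protocol <- function(phases = list(), sampling_rate_hz = 100,
                          noise_sd_g = 0, clip_range_g = NULL, seed = 1L) {
  if (!is.list(phases)) stop("phases must be a list of phase_spec objects")
  phases <- lapply(phases, function(p) {
    if (!inherits(p, "phase_spec")) stop("each phase must be a phase_spec")
    validate_phase_spec(p)
  })
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (noise_sd_g < 0) stop("noise_sd_g must be non-negative")
  if (!is.null(clip_range_g) && clip_range_g <= 0)
    stop("clip_range_g must be positive (or NULL)")
  structure(list(phases = phases,
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 noise_sd_g = as.numeric(noise_sd_g),
                 clip_range_g = if (is.null(clip_range_g)) NULL else
                   as.numeric(clip_range_g),
                 seed = as.integer(seed)),
            class = "fall_protocol")
}

#' @export
print.fall_protocol <- function(x, ...) {
  cat(sprintf("Fall simulation protocol: %d phase(s), %g Hz, noise sd %g g%s, seed %d\n",
              length(x$phases), x$sampling_rate_hz, x$noise_sd_g,
              if (is.null(x$clip_range_g)) "" else
                sprintf(", clip +/-%g g", x$clip_range_g),
              x$seed))
  for (ph in x$phases) {
    pp <- paste(sprintf("%s=%g", names(ph$params), unlist(ph$params)),
                collapse = ", ")
    cat(sprintf("  phase %d (%-11s) %5.2f s  %s\n", ph$label,
                phase_kind(ph$label), ph$duration_s, pp))
  }
  invisible(x)
}

#' Default six-phase re-enactment protocol
#'
#' The packaged demonstration protocol follows the written third-iteration
#' instructions of a stumble-forward fall re-enactment: prefall steps; a
#' stumble and forward fall onto the knees; resting with the hands touching
#' the ground (1.5 s, inside the instructed 1-2 s window); sudden raising of
#' the upper body; 4 s of resting on the knees with the upper body upright;
#' and standing up. Durations for phases 3 and 5 come from those
#' instructions; the remaining durations and all amplitudes are package
#' defaults chosen to produce a plausible lower-back acceleration trace.
#'
#' @param noise_sd_g sensor noise standard deviation (default 0.02 g).
#' @param seed noise seed.
#' @return a \code{\link{fall_protocol}} with phases labeled 1..6.
#' @examples
#' default_protocol()
#' @export
default_protocol <- function(noise_sd_g = 0.02, seed = 20L) {
  fall_protocol(
    phases = list(
      phase_spec(1, 4.0, step_frequency_hz = 1.8, step_amplitude_g = 0.25),
      phase_spec(2, 1.5, freefall_duration_s = 0.3, impact_peak_g = 3,
                 impact_duration_s = 0.15, end_pitch_deg = 70),
      phase_spec(3, 1.5, pitch_deg = 70),
      phase_spec(4, 1.5, start_pitch_deg = 70, end_pitch_deg = 15,
                 transient_amplitude_g = 0.15),
      phase_spec(5, 4.0, pitch_deg = 15),
      phase_spec(6, 2.0, start_pitch_deg = 15, end_pitch_deg = 0,
                 transient_amplitude_g = 0.1)
    ),
    sampling_rate_hz = 100, noise_sd_g = noise_sd_g,
    clip_range_g = NULL, seed = seed)
}

#' Perturb a protocol
#'
#' Produces a variant of a protocol, emulating the between-trial variability
#' of successive re-enactment attempts: per-phase duration offsets are added
#' (durations of originally positive phases are clamped at 0.1 s, zero
#' phases at 0), and every amplitude/frequency parameter
#' (\code{step_frequency_hz}, \code{step_amplitude_g}, \code{impact_peak_g},
#' \code{transient_amplitude_g}) is multiplied by an independent factor
#' drawn uniformly from [1 - param_scale, 1 + param_scale]. With zero deltas
#' and \code{param_scale = 0} the protocol is returned unchanged. Pitch
#' angles and the freefall/impact sub-durations are never perturbed.
#'
#' @param protocol a \code{\link{fall_protocol}}.
#' @param duration_deltas_s numeric vector of per-phase duration offsets in
#'   seconds; length 1 (recycled) or one per phase.
#' @param param_scale non-negative half-width of the multiplicative
#'   perturbation.
#' @param seed integer seed for the perturbation draws.
#' @return a new \code{\link{fall_protocol}}.
#' @export
perturb_protocol <- function(protocol, duration_deltas_s = 0,
                             param_scale = 0, seed = 1L) {
  stopifnot(inherits(protocol, "fall_protocol"))
  np <- length(protocol$phases)
  if (length(duration_deltas_s) == 1L)
    duration_deltas_s <- rep(duration_deltas_s, np)
  if (length(duration_deltas_s) != np)
    stop("duration_deltas_s must have one entry per phase (", np, ")")
  if (param_scale < 0) stop("param_scale must be non-negative")
  scaled <- c("step_frequency_hz", "step_amplitude_g", "impact_peak_g",
              "transient_amplitude_g")
  out <- protocol
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (k in seq_len(np)) {
      ph <- protocol$phases[[k]]
      floor_s <- if (ph$duration_s > 0) 0.1 else 0
      ph$duration_s <- max(ph$duration_s + duration_deltas_s[k], floor_s)
      for (p in intersect(names(ph$params), scaled)) {
        ph$params[[p]] <- ph$params[[p]] *
          stats::runif(1L, 1 - param_scale, 1 + param_scale)
      }
      out$phases[[k]] <- validate_phase_spec(ph)
    }
  })
  out
}

# run code with the caller's .Random.seed restored afterwards
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  eval.parent(substitute(expr))
}

protocol_schema_keys <- list(
  top = c("phases", "sampling_rate_hz", "noise_sd_g", "clip_range_g", "seed"),
  phase = c("label", "duration_s"))

#' Read / write a simulation protocol as YAML
#'
#' The protocol config is a YAML mapping with keys \code{sampling_rate_hz},
#' \code{noise_sd_g}, optional \code{clip_range_g}, \code{seed}, and
#' \code{phases}: a sequence of mappings each carrying \code{label},
#' \code{duration_s} and the phase-kind parameters of
#' \code{\link{phase_spec}}. Unknown keys are rejected. A schema example
#' ships in \code{inst/extdata/demo_protocol.yaml}.
#'
#' @param path file path.
#' @param protocol a \code{\link{fall_protocol}}.
#' @return \code{load_protocol} returns a \code{\link{fall_protocol}};
#'   \code{save_protocol} returns \code{path} invisibly.
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("protocol file must be a YAML mapping")
  extra <- setdiff(names(raw), protocol_schema_keys$top)
  if (length(extra))
    stop("unknown protocol key(s): ", paste(extra, collapse = ", "))
  phases <- lapply(raw$phases, function(p) {
    if (!is.list(p) || is.null(p$label) || is.null(p$duration_s))
      stop("each phase entry needs 'label' and 'duration_s'")
    params <- p[setdiff(names(p), protocol_schema_keys$phase)]
    do.call(phase_spec, c(list(label = p$label, duration_s = p$duration_s),
                          params))
  })
  fall_protocol(phases = phases,
                sampling_rate_hz = raw$sampling_rate_hz %||% 100,
                noise_sd_g = raw$noise_sd_g %||% 0,
                clip_range_g = raw$clip_range_g,
                seed = raw$seed %||% 1L)
}

#' @rdname load_protocol
#' @export
save_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "fall_protocol"))
  obj <- list(
    sampling_rate_hz = protocol$sampling_rate_hz,
    noise_sd_g = protocol$noise_sd_g,
    seed = protocol$seed,
    phases = lapply(protocol$phases, function(ph)
      c(list(label = ph$label, duration_s = ph$duration_s), ph$params)))
  if (!is.null(protocol$clip_range_g))
    obj$clip_range_g <- protocol$clip_range_g
  writeLines(yaml::as.yaml(obj, precision = 17L), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
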