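#' Per-axis DTW comparison of a reference and a re-enacted signal
#'
#' Aligns each axis (x, y, z) of the reference recording (query) onto the
#' re-enacted recording (template) with \code{\link{align_axis}} and
#' returns the three normalized distances. Open begin and open end are on
#' by default, allowing the re-enacted recording to carry unmatched lead-in
#' and lead-out.
#'
#' @param reference,reenacted \code{\link{accsignal}} objects at the same
#'   sampling rate.
#' @param open_begin,open_end logical, default \code{TRUE}.
#' @return named numeric vector \code{c(x =, y =, z =)} of normalized
#'   distances.
#' @export
compare_axes <- function(reference, reenacted, open_begin = TRUE,
                         open_end = TRUE) {
  vapply(c(x = "x", y = "y", z = "z"), function(ax)
    align_axis(reference, reenacted, ax,
               open_begin = open_begin, open_end = open_end)$normalized_distance,
    numeric(1L))
}

#' Iteration report over successive re-enactments
#'
#' Reproduces the iterate-compare-adapt bookkeeping of the re-enactment
#' workflow: each re-enacted recording is compared per axis against the
#' reference, percent improvements are computed between consecutive
#' iterations, and the best iteration (lowest mean per-axis normalized
#' distance; earliest on ties) is flagged. The percent change from distance
#' a to distance b is \code{100 * (a - b) / a} (positive = improvement),
#' undefined (\code{NA}) when a = 0.
#'
#' @param reference the real-world reference \code{\link{accsignal}}.
#' @param reenactments non-empty list of re-enacted \code{accsignal}s, in
#'   iteration order (names, if any, become iteration ids).
#' @param open_begin,open_end passed to \code{\link{compare_axes}}.
#' @return An object of class \code{comparison_report}: a list with
#'   \code{iterations} (data.frame: iteration, x, y, z, mean),
#'   \code{improvements} (data.frame: iteration, x, y, z; percent change
#'   from the previous iteration; one row fewer) and
#'   \code{best_iteration}.
#' @export
iteration_report <- function(reference, reenactments, open_begin = TRUE,
                             open_end = TRUE) {
  if (!is.list(reenactments) || length(reenactments) == 0L)
    stop("reenactments must be a non-empty list of signals")
  ids <- names(reenactments)
  if (is.null(ids) || any(ids == ""))
    ids <- as.character(seq_along(reenactments))
  dist <- t(vapply(reenactments, compare_axes, numeric(3L),
                   reference = reference,
                   open_begin = open_begin, open_end = open_end))
  iterations <- data.frame(iteration = ids, x = dist[, "x"], y = dist[, "y"],
                           z = dist[, "z"], mean = rowMeans(dist),
                           row.names = NULL)
  k <- nrow(iterations)
  improvements <- if (k > 1L) {
    prev <- dist[-k, , drop = FALSE]
    cur <- dist[-1L, , drop = FALSE]
    imp <- 100 * (prev - cur) / prev
    imp[prev == 0] <- NA_real_
    data.frame(iteration = ids[-1L], x = imp[, "x"], y = imp[, "y"],
               z = imp[, "z"], row.names = NULL)
  } else {
    data.frame(iteration = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0))
  }
  structure(list(iterations = iterations, improvements = improvements,
                 best_iteration = ids[which.min(iterations$mean)]),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Re-enactment comparison report (normalized distances per axis)\n")
  print(format(x$iterations, digits = 4), row.names = FALSE)
  if (nrow(x$improvements)) {
    cat("Percent improvement over previous iteration:\n")
    print(format(x$improvements, digits = 4), row.names = FALSE)
  }
  cat("Best iteration:", x$best_iteration, "\n")
  invisible(x)
}

#' Per-phase signal summary
#'
#' Summarizes a signal over its phase annotations: duration and per-axis
#' minimum and maximum of each annotated phase, the quantities the
#' phase-by-phase comparison of real and re-enacted recordings reasons
#' about.
#'
#' @param signal an \code{\link{accsignal}}.
#' @param annotations a phase-annotation data.frame
#'   (\code{\link{phase_annotations}}) valid for the signal.
#' @return data.frame with columns \code{label}, \code{duration_s},
#'   \code{x_min}, \code{x_max}, \code{y_min}, \code{y_max}, \code{z_min},
#'   \code{z_max}.
#' @export
phase_summary <- function(signal, annotations) {
  stopifnot(inherits(signal, "accsignal"))
  validate_annotations(annotations, n_samples = nrow(signal$data))
  rows <- lapply(seq_len(nrow(annotations)), function(k) {
    a <- annotations[k, ]
    span <- (a$start_index + 1L):a$end_index
    seg <- signal$data[span, , drop = FALSE]
    data.frame(label = a$label,
               duration_s = (a$end_index - a$start_index) / signal$sampling_rate_hz,
               x_min = min(seg[, "x"]), x_max = max(seg[, "x"]),
               y_min = min(seg[, "y"]), y_max = max(seg[, "y"]),
               z_min = min(seg[, "z"]), z_max = max(seg[, "z"]))
  })
  if (!length(rows))
    return(data.frame(label = integer(0), duration_s = numeric(0),
                      x_min = numeric(0), x_max = numeric(0),
                      y_min = numeric(0), y_max = numeric(0),
                      z_min = numeric(0), z_max = numeric(0)))
  do.call(rbind, rows)
}

#' Transfer phase annotations through a warping path
#'
#' Maps phase boundaries from one side of an alignment to the other, linking
#' the movement sequences of the two recordings: a start boundary maps
#' through the first warping-path pair that matches it, an end boundary
#' through the last. Boundaries that fall outside the matched template range
#' (possible with open begin/end) raise an error naming the offending
#' annotation.
#'
#' @param annotations phase annotations indexed on the source side.
#' @param result a \code{dtw_alignment}.
#' @param direction \code{"query_to_template"} or
#'   \code{"template_to_query"}.
#' @return phase annotations indexed on the destination side; sorted,
#'   non-overlapping and in-bounds.
#' @export
transfer_phases <- function(annotations, result,
                            direction = c("query_to_template",
                                          "template_to_query")) {
  stopifnot(inherits(result, "dtw_alignment"))
  direction <- match.arg(direction)
  validate_annotations(annotations)
  if (nrow(annotations) == 0L) return(annotations)
  src_col <- if (direction == "query_to_template") "query_index" else "template_index"
  dst_col <- if (direction == "query_to_template") "template_index" else "query_index"
  src <- result$path[, src_col]
  dst <- result$path[, dst_col]
  map_boundary <- function(idx, last) {
    hits <- which(src == idx)
    if (!length(hits))
      stop("annotation boundary at source index ", idx,
           " lies outside the matched range of the alignment")
    dst[if (last) hits[length(hits)] else hits[1L]]
  }
  out <- annotations
  out$start_index <- vapply(annotations$start_index, map_boundary,
                            integer(1L), last = FALSE)
  out$end_index <- vapply(annotations$end_index - 1L, map_boundary,
                          integer(1L), last = TRUE) + 1L
  # where a multi-cell rule stalls the destination axis, the mapped end of
  # one phase can poke one sample into the next phase's mapped start; clip
  # so a tiling stays a tiling
  k <- nrow(out)
  if (k > 1L)
    out$end_index[-k] <- pmin(out$end_index[-k], out$start_index[-1L])
  validate_annotations(out)
  out
}

#' Re-enactment convergence study
#'
#' The package's restatement of the central claim of iterative
#' re-enactment: as a re-enactment protocol is perturbed less and less from
#' the reference protocol, its simulated recording grows more similar to
#' the reference recording. For each perturbation scale, \code{n_reps}
#' perturbed protocols are drawn (durations jittered by up to
#' \code{2 * scale} seconds per phase, amplitude/frequency parameters
#' scaled by \code{1 +/- scale}, independent noise seeds), simulated, and
#' compared per axis against the fixed reference simulation.
#'
#' @param protocol the reference \code{\link{fall_protocol}} (default
#'   \code{\link{default_protocol}()}).
#' @param scales decreasing perturbation scales to probe.
#' @param n_reps simulated re-enactments per scale.
#' @param seed master seed; all draws derive from it.
#' @param open_begin,open_end passed to \code{\link{compare_axes}}.
#' @return data.frame with columns \code{scale}, \code{rep}, \code{x},
#'   \code{y}, \code{z} of normalized distances; aggregate with
#'   \code{aggregate(cbind(x, y, z) ~ scale, d, mean)}.
#' @export
reenactment_convergence <- function(protocol = default_protocol(),
                                    scales = c(0.5, 0.2, 0.05),
                                    n_reps = 20L, seed = 1L,
                                    open_begin = TRUE, open_end = TRUE) {
  reference <- simulate_fall(protocol)$signal
  np <- length(protocol$phases)
  draws <- NULL
  with_preserved_rng({
    set.seed(as.integer(seed))
    draws <- lapply(seq_len(length(scales) * n_reps), function(i)
      list(deltas = stats::runif(np, -1, 1),
           sub_seed = sample.int(.Machine$integer.max, 2L)))
  })
  rows <- list()
  i <- 0L
  for (s in scales) for (r in seq_len(n_reps)) {
    i <- i + 1L
    dr <- draws[[i]]
    pert <- perturb_protocol(protocol,
                             duration_deltas_s = dr$deltas * 2 * s,
                             param_scale = s, seed = dr$sub_seed[1L])
    pert$seed <- dr$sub_seed[2L]
    d <- compare_axes(reference, simulate_fall(pert)$signal,
                      open_begin = open_begin, open_end = open_end)
    rows[[i]] <- data.frame(scale = s, rep = r, x = d["x"], y = d["y"],
                            z = d["z"], row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Export a comparison report as JSON
#'
#' @param report a \code{comparison_report}.
#' @param path output file, or \code{NULL} to return the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  obj <- list(iterations = report$iterations,
              improvements = report$improvements,
              best_iteration = report$best_iteration)
  if (is.null(path))
    return(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, na = "null"))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
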