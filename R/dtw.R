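#' Slope-constrained dynamic time warping
#'
#' Aligns a query series onto a template by dynamic programming under a
#' slope-constrained asymmetric step pattern (default
#' \code{\link{asymmetric_p1}}), optionally with open begin and/or open end.
#' The query is the reference recording (every query sample must be
#' matched); the template is the re-enacted recording, whose time axis is
#' stretched onto the query's. With \code{open_begin} the alignment may
#' start at any template sample (the unmatched template prefix costs
#' nothing); with \code{open_end} it may stop at any template sample. The
#' local cost of matching query sample i to template sample j is the
#' Euclidean distance between them (absolute difference for univariate
#' series). The similarity score is the \emph{normalized distance}: the
#' optimal cumulative weighted cost divided by the number of samples in the
#' query.
#'
#' The dynamic-programming table g satisfies \code{g(1, 1) = d(1, 1)}
#' (closed begin) or \code{g(1, j) = d(1, j)} for every j (open begin), with
#' transitions given by the pattern's rules; a rule that would reference a
#' cell outside the table is inadmissible. The final cumulative distance is
#' \code{g(N, M)} for a closed end, or the minimum of \code{g(N, j)} over j
#' for an open end (earliest j on ties). The slope constraints can make an
#' alignment infeasible (for asymmetricP1, a closed-end alignment needs
#' \code{(N-1)/2 + 1 <= M <= 2(N-1) + 1}); this raises an error of class
#' \code{fallwarp_infeasible_error} naming both lengths.
#'
#' @param query numeric vector (or matrix, one column per channel, for
#'   multivariate alignment) of length >= 2; the reference series.
#' @param template numeric vector (or matrix with the same number of
#'   columns) of length >= 2; the series whose time axis is warped.
#' @param pattern a \code{\link{step_pattern}}; default
#'   \code{\link{asymmetric_p1}}.
#' @param open_begin,open_end logical; free the template prefix/suffix.
#' @return An object of class \code{dtw_alignment}: a list with
#'   \code{cumulative_distance}, \code{normalized_distance}, \code{path}
#'   (two-column integer matrix of 0-based \code{query_index},
#'   \code{template_index} pairs, including the intermediate cells of
#'   multi-cell rules), \code{template_match_start} /
#'   \code{template_match_end} (0-based inclusive matched template range),
#'   \code{step_pattern_id}, \code{open_begin}, \code{open_end},
#'   \code{query_length}, \code{template_length}, and the two input series.
#' @examples
#' a <- dtw_align(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0))
#' a$normalized_distance  # 0: identical series
#' @export
dtw_align <- function(query, template, pattern = asymmetric_p1(),
                      open_begin = FALSE, open_end = FALSE) {
  stopifnot(inherits(pattern, "step_pattern"))
  q <- if (is.matrix(query)) query else matrix(as.numeric(query), ncol = 1L)
  t_ <- if (is.matrix(template)) template else matrix(as.numeric(template), ncol = 1L)
  if (ncol(q) != ncol(t_))
    stop("query and template must have the same number of channels")
  n <- nrow(q); m <- nrow(t_)
  if (n < 2L || m < 2L)
    stop("query and template must each have at least 2 samples")
  if (!all(is.finite(q)) || !all(is.finite(t_)))
    stop("series values must be finite")

  D <- local_cost_matrix(q, t_)
  dp <- dtw_dp(D, pattern, open_begin, open_end)
  path1 <- dtw_backtrack(dp$choice, pattern, dp$end_j)

  cumulative <- dp$cumulative
  structure(list(
    cumulative_distance = cumulative,
    normalized_distance = normalized_distance(cumulative, n),
    path = cbind(query_index = path1[, 1L] - 1L,
                 template_index = path1[, 2L] - 1L),
    template_match_start = path1[1L, 2L] - 1L,
    template_match_end = dp$end_j - 1L,
    step_pattern_id = pattern$pattern_id,
    open_begin = open_begin,
    open_end = open_end,
    query_length = n,
    template_length = m,
    query = query,
    template = template
  ), class = "dtw_alignment")
}

# n x m matrix of local Euclidean costs (absolute difference when univariate)
local_cost_matrix <- function(q, t_) {
  if (ncol(q) == 1L) return(abs(outer(q[, 1L], t_[, 1L], "-")))
  acc <- 0
  for (k in seq_len(ncol(q)))
    acc <- acc + outer(q[, k], t_[, k], "-")^2
  sqrt(acc)
}

# Vectorized DP over the template axis: each row of the cumulative-cost
# table depends only on earlier rows, so rules evaluate as shifted vector
# sums. Returns the rule-choice table for backtracking.
dtw_dp <- function(D, pattern, open_begin, open_end) {
  n <- nrow(D); m <- ncol(D)
  shiftv <- function(v, dt) {
    if (dt == 0L) v
    else if (-dt >= m) rep(Inf, m)
    else c(rep(Inf, -dt), v[seq_len(m + dt)])
  }
  G <- matrix(Inf, n, m)
  choice <- matrix(0L, n, m)
  if (open_begin) G[1L, ] <- D[1L, ] else G[1L, 1L] <- D[1L, 1L]

  rules <- pattern$rules
  pref <- rule_preference(pattern)
  for (i in 2:n) {
    costs <- vector("list", length(rules))
    for (r in seq_along(rules)) {
      rule <- rules[[r]]
      i_start <- i + rule[1L, "dq"]
      if (i_start < 1L) { costs[[r]] <- rep(Inf, m); next }
      cost <- shiftv(G[i_start, ], rule[1L, "dt"])
      for (k in 2:nrow(rule)) {
        w <- rule[k, "w"]
        if (w == 0) next
        cost <- cost + w * shiftv(D[i + rule[k, "dq"], ], rule[k, "dt"])
      }
      costs[[r]] <- cost
    }
    cmin <- do.call(pmin, costs)
    ch <- integer(m)
    for (r in pref) {
      hit <- costs[[r]] == cmin & ch == 0L & is.finite(cmin)
      ch[hit] <- r
    }
    G[i, ] <- cmin
    choice[i, ] <- ch
  }

  if (open_end) {
    end_j <- which.min(G[n, ])  # earliest on ties
    cumulative <- G[n, end_j]
  } else {
    end_j <- m
    cumulative <- G[n, m]
  }
  if (!is.finite(cumulative))
    stop(structure(class = c("fallwarp_infeasible_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("no admissible warping path for query length %d ",
                            "and template length %d under pattern '%s'",
                            " (open_begin=%s, open_end=%s)"),
                     n, m, pattern$pattern_id, open_begin, open_end),
                     call = NULL)))
  list(cumulative = cumulative, end_j = end_j, choice = choice)
}

# Recover the optimal path (1-based (i, j) pairs, increasing), emitting every
# chain cell of every applied rule; the start cell of each rule is the end
# cell of its predecessor.
dtw_backtrack <- function(choice, pattern, end_j) {
  n <- nrow(choice)
  rules <- pattern$rules
  cells <- list()
  i <- n; j <- end_j
  while (choice[i, j] != 0L) {
    rule <- unname(rules[[choice[i, j]]])
    for (k in nrow(rule):2) {
      cells[[length(cells) + 1L]] <- c(i + rule[k, 1L], j + rule[k, 2L])
    }
    i <- i + rule[1L, 1L]
    j <- j + rule[1L, 2L]
  }
  cells[[length(cells) + 1L]] <- c(i, j)
  path <- do.call(rbind, rev(cells))
  dimnames(path) <- NULL
  storage.mode(path) <- "integer"
  path
}

#' Normalized DTW distance
#'
#' The cumulative weighted distance divided by the number of samples in the
#' query. Under asymmetric step patterns the path weights sum to the query
#' length, so this is a weighted mean local cost per query sample.
#'
#' @param cumulative non-negative cumulative distance.
#' @param query_length positive number of query samples.
#' @return \code{cumulative / query_length}.
#' @export
normalized_distance <- function(cumulative, query_length) {
  if (query_length < 1) stop("query_length must be positive")
  cumulative / query_length
}

#' Align one axis of two triaxial signals
#'
#' Extracts the named axis from the query (reference) and template
#' (re-enacted) signals and aligns them with \code{\link{dtw_align}} under
#' the asymmetricP1 pattern. Both signals must share one sampling rate;
#' resample first (\code{\link{resample_signal}}) if they do not.
#'
#' @param query_signal,template_signal \code{\link{accsignal}} objects with
#'   equal sampling rates.
#' @param axis one of \code{"x"}, \code{"y"}, \code{"z"}.
#' @param open_begin,open_end passed to \code{\link{dtw_align}}.
#' @return a \code{dtw_alignment}.
#' @export
align_axis <- function(query_signal, template_signal, axis = "z",
                       open_begin = FALSE, open_end = FALSE) {
  stopifnot(inherits(query_signal, "accsignal"),
            inherits(template_signal, "accsignal"))
  axis <- match.arg(axis, c("x", "y", "z"))
  if (query_signal$sampling_rate_hz != template_signal$sampling_rate_hz)
    stop("signals have different sampling rates (",
         query_signal$sampling_rate_hz, " vs ",
         template_signal$sampling_rate_hz, " Hz); resample first")
  dtw_align(query_signal$data[, axis], template_signal$data[, axis],
            asymmetric_p1(), open_begin = open_begin, open_end = open_end)
}

#' Warp a template onto the query time axis
#'
#' Produces a series on the query's time axis by repeating each template
#' sample as many times as the warping path dictates: query index i receives
#' the template sample at the largest template index paired with i in the
#' path. The output always has exactly \code{query_length} samples.
#'
#' @param template the template series the alignment was computed from.
#' @param result a \code{dtw_alignment}.
#' @return numeric vector of length \code{result$query_length}.
#' @export
warp_template <- function(template, result) {
  stopifnot(inherits(result, "dtw_alignment"))
  tv <- if (is.matrix(template)) template[, 1L] else as.numeric(template)
  path <- result$path
  if (max(path[, "template_index"]) + 1L > length(tv))
    stop("warping path is inconsistent with the template length")
  # path is sorted by construction; for each query index keep the last
  # (largest) template index
  idx <- vapply(split(path[, "template_index"], path[, "query_index"]),
                max, integer(1L))
  tv[idx + 1L]
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("DTW alignment (pattern %s, open begin: %s, open end: %s)\n",
              x$step_pattern_id, x$open_begin, x$open_end))
  cat(sprintf("  query %d samples -> template %d samples (matched range %d..%d)\n",
              x$query_length, x$template_length,
              x$template_match_start, x$template_match_end))
  cat(sprintf("  cumulative distance: %.6g\n  normalized distance: %.6g\n",
              x$cumulative_distance, x$normalized_distance))
  invisible(x)
}

#' @export
summary.dtw_alignment <- function(object, ...) {
  out <- list(
    step_pattern_id = object$step_pattern_id,
    open_begin = object$open_begin,
    open_end = object$open_end,
    query_length = object$query_length,
    template_length = object$template_length,
    template_match_start = object$template_match_start,
    template_match_end = object$template_match_end,
    path_length = nrow(object$path),
    cumulative_distance = object$cumulative_distance,
    normalized_distance = object$normalized_distance)
  class(out) <- "summary.dtw_alignment"
  out
}

#' @export
print.summary.dtw_alignment <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Plot a DTW alignment
#'
#' Two panels: the warping path (template index against query index), and
#' the query overlaid with the template warped onto the query's time axis.
#'
#' @param x a \code{dtw_alignment}.
#' @param ... passed to the line plots.
#' @export
plot.dtw_alignment <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$path[, "query_index"], x$path[, "template_index"],
                 type = "l", xlab = "query index", ylab = "template index",
                 main = "Warping path", ...)
  qv <- if (is.matrix(x$query)) x$query[, 1L] else x$query
  wt <- warp_template(x$template, x)
  graphics::matplot(cbind(qv, wt), type = "l", lty = c(1, 2),
                    col = c("black", "red3"), xlab = "query index",
                    ylab = "value",
                    main = "Query (solid) vs warped template (dashed)")
  invisible(x)
}

#' Export an alignment
#'
#' \code{write_alignment_json} writes the distances, flags and matched range
#' as JSON; \code{write_path_csv} writes the warping path as a two-column
#' CSV of 0-based \code{query_index,template_index} pairs.
#'
#' @param result a \code{dtw_alignment}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_alignment_json <- function(result, path) {
  stopifnot(inherits(result, "dtw_alignment"))
  fields <- result[c("cumulative_distance", "normalized_distance",
                     "template_match_start", "template_match_end",
                     "step_pattern_id", "open_begin", "open_end",
                     "query_length", "template_length")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_alignment_json
#' @export
write_path_csv <- function(result, path) {
  stopifnot(inherits(result, "dtw_alignment"))
  utils::write.csv(as.data.frame(result$path), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
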