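#' Phase annotations
#'
#' A phase annotation labels a contiguous stretch of a signal with one of the
#' six fall-event phases: 1 prefall steps, 2 stumbling/falling/impact,
#' 3 resting, 4 raising the upper body, 5 resting, 6 straightening up into
#' standing. Indices are 0-based and half-open: an annotation covers samples
#' \code{start_index} to \code{end_index - 1}.
#'
#' @param label integer vector of phase codes in 1..6.
#' @param start_index,end_index integer vectors; 0-based half-open sample
#'   ranges.
#' @return a \code{data.frame} with columns \code{label},
#'   \code{start_index}, \code{end_index}.
#' @export
phase_annotations <- function(label, start_index, end_index) {
  ann <- data.frame(label = as.integer(label),
                    start_index = as.integer(start_index),
                    end_index = as.integer(end_index))
  validate_annotations(ann)
  ann
}

#' Validate a phase-annotation table against a signal
#'
#' Checks phase codes, index bounds, ordering and non-overlap. Called by
#' every consumer of annotations; exported so callers can validate
#' hand-built tables.
#'
#' @param annotations a data.frame as returned by
#'   \code{\link{phase_annotations}}.
#' @param n_samples optional signal length; when given, annotations must lie
#'   within \code{[0, n_samples]}.
#' @return the annotations, invisibly.
#' @export
validate_annotations <- function(annotations, n_samples = NULL) {
  need <- c("label", "start_index", "end_index")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations)))
    stop("annotations must be a data.frame with columns label, start_index, end_index")
  if (nrow(annotations) == 0L) return(invisible(annotations))
  with(annotations, {
    if (!all(label %in% 1:6)) stop("phase labels must be integers in 1..6")
    if (any(start_index < 0L)) stop("start_index must be >= 0")
    if (any(end_index <= start_index)) stop("annotations must satisfy start_index < end_index")
  })
  if (nrow(annotations) > 1L) {
    s <- annotations$start_index[-1L]
    e <- annotations$end_index[-nrow(annotations)]
    if (any(s < e)) stop("annotations must be sorted and non-overlapping")
  }
  if (!is.null(n_samples) && any(annotations$end_index > n_samples))
    stop("annotation exceeds signal length (", n_samples, " samples)")
  invisible(annotations)
}

#' Write / read phase annotations as CSV
#'
#' Plain CSV with columns \code{label,start_index,end_index} (0-based,
#' half-open).
#'
#' @param annotations annotation data.frame.
#' @param path file path.
#' @return \code{path} (write) or the annotation data.frame (read).
#' @export
write_annotations_csv <- function(annotations, path) {
  validate_annotations(annotations)
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.csv(path)
  phase_annotations(ann$label, ann$start_index, ann$end_index)
}
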