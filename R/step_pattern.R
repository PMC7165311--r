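#' Step patterns for slope-constrained dynamic time warping
#'
#' A step pattern is the set of admissible local transitions of the DTW
#' recursion. Each rule is a chain of cells ending at the cell being
#' computed, given as offsets \code{(query_offset, template_offset, weight)}
#' measured backward from the end cell; the chain's first cell is the rule's
#' start and carries no weight (its cost is already accumulated). Patterns of
#' the asymmetric family advance the query index by at least one on every
#' rule and normalize the cumulative distance by the query length, so the
#' normalized distance is a weighted mean local cost per query sample.
#'
#' @param pattern_id name of the pattern.
#' @param rules list of numeric matrices, one per rule, with columns
#'   \code{dq}, \code{dt}, \code{w}; rows ordered from the start cell (weight
#'   \code{NA}) to the end cell (offsets \code{0, 0}).
#' @param normalization_kind currently only \code{"query_length"}.
#' @return an object of class \code{step_pattern}.
#' @seealso \code{\link{asymmetric_p1}}
#' @export
step_pattern <- function(pattern_id, rules,
                         normalization_kind = "query_length") {
  normalization_kind <- match.arg(normalization_kind)
  if (!length(rules)) stop("a step pattern needs at least one rule")
  rules <- lapply(rules, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 3L) stop("each rule must have columns dq, dt, w")
    colnames(r) <- c("dq", "dt", "w")
    if (any(r[nrow(r), c("dq", "dt")] != 0))
      stop("each rule must end at offset (0, 0)")
    if (!is.na(r[1L, "w"]))
      stop("the start cell of a rule carries no weight (use NA)")
    if (nrow(r) > 1L && anyNA(r[-1L, "w"]))
      stop("chain cells must carry weights")
    adv_q <- -r[1L, "dq"]
    adv_t <- -r[1L, "dt"]
    if (adv_q < 1) stop("asymmetric rules must advance the query index")
    if (adv_t < 0) stop("rules must not move backward along the template")
    w <- r[-1L, "w"]
    if (any(w < 0)) stop("weights must be non-negative")
    if (abs(sum(w) - adv_q) > 1e-12)
      stop("rule weights must sum to the rule's query advance")
    r
  })
  structure(list(pattern_id = pattern_id, rules = rules,
                 normalization_kind = normalization_kind),
            class = "step_pattern")
}

#' @export
print.step_pattern <- function(x, ...) {
  cat(sprintf("Step pattern '%s' (%d rules, normalization: %s)\n",
              x$pattern_id, length(x$rules), x$normalization_kind))
  for (k in seq_along(x$rules)) {
    r <- x$rules[[k]]
    cells <- apply(r, 1L, function(row)
      sprintf("(i%+d, j%+d)%s", row["dq"], row["dt"],
              if (is.na(row["w"])) "" else sprintf(" w=%g", row["w"])))
    cat(sprintf("  rule %d: %s\n", k, paste(cells, collapse = " -> ")))
  }
  invisible(x)
}

#' The Sakoe-Chiba asymmetricP1 step pattern
#'
#' The asymmetric slope-constrained step pattern with slope parameter P = 1:
#' three production rules ending at cell (i, j),
#' \describe{
#'   \item{flat}{start (i-1, j-2), through (i, j-1) weight 0.5, end (i, j)
#'     weight 0.5 — local slope 1/2;}
#'   \item{diagonal}{start (i-1, j-1), end (i, j) weight 1 — slope 1;}
#'   \item{steep}{start (i-2, j-1), through (i-1, j) weight 1, end (i, j)
#'     weight 1 — slope 2.}
#' }
#' Every rule advances the query by its weight sum, so the cumulative
#' distance is normalized by the query length. P = 1 confines the local
#' warping slope to the interval [1/2, 2].
#'
#' @return a \code{\link{step_pattern}}.
#' @examples
#' asymmetric_p1()
#' @export
asymmetric_p1 <- function() {
  step_pattern("asymmetricP1", list(
    flat     = rbind(c(-1, -2, NA), c(0, -1, 0.5), c(0, 0, 0.5)),
    diagonal = rbind(c(-1, -1, NA), c(0, 0, 1)),
    steep    = rbind(c(-2, -1, NA), c(-1, 0, 1), c(0, 0, 1))
  ))
}

# DP evaluation order: ties in the cell-wise argmin are broken by preferring
# the diagonal rule, then the flat rule, then the steep rule, so recovered
# paths are deterministic.
rule_preference <- function(pattern) {
  if (pattern$pattern_id == "asymmetricP1") c(2L, 1L, 3L) else
    seq_along(pattern$rules)
}
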