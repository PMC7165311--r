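# Test oracles, kept deliberately independent of the package's vectorized
# dynamic program.
#
# enum_dtw(): exhaustive enumeration of every admissible warping path for the
# asymmetricP1 rules, hard-coded forward: from cell (i, j),
#   flat:     weighted cells (i+1, j+1, 0.5), (i+1, j+2, 0.5) -> (i+1, j+2)
#   diagonal: weighted cell  (i+1, j+1, 1)                    -> (i+1, j+1)
#   steep:    weighted cells (i+1, j, 1), (i+2, j+1, 1)       -> (i+2, j+1)
# A path starts at (1, 1) (or (1, j0) for any j0 when open-begin) with the
# start cell weighted 1, and ends at row N in column M (or any column when
# open-end). Path sets depend only on the shape (N, M) and the open flags, so
# they are enumerated once per shape and stored as a weight matrix W (paths x
# N*M cells); a pair's path costs are then W %*% vec(|q_i - t_j|).

.oracle_cache <- new.env(parent = emptyenv())

enum_path_weights <- function(n, m, open_begin, open_end) {
  key <- paste(n, m, open_begin, open_end, sep = "_")
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  paths <- list()
  walk <- function(i, j, cells) {
    if (i == n) {
      if (open_end || j == m) paths[[length(paths) + 1L]] <<- cells
      return(invisible(NULL))
    }
    if (j + 1L <= m)  # diagonal
      walk(i + 1L, j + 1L, rbind(cells, c(i + 1L, j + 1L, 1)))
    if (j + 2L <= m)  # flat (slope 1/2)
      walk(i + 1L, j + 2L, rbind(cells, c(i + 1L, j + 1L, 0.5),
                                 c(i + 1L, j + 2L, 0.5)))
    if (i + 2L <= n && j + 1L <= m)  # steep (slope 2)
      walk(i + 2L, j + 1L, rbind(cells, c(i + 1L, j + 1L, 1),
                                 c(i + 2L, j + 1L, 1)))
  }
  starts <- if (open_begin) seq_len(m) else 1L
  for (j0 in starts) walk(1L, j0, matrix(c(1L, j0, 1), 1L, 3L))
  W <- matrix(0, length(paths), n * m)
  for (p in seq_along(paths)) {
    cc <- paths[[p]]
    idx <- (cc[, 2L] - 1L) * n + cc[, 1L]
    for (r in seq_len(nrow(cc))) W[p, idx[r]] <- W[p, idx[r]] + cc[r, 3L]
  }
  .oracle_cache[[key]] <- W
  W
}

# minimum cumulative cost over all enumerated paths; NA when no path exists
enum_dtw <- function(query, template, open_begin = FALSE, open_end = FALSE) {
  n <- length(query); m <- length(template)
  W <- enum_path_weights(n, m, open_begin, open_end)
  if (nrow(W) == 0L) return(list(cumulative = NA_real_, n_paths = 0L))
  D <- abs(outer(query, template, "-"))
  costs <- as.vector(W %*% as.vector(D))
  list(cumulative = min(costs), n_paths = nrow(W),
       weight_sums = rowSums(W))
}

# Independent reference implementation: plain scalar double loop over the
# cumulative-cost table, coded directly from the recurrence (no shared code
# with the package's row-vectorized version). Used to cross-check distances
# on series too long for exhaustive enumeration.
ref_dtw <- function(q, t_, open_begin = FALSE, open_end = FALSE) {
  n <- length(q); m <- length(t_)
  d <- function(i, j) abs(q[i] - t_[j])
  f <- matrix(Inf, n, m)
  if (open_begin) for (j in 1:m) f[1, j] <- d(1, j) else f[1, 1] <- d(1, 1)
  for (i in 2:n) for (j in 1:m) {
    best <- Inf
    if (j >= 2 && is.finite(f[i - 1, j - 1]))
      best <- min(best, f[i - 1, j - 1] + d(i, j))
    if (j >= 3 && is.finite(f[i - 1, j - 2]))
      best <- min(best, f[i - 1, j - 2] + 0.5 * d(i, j - 1) + 0.5 * d(i, j))
    if (i >= 3 && j >= 2 && is.finite(f[i - 2, j - 1]))
      best <- min(best, f[i - 2, j - 1] + d(i - 1, j) + d(i, j))
    f[i, j] <- best
  }
  cum <- if (open_end) min(f[n, ]) else f[n, m]
  list(cumulative = cum, normalized = cum / n)
}

# random test series over a small alphabet (criterion: values in {0, 1, 2})
rand_series <- function(n, alphabet = 0:2) {
  sample(alphabet, n, replace = TRUE)
}

# warping-path sanity: monotone, covers every query index, increments
# restricted to the three admissible cell-to-cell moves
expect_valid_path <- function(al) {
  path <- al$path
  dq <- diff(path[, "query_index"])
  dt <- diff(path[, "template_index"])
  expect_true(all(dq >= 0) && all(dt >= 0))
  moves <- paste(dq, dt)
  expect_true(all(moves %in% c("1 1", "0 1", "1 0")))
  expect_identical(sort(unique(path[, "query_index"])),
                   0:(al$query_length - 1L))
}
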