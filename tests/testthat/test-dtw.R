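test_that("aligning a series with itself gives zero distance on the diagonal", {
  set.seed(11)
  for (n in c(2L, 5L, 40L)) {
    s <- rnorm(n)
    a <- dtw_align(s, s)
    expect_equal(a$cumulative_distance, 0)
    expect_equal(a$normalized_distance, 0)
    expect_identical(a$path,
                     cbind(query_index = 0:(n - 1L),
                           template_index = 0:(n - 1L)))
    expect_identical(a$template_match_start, 0L)
    expect_identical(a$template_match_end, n - 1L)
  }
})

test_that("the closed-end optimum matches the pre-computed enumeration value", {
  # exhaustive enumeration for query (0,1,2) vs template (0,2): single
  # admissible path (1,1) -steep-> (2,2),(3,2) with cost 0 + 1 + 0 = 1
  a <- dtw_align(c(0, 1, 2), c(0, 2))
  expect_equal(a$cumulative_distance, 1)
  expect_equal(a$normalized_distance, 1 / 3)
  expect_identical(a$path, cbind(query_index = c(0L, 1L, 2L),
                                 template_index = c(0L, 1L, 1L)))
})

test_that("open end leaves the trailing template unmatched at zero cost", {
  a <- dtw_align(c(5, 5), c(5, 5, 9, 9), open_end = TRUE)
  expect_equal(a$cumulative_distance, 0)
  expect_identical(a$template_match_end, 1L)
  expect_identical(a$template_match_start, 0L)
})

test_that("open begin skips a template prefix at zero cost", {
  a <- dtw_align(c(7, 8), c(0, 0, 7, 8), open_begin = TRUE)
  expect_equal(a$cumulative_distance, 0)
  expect_identical(a$template_match_start, 2L)
})

test_that("distances are shift-invariant and scale linearly", {
  set.seed(5)
  for (rep in 1:10) {
    q <- rand_series(sample(4:30, 1))
    t_ <- rand_series(max(2L, length(q) + sample(-2:2, 1)))
    base <- tryCatch(dtw_align(q, t_, open_end = TRUE),
                     fallwarp_infeasible_error = function(e) NULL)
    if (is.null(base)) next
    shifted <- dtw_align(q + 3.7, t_ + 3.7, open_end = TRUE)
    scaled <- dtw_align(2.5 * q, 2.5 * t_, open_end = TRUE)
    expect_equal(shifted$cumulative_distance, base$cumulative_distance,
                 tolerance = 1e-9)
    expect_equal(scaled$cumulative_distance, 2.5 * base$cumulative_distance,
                 tolerance = 1e-9)
    expect_valid_path(base)
  }
})

test_that("a template stretched by integer repetition aligns at distance 0", {
  set.seed(9)
  s <- cumsum(rnorm(12))
  # the open begin lets the path enter at the second copy of each repeated
  # element, after which the flat rule tracks the doubling at zero cost
  a <- dtw_align(s, rep(s, each = 2), open_begin = TRUE, open_end = TRUE)
  expect_equal(a$normalized_distance, 0)
})

test_that("infeasible alignments raise a typed error naming both lengths", {
  err <- expect_error(dtw_align(rep(0, 10), rep(0, 30)),
                      class = "fallwarp_infeasible_error")
  expect_match(conditionMessage(err), "10")
  expect_match(conditionMessage(err), "30")
  # template too short for the query under slope >= 1/2
  expect_error(dtw_align(rep(0, 10), rep(0, 3)),
               class = "fallwarp_infeasible_error")
  # open end relaxes the upper bound on the template length
  expect_silent(dtw_align(rep(0, 10), rep(0, 30), open_end = TRUE))
  expect_error(dtw_align(1, 1:3), "at least 2")
})

test_that("multivariate alignment uses the per-sample Euclidean distance", {
  set.seed(21)
  q <- matrix(rnorm(30), ncol = 3)
  a3 <- dtw_align(q, q)
  expect_equal(a3$cumulative_distance, 0)
  # one channel reduces to the univariate case
  q1 <- matrix(rand_series(8), ncol = 1)
  t1 <- matrix(rand_series(8), ncol = 1)
  expect_equal(dtw_align(q1, t1)$cumulative_distance,
               dtw_align(q1[, 1], t1[, 1])$cumulative_distance)
})

test_that("align_axis equals dtw_align on the extracted axis", {
  sim <- simulate_fall(default_protocol())
  other <- simulate_fall(perturb_protocol(default_protocol(),
                                          param_scale = 0.2, seed = 3))
  for (ax in c("x", "y", "z")) {
    a <- align_axis(sim$signal, other$signal, ax, open_begin = TRUE,
                    open_end = TRUE)
    b <- dtw_align(sim$signal$data[, ax], other$signal$data[, ax],
                   open_begin = TRUE, open_end = TRUE)
    expect_equal(a$cumulative_distance, b$cumulative_distance)
    expect_equal(a$normalized_distance, b$normalized_distance)
  }
  expect_equal(unname(align_axis(sim$signal, sim$signal,
                                 "z")$normalized_distance), 0)
  expect_error(align_axis(sim$signal, sim$signal, "w"), "arg")
  slow <- resample_signal(sim$signal, 50)
  expect_error(align_axis(sim$signal, slow, "z"), "sampling rates")
})

test_that("warp_template repeats template samples along the path", {
  s <- c(0, 1, 4, 9, 16)
  a <- dtw_align(s, s)
  expect_equal(warp_template(s, a), s)
  # steep section: template index repeated for consecutive query indices
  q <- c(0, 0, 1, 1, 2, 2, 3)
  t_ <- c(0, 1, 2, 3)
  al <- dtw_align(q, t_)
  w <- warp_template(t_, al)
  expect_length(w, length(q))
  for (i in unique(al$path[, "query_index"])) {
    j_max <- max(al$path[al$path[, "query_index"] == i, "template_index"])
    expect_equal(w[i + 1], t_[j_max + 1])
  }
  expect_error(warp_template(t_[1:2], al), "inconsistent")
})

test_that("normalized_distance divides by the query length", {
  expect_equal(normalized_distance(0, 17), 0)
  expect_equal(normalized_distance(4.2, 1), 4.2)
  expect_equal(normalized_distance(6, 4), 1.5)
  expect_error(normalized_distance(1, 0), "positive")
})

test_that("optimal path weights always sum to the query length", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    q <- rand_series(n); t_ <- rand_series(m)
    or <- enum_dtw(q, t_, open_begin = TRUE, open_end = TRUE)
    if (or$n_paths > 0L)
      expect_equal(unname(or$weight_sums), rep(n, or$n_paths))
  }
})

test_that("alignment export formats round-trip the key fields", {
  a <- dtw_align(c(0, 1, 2, 3), c(0, 1, 2, 3), open_end = TRUE)
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_alignment_json(a, fj)
  j <- jsonlite::read_json(fj)
  expect_equal(j$normalized_distance, 0)
  expect_equal(j$step_pattern_id, "asymmetricP1")
  expect_true(j$open_end)
  write_path_csv(a, fc)
  p <- utils::read.csv(fc)
  expect_equal(as.matrix(p), unname(a$path), ignore_attr = TRUE)
})
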