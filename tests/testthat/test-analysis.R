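ref_sim <- function(seed = 20) simulate_fall(default_protocol(seed = seed))

test_that("a signal compared with itself is at zero distance on all axes", {
  s <- ref_sim()$signal
  d <- compare_axes(s, s)
  expect_equal(unname(d), c(0, 0, 0))
  expect_named(d, c("x", "y", "z"))
})

test_that("compare_axes matches independent per-axis dtw_align runs", {
  ref <- ref_sim()$signal
  re_ <- simulate_fall(perturb_protocol(default_protocol(),
                                        param_scale = 0.3, seed = 5))$signal
  d <- compare_axes(ref, re_, open_begin = TRUE, open_end = TRUE)
  for (ax in c("x", "y", "z")) {
    manual <- dtw_align(ref$data[, ax], re_$data[, ax],
                        open_begin = TRUE, open_end = TRUE)
    expect_equal(unname(d[ax]), manual$normalized_distance)
  }
})

test_that("a faithful re-enactment scores below a heavily perturbed one", {
  base <- default_protocol()
  ref <- simulate_fall(base)$signal
  # same protocol, fresh sensor noise: the "perfect" re-enactment
  faithful <- base; faithful$seed <- 91L
  near <- simulate_fall(faithful)$signal
  rough <- perturb_protocol(base, duration_deltas_s = c(1, 0.5, -0.5, 1, -2, 1),
                            param_scale = 0.5, seed = 17)
  rough$seed <- 92L
  far <- simulate_fall(rough)$signal
  d_near <- compare_axes(ref, near)
  d_far <- compare_axes(ref, far)
  expect_true(all(d_near < d_far))
})

test_that("iteration reports follow the percent-change bookkeeping", {
  ref <- ref_sim()$signal
  re1 <- simulate_fall(perturb_protocol(default_protocol(), 0, 0.4,
                                        seed = 1))$signal
  rep1 <- iteration_report(ref, list(re1))
  expect_equal(nrow(rep1$iterations), 1L)
  expect_equal(nrow(rep1$improvements), 0L)
  expect_equal(rep1$best_iteration, "1")

  rep2 <- iteration_report(ref, list(a = re1, b = re1))
  expect_equal(unname(unlist(rep2$improvements[, c("x", "y", "z")])),
               rep(0, 3))
  expect_equal(rep2$best_iteration, "a")  # tie broken by earliest

  d <- rep2$iterations
  expect_equal(d$mean, rowMeans(d[, c("x", "y", "z")]))
  expect_error(iteration_report(ref, list()), "non-empty")
})

test_that("percent improvement is 100 * (previous - current) / previous", {
  # distances 2.0 -> 1.4 must read as a 30% reduction
  expect_equal(100 * (2.0 - 1.4) / 2.0, 30)
  ref <- ref_sim()$signal
  res <- lapply(c(3, 4), function(s)
    simulate_fall(perturb_protocol(default_protocol(), 0, 0.3,
                                   seed = s))$signal)
  rp <- iteration_report(ref, res)
  it <- rp$iterations
  for (ax in c("x", "y", "z")) {
    expect_equal(rp$improvements[[ax]],
                 100 * (it[[ax]][1] - it[[ax]][2]) / it[[ax]][1])
  }
  expect_equal(rp$best_iteration, it$iteration[which.min(it$mean)])
})

test_that("phase_summary equals a brute-force recomputation", {
  sim <- ref_sim()
  tab <- phase_summary(sim$signal, sim$annotations)
  expect_identical(tab$label, sim$annotations$label)
  for (k in seq_len(nrow(tab))) {
    span <- (sim$annotations$start_index[k] + 1):sim$annotations$end_index[k]
    seg <- sim$signal$data[span, , drop = FALSE]
    expect_equal(tab$duration_s[k], length(span) / 100)
    for (ax in c("x", "y", "z")) {
      expect_equal(tab[[paste0(ax, "_min")]][k], min(seg[, ax]))
      expect_equal(tab[[paste0(ax, "_max")]][k], max(seg[, ax]))
    }
  }
  empty <- phase_summary(sim$signal,
                         phase_annotations(integer(0), integer(0), integer(0)))
  expect_equal(nrow(empty), 0L)
  expect_error(phase_summary(sim$signal, phase_annotations(1L, 0L, 10000L)),
               "exceeds")
})

test_that("phase transfer through a diagonal path is the identity", {
  s <- ref_sim()
  a <- align_axis(s$signal, s$signal, "z")  # closed: pure diagonal
  out <- transfer_phases(s$annotations, a, "query_to_template")
  expect_equal(out, s$annotations)
  back <- transfer_phases(out, a, "template_to_query")
  expect_equal(back, s$annotations)
})

test_that("phase transfer follows repeated path indices", {
  q <- c(0, 0, 1, 1, 2, 2, 3)
  t_ <- c(0, 1, 2, 3)
  a <- dtw_align(q, t_)
  ann <- phase_annotations(c(1L, 2L), c(0L, 4L), c(4L, 7L))
  out <- transfer_phases(ann, a, "query_to_template")
  validate_annotations(out, n_samples = length(t_))
  # a query boundary inside a template repeat maps to that single index
  for (k in seq_len(nrow(ann))) {
    hits <- which(a$path[, "query_index"] == ann$start_index[k])
    expect_equal(out$start_index[k],
                 a$path[hits[1], "template_index"], ignore_attr = TRUE)
  }
})

test_that("round-trip phase transfer lands within one rule length", {
  base <- default_protocol(noise_sd_g = 0.01, seed = 6)
  s <- simulate_fall(base)
  other <- perturb_protocol(base, duration_deltas_s = 0.3, param_scale = 0.1,
                            seed = 8)
  other$seed <- 60L
  t_sig <- simulate_fall(other)$signal
  a <- align_axis(s$signal, t_sig, "z")  # closed ends: full coverage
  fwd <- transfer_phases(s$annotations, a, "query_to_template")
  back <- transfer_phases(fwd, a, "template_to_query")
  expect_true(all(abs(back$start_index - s$annotations$start_index) <= 2))
  expect_true(all(abs(back$end_index - s$annotations$end_index) <= 2))
})

test_that("boundaries outside the matched range are reported", {
  a <- dtw_align(c(7, 8), c(0, 0, 7, 8), open_begin = TRUE)
  ann <- phase_annotations(1L, 0L, 2L)  # template indices 0..1 unmatched
  expect_error(transfer_phases(ann, a, "template_to_query"),
               "outside the matched range")
})

test_that("report JSON serializes iterations, improvements and best id", {
  ref <- ref_sim()$signal
  rp <- iteration_report(ref, list(ref))
  j <- jsonlite::fromJSON(report_to_json(rp))
  expect_equal(j$best_iteration, "1")
  expect_equal(nrow(j$iterations), 1L)
  expect_equal(j$iterations$z, 0)
  expect_length(j$improvements, 0L)
})
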