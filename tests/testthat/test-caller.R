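# minimal count-table stand-in for caller tests
fake_table <- function(unused_reads, assay = c(protein = 100)) {
  data.frame(
    protein = c(names(assay), sprintf("bg%02d", seq_along(unused_reads))),
    role = c(rep("assay", length(assay)), rep("unused", length(unused_reads))),
    assigned_reads = c(unname(assay), unused_reads),
    molecule_count = c(unname(assay), unused_reads),
    stringsAsFactors = FALSE)
}

test_that("noise floor is mean + 3 sample-SD of unused-barcode reads", {
  nf <- noise_floor(fake_table(c(2, 4, 6)))
  expect_equal(nf$mean, 4)
  expect_equal(nf$sd, 2)
  expect_equal(nf$threshold, 10)

  zero <- noise_floor(fake_table(c(0, 0, 0, 0)))
  expect_equal(zero$threshold, 0)

  expect_error(noise_floor(fake_table(5)), "at least 2 unused")
})

test_that("the interaction-call rule grid matches the three-rule truth table", {
  floor <- noise_floor(fake_table(c(2, 4, 6)))     # threshold 10
  grid <- expand.grid(reads = c(9, 10, 11), control = c(0, 10, 12))
  calls <- call_ppi(grid$reads, grid$control, floor = floor, min_reads = 10)
  # independent statement of the rules: >=10 reads, strictly above control,
  # at or above the noise floor
  expected <- ifelse(grid$reads >= 10 & grid$reads > grid$control &
                       grid$reads >= floor$threshold, "positive", "negative")
  expect_identical(calls$call, expected)
  # the printed boundary: below 10 reads is always negative
  expect_true(all(calls$call[grid$reads < 10] == "negative"))
  # ties with the control are negative ("exceeded" is strict)
  expect_identical(calls$call[grid$reads == 10 & grid$control == 10],
                   "negative")
})

test_that("noise-floor-only failures are labelled background noise", {
  floor <- noise_floor(fake_table(c(20, 30, 40)))   # threshold 60
  call <- call_ppi(50, 10, floor = floor)
  expect_identical(call$call, "background_noise")
  expect_true(call$rule_min_reads && call$rule_control_exceed)
  expect_false(call$rule_noise_floor)
})

test_that("calls are monotone in prey reads", {
  set.seed(50)
  for (i in 1:20) {
    ctrl <- sample(0:100, 1)
    floor <- noise_floor(fake_table(sample(0:30, 3)))
    prey <- sort(sample(0:200, 30))
    calls <- call_ppi(prey, ctrl, floor = floor)$call
    # once positive, increasing reads never reverts to negative
    first_pos <- match("positive", calls)
    if (!is.na(first_pos))
      expect_true(all(calls[first_pos:length(calls)] == "positive"))
  }
})

test_that("fisher_exact_two_tailed reproduces known values", {
  # published screen table: 7/16 PRS vs 1/16 RRS positives
  expect_equal(signif(fisher_exact_two_tailed(7, 9, 1, 15), 3), 0.0373)
  # symmetric table
  expect_equal(fisher_exact_two_tailed(5, 5, 5, 5), 1)
  # extreme-tail table checked by explicit choose()-based enumeration
  enum_p <- local({
    n <- 32; row1 <- 16; col1 <- 8
    x <- 0:8
    probs <- choose(row1, x) * choose(n - row1, col1 - x) / choose(n, col1)
    p_obs <- probs[x == 8]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  })
  expect_equal(fisher_exact_two_tailed(8, 8, 0, 16), enum_p, tolerance = 1e-12)
  expect_error(fisher_exact_two_tailed(0, 0, 0, 0), "all-zero")
})

test_that("fisher_exact_two_tailed agrees with stats::fisher.test on random tables", {
  set.seed(51)
  for (i in 1:60) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b + c_ + d == 0) next
    ours <- fisher_exact_two_tailed(a, b, c_, d)
    ref <- stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value
    expect_equal(ours, min(ref, 1), tolerance = 1e-9)
  }
})

test_that("fisher_exact_two_tailed is symmetric under row and column swaps", {
  set.seed(52)
  for (i in 1:20) {
    t <- sample(0:15, 4, replace = TRUE)
    if (sum(t) == 0) next
    p <- fisher_exact_two_tailed(t[1], t[2], t[3], t[4])
    expect_equal(fisher_exact_two_tailed(t[3], t[4], t[1], t[2]), p)
    expect_equal(fisher_exact_two_tailed(t[2], t[1], t[4], t[3]), p)
  }
})

test_that("screen summaries report rates and the Fisher comparison", {
  prs <- c(rep("positive", 7), rep("negative", 9))
  rrs <- c("positive", rep("negative", 15))
  s <- summarize_screen(prs, rrs)
  expect_equal(s$prs_rate, 7 / 16)
  expect_equal(s$rrs_rate, 1 / 16)
  expect_equal(signif(s$p_two_tailed, 3), 0.0373)

  same <- summarize_screen(prs, prs)
  expect_equal(same$p_two_tailed, 1)

  # accepts call_ppi output directly
  floor <- noise_floor(fake_table(c(0, 0)))
  calls <- call_ppi(c(100, 5), 0, floor = floor)
  s2 <- summarize_screen(calls, calls)
  expect_equal(s2$prs_positive, 1L)
})

test_that("IP series sums replicates, calls against control, and reports ratios", {
  assay <- data.frame(dilution = rep(c(1e4, 1e5), each = 4),
                      reads = c(100, 80, 90, 70, 10, 8, 7, 5))
  control <- data.frame(dilution = c(1e4, 1e5), reads = c(50, 50))
  serum <- data.frame(dilution = c(1e4, 1e5), reads = c(170, 20))
  res <- call_ip_series(assay, control, serum)
  expect_equal(res$reads_sum[res$dilution == 1e4], 340)
  expect_identical(res$call, c("positive", "negative"))
  expect_equal(res$specificity_ratio[1], 340 / 170)
  expect_true(is.na(res$specificity_ratio[2]))   # defined only when positive
  expect_equal(attr(res, "detection_limit"), 1e4)

  # sum below control is negative
  res2 <- call_ip_series(data.frame(dilution = 1, reads = 30),
                         data.frame(dilution = 1, reads = 50))
  expect_identical(res2$call, "negative")

  # dilution missing from the control series is uncallable
  res3 <- call_ip_series(assay, control[control$dilution == 1e4, ])
  expect_true(is.na(res3$call[res3$dilution == 1e5]))
})

test_that("a simulated dilution ladder places the detection limit where signal crosses control", {
  # 10-fold signal decay across the ladder against a flat background
  dil <- 10^(2:7)
  signal <- round(2e6 / dil)     # 20000 ... 0.2 reads
  assay <- data.frame(dilution = dil, reads = signal)
  control <- data.frame(dilution = dil, reads = 15)
  res <- call_ip_series(assay, control)
  expect_equal(attr(res, "detection_limit"), max(dil[signal > 15]))
})
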