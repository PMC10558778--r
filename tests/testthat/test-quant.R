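test_that("count table collects distinct variants with zeros elsewhere", {
  ref <- toy_reference()
  r1 <- tibble::tibble(sequence = "UAUGGCACUGGUAGAAUUCACU", count = 3L)
  r2 <- tibble::tibble(sequence = window_read(ref, "miR-21-5p", 1L, 0L),
                       count = 7L)
  design <- tibble::tibble(sample_id = c("s1", "s2"),
                           condition = c("ctl", "case"))
  calls <- list(s1 = classify_reads(r1, ref, verbose = FALSE),
                s2 = classify_reads(r2, ref, verbose = FALSE))
  ct <- build_count_table(calls, design)
  expect_identical(nrow(ct), 2L)
  expect_identical(sum(ct$s1), 3L)
  expect_identical(sum(ct$s2), 7L)
  expect_identical(ct$s2[ct$mature_id == "miR-183-5p"], 0L)
  expect_error(build_count_table(calls["s1"], design),
               class = "isomirq_design_mismatch")
  empty <- build_count_table(list(s1 = calls$s1[0, ], s2 = calls$s2[0, ]),
                             design)
  expect_identical(nrow(empty), 0L)
})

test_that("RPM columns sum to one million and zero columns warn", {
  m <- matrix(c(5L, 0L, 1L, 3L, 0L, 0L), nrow = 2,
              dimnames = list(NULL, c("a", "b", "c")))
  ct <- counts_from_matrix(m, c("x", "x", "y"))
  expect_warning(rpm <- to_rpm(ct), class = "isomirq_zero_column")
  expect_equal(sum(rpm$a), 1e6)
  expect_equal(rpm$b, c(250000, 750000))
  expect_equal(rpm$c, c(0, 0))

  set.seed(1)
  m2 <- matrix(rpois(60, 40) + 1L, nrow = 10,
               dimnames = list(NULL, paste0("s", 1:6)))
  rpm2 <- to_rpm(counts_from_matrix(m2, rep(c("x", "y"), each = 3)))
  expect_true(all(abs(colSums(as.data.frame(rpm2)[, paste0("s", 1:6)]) -
                        1e6) < 1e-6))
})

test_that("group means average replicates after normalization", {
  m <- matrix(c(10, 30, 20, 20), nrow = 1,
              dimnames = list(NULL, paste0("s", 1:4)))
  ct <- counts_from_matrix(m, c("x", "x", "y", "y"))
  gm <- group_means(ct)   # raw counts work the same way as RPM here
  expect_equal(gm$x, 20)
  expect_equal(gm$y, 20)
  set.seed(42)
  m2 <- matrix(rpois(60, 50), nrow = 10,
               dimnames = list(NULL, paste0("s", 1:6)))
  cond <- rep(c("x", "y"), each = 3)
  gm2 <- group_means(counts_from_matrix(m2, cond))
  expect_equal(gm2$x, rowMeans(m2[, 1:3]))
  expect_equal(gm2$y, rowMeans(m2[, 4:6]))
})

test_that("isomir_ratio reproduces worked examples and edge behavior", {
  expect_equal(round(isomir_ratio(1566, 2122), 1), 1.4)
  expect_equal(round(isomir_ratio(2641.9, 223.6), 2), 0.08)
  expect_true(is.na(isomir_ratio(0, 0)))
  expect_true(is.na(isomir_ratio(0, 10)))
  expect_equal(isomir_ratio(3.7, 3.7), 1)
  expect_error(isomir_ratio(-1, 2), class = "isomirq_negative_rpm")
  # monotonicity: increasing in case, decreasing in control
  expect_true(isomir_ratio(10, 21) > isomir_ratio(10, 20))
  expect_true(isomir_ratio(11, 20) < isomir_ratio(10, 20))
})

test_that("ratio_table lays out variants extensions-first per mature", {
  ref <- toy_reference()
  reads <- tibble::tibble(
    sequence = c(window_read(ref, "miR-183-5p", 2L, 0L),
                 "UAUGGCACUGGUAGAAUUCACU",
                 window_read(ref, "miR-183-5p", -1L, 0L)),
    count = c(2L, 50L, 10L))
  design <- tibble::tibble(sample_id = c("s1", "s2"),
                           condition = c("ctl", "trt"))
  calls <- list(s1 = classify_reads(reads, ref, verbose = FALSE),
                s2 = classify_reads(reads, ref, verbose = FALSE))
  rt <- ratio_table(to_rpm(build_count_table(calls, design)),
                    "ctl", "trt")
  expect_identical(rt$offset5, c(2L, 0L, -1L))
  expect_identical(rt$length_nt, c(24L, 22L, 21L))
  expect_equal(rt$ratio, rep(1, 3))  # identical columns
  expect_identical(nrow(rt), 3L)
})

test_that("TMM factors have geometric mean one and expected closed forms", {
  m <- matrix(rep(c(10L, 20L, 40L, 80L, 25L), 2), ncol = 2,
              dimnames = list(NULL, c("r", "s")))
  f <- tmm_factors(counts_from_matrix(m, c("x", "y")))
  expect_equal(f$norm_factor, c(1, 1))  # identical columns -> M = 0

  m2 <- cbind(r = c(10L, 20L, 40L, 80L, 25L),
              s = 2L * c(10L, 20L, 40L, 80L, 25L))
  f2 <- tmm_factors(m2)
  # pure library-size doubling carries no compositional change
  expect_equal(f2$norm_factor, c(1, 1))
  expect_equal(exp(mean(log(f2$norm_factor))), 1, tolerance = 1e-12)
})

test_that("TMM factors are invariant to joint rescaling of all columns", {
  set.seed(7)
  m <- matrix(rnbinom(300, mu = exp(rnorm(50, 4, 1.5)), size = 10), 50, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  f1 <- tmm_factors(m)
  f2 <- tmm_factors(m * 4L)
  expect_equal(f1$norm_factor, f2$norm_factor, tolerance = 1e-12)
  expect_equal(exp(mean(log(f1$norm_factor))), 1, tolerance = 1e-12)
})

test_that("TMM errors when a sample shares no features with the reference", {
  m <- cbind(a = c(10L, 0L, 0L), b = c(12L, 5L, 1L), d = c(0L, 8L, 9L))
  expect_error(tmm_factors(m, reference_sample = "a"),
               class = "isomirq_no_shared_features")
})
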