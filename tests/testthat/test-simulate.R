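test_that("make_reference is deterministic, slice-consistent, unambiguous", {
  r1 <- make_reference(10, 22, 10, 5, seed = 55)
  r2 <- make_reference(10, 22, 10, 5, seed = 55)
  expect_identical(r1$hairpin_seq, r2$hairpin_seq)
  expect_identical(
    r1$mature_seq,
    substr(r1$hairpin_seq, r1$start + 1L, r1$end))
  # all-pairs: no window string is shared between matures
  wins <- isomiRq:::candidate_windows(r1, classifier_config())
  expect_false(any(duplicated(wins$window)))
})

test_that("simulated counts track programmed means and fold changes", {
  ref <- make_reference(20, 22, 10, 5, seed = 9)
  fc <- setNames(rep(1, 20), ref$mature_id)
  fc["syn-mir-001"] <- 0.5
  cfg <- sim_config(n_hairpins = 20, depth = 5e4, dispersion = 20,
                    foldchange = fc)
  sim <- simulate_counts(cfg, ref, seed = 99)
  expect_identical(nrow(sim$design), 9L)
  # empirical means within 3 standard errors of configured means
  chk <- merge(sim$counts, data.frame(mature_id = ref$mature_id))
  agg <- aggregate(cbind(count, mu) ~ mature_id + condition, chk, mean)
  nrep <- ifelse(agg$condition == "control", 4, 5)
  se <- sqrt((agg$mu + agg$mu^2 / 20) / nrep)
  expect_true(all(abs(agg$count - agg$mu) <= 3.5 * se))
  # programmed 0.5 fold change shows in the case/control count ratio
  m1 <- subset(agg, mature_id == "syn-mir-001")
  ratio <- m1$count[m1$condition == "case"] /
    m1$count[m1$condition == "control"]
  expect_lt(abs(ratio - m1$mu[m1$condition == "case"] /
                  m1$mu[m1$condition == "control"]), 0.15)
})

test_that("Poisson limit: equal probabilities give near-equal counts", {
  ref <- make_reference(5, 22, 10, 5, seed = 14)
  cfg <- sim_config(n_hairpins = 5, depth = 1e5, dispersion = Inf,
                    abundance_sdlog = 0)
  sim <- simulate_counts(cfg, ref, seed = 1)
  cv <- sd(sim$counts$count) / mean(sim$counts$count)
  expect_lt(cv, 0.05)   # 1/sqrt(20000) Poisson noise only
})

test_that("reads conserve counts and reconcile with the truth table", {
  sc <- drosha_loss_scenario(seed = 21, n_matures = 15, depth = 8000)
  per_sample_counts <- aggregate(count ~ sample_id, sc$counts$counts, sum)
  emitted <- vapply(per_sample_counts$sample_id,
                    function(s) sum(sc$read_sets[[s]]$count), 0)
  expect_equal(unname(emitted), per_sample_counts$count)
  truth_by_sample <- aggregate(count ~ sample_id, sc$truth$reads, sum)
  expect_equal(truth_by_sample$count,
               per_sample_counts$count[match(truth_by_sample$sample_id,
                                             per_sample_counts$sample_id)])
  # truth fraction programmed down is exactly as constructed
  expect_equal(sc$truth$frac_down, 10 / 15)
})

test_that("programmed offset distributions are recovered by classification", {
  set.seed(60)
  ref <- make_reference(4, 22, 10, 5)
  cfg <- sim_config(
    n_hairpins = 4, depth = 10000, dispersion = Inf,
    conditions = tibble::tibble(condition = "only", n_replicates = 1L),
    offset5_dist = list(only = list(.default = c(`-1` = 0.25, `0` = 0.5,
                                                 `1` = 0.25))))
  sim <- simulate_counts(cfg, ref)
  reads <- simulate_reads(sim, ref, cfg)
  calls <- classify_reads(reads$read_sets[[1]], ref, verbose = FALSE)
  tot <- sum(calls$count)
  prop <- vapply(c(-1L, 0L, 1L), function(o) {
    sum(calls$count[calls$offset5 == o]) / tot
  }, 0)
  se <- sqrt(c(0.25, 0.5, 0.25) * (1 - c(0.25, 0.5, 0.25)) / tot)
  expect_true(all(abs(prop - c(0.25, 0.5, 0.25)) <= 3 * se))
})

test_that("zero error and point-mass offsets give perfect classification", {
  ref <- make_reference(6, 22, 10, 5, seed = 71)
  cfg <- sim_config(n_hairpins = 6, depth = 3000, dispersion = 20)
  sim <- simulate_counts(cfg, ref, seed = 72)
  reads <- simulate_reads(sim, ref, cfg, seed = 73)
  for (s in names(reads$read_sets)[c(1, 5)]) {
    calls <- classify_reads(reads$read_sets[[s]], ref, verbose = FALSE)
    expect_true(all(calls$category == "canonical"))
  }
})

test_that("sequencing errors are applied at the configured rate", {
  ref <- make_reference(3, 22, 10, 5, seed = 81)
  cfg <- sim_config(n_hairpins = 3, depth = 20000, dispersion = Inf,
                    conditions = tibble::tibble(condition = "only",
                                                n_replicates = 1L),
                    seq_error_rate = 0.01)
  sim <- simulate_counts(cfg, ref, seed = 82)
  reads <- simulate_reads(sim, ref, cfg, seed = 83)
  truth <- reads$truth_reads
  # truth still reconciles and some sequences now differ from their window
  expect_equal(sum(truth$count), sum(sim$counts$count))
  frac_mut <- sum(truth$count[truth$sequence !=
                                ref$mature_seq[match(truth$mature_id,
                                                     ref$mature_id)]]) /
    sum(truth$count)
  p_read <- 1 - (1 - 0.01)^22
  expect_lt(abs(frac_mut - p_read), 3 * sqrt(p_read / sum(truth$count)) +
              0.02)
})

test_that("scenario and assay simulators are reproducible under a seed", {
  a <- drosha_loss_scenario(seed = 33, n_matures = 8, depth = 2000)
  b <- drosha_loss_scenario(seed = 33, n_matures = 8, depth = 2000)
  expect_identical(a$reference$hairpin_seq, b$reference$hairpin_seq)
  expect_equal(as.data.frame(a$truth$reads), as.data.frame(b$truth$reads))
  x <- simulate_assays(seed = 5)
  y <- simulate_assays(seed = 5)
  expect_equal(x$ct$ct, y$ct$ct)
  expect_equal(x$growth$count, y$growth$count)
})

test_that("zero-noise assay fixtures are recovered exactly by the formulas", {
  sim <- simulate_assays(seed = 3, ct_noise_sd = 0, growth_sigma = 0)
  cts <- summarise_ct(sim$ct)
  for (tg in names(sim$truth$folds)) {
    fold <- ddct_fold(
      cts$ct[cts$sample == "case" & cts$target == tg],
      cts$ct[cts$sample == "case" & cts$target == "reference"],
      cts$ct[cts$sample == "control" & cts$target == tg],
      cts$ct[cts$sample == "control" & cts$target == "reference"])
    expect_equal(fold, unname(sim$truth$folds[tg]))
  }
  acts <- ivp_activity(sim$ivp$pre_signal, sim$ivp$pri_signal,
                       sim$ivp$protein_amount)
  expect_equal(acts, unname(sim$truth$ivp_activity))
  for (s in names(sim$truth$td)) {
    g <- subset(sim$growth, sample == s)
    expect_equal(doubling_time(g$time, g$count)$td,
                 unname(sim$truth$td[s]))
  }
})

test_that("sim config survives a YAML round trip", {
  sc <- drosha_loss_scenario(seed = 44, n_matures = 6, depth = 1000)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(sc$config, f)
  back <- read_sim_config(f)
  expect_equal(back$depth, sc$config$depth)
  expect_equal(back$foldchange, sc$config$foldchange)
  expect_equal(back$offset5_dist$case$.default,
               sc$config$offset5_dist$case$.default)
  expect_equal(back$conditions$n_replicates,
               sc$config$conditions$n_replicates)
})
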