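test_that("canonical, extended and trimmed reads get the expected calls", {
  ref <- toy_reference()

  canon <- classify_read("UAUGGCACUGGUAGAAUUCACU", ref)
  expect_identical(canon$mature_id, "miR-183-5p")
  expect_identical(canon$category, "canonical")
  expect_identical(c(canon$offset5, canon$offset3), c(0L, 0L))
  expect_identical(canon$seed, "AUGGCAC")
  expect_false(canon$seed_shifted)

  # 2 extra templated 5' nucleotides copied from the upstream flank
  ext2 <- classify_read(window_read(ref, "miR-183-5p", 2L, 0L), ref)
  expect_identical(ext2$category, "iso5")
  expect_identical(ext2$offset5, 2L)
  expect_identical(ext2$offset3, 0L)
  expect_identical(ext2$templated5, "templated")
  expect_true(ext2$seed_shifted)

  # first nucleotide removed
  trim1 <- classify_read("AUGGCACUGGUAGAAUUCACU", ref)
  expect_identical(trim1$offset5, -1L)
  expect_identical(trim1$offset3, 0L)
  expect_identical(trim1$category, "iso5")
  expect_identical(trim1$templated5, "not_applicable")

  none <- classify_read("ACGUACGUACGUACGUACGUA", ref)
  expect_identical(none$category, "unassigned")
  expect_true(is.na(none$mature_id))
})

test_that("a +1 extension mismatching the flank yields no candidate at 0 mm", {
  ref <- toy_reference()
  true_ext <- window_read(ref, "miR-21-5p", 1L, 0L)   # flank base is G
  wrong_first <- setdiff(c("A", "C", "U"), substr(true_ext, 1L, 1L))[1]
  bad_ext <- paste0(wrong_first, substr(true_ext, 2L, nchar(true_ext)))
  cands <- align_candidates(bad_ext, ref, classifier_config())
  expect_false(any(cands$offset5 == 1L & cands$mature_id == "miR-21-5p"))
  # with one mismatch allowed the placement exists and is nontemplated
  cands1 <- align_candidates(bad_ext, ref,
                             classifier_config(max_mismatch = 1L))
  hit <- cands1[cands1$offset5 == 1L & cands1$mature_id == "miR-21-5p", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$templated5, "nontemplated")
  expect_identical(hit$mismatches, 1L)
})

test_that("equidistant reads from two matures are ambiguous by default", {
  shared <- "UAGCUUAUCAGACUGAUGUUGA"
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">hpA", paste0("AACCGGAA", shared, "GGUUCCAA"),
               ">hpB", paste0("CCGGAAUU", shared, "AAUUGGCC")), fa)
  ann <- tibble::tibble(hairpin_id = c("hpA", "hpB"),
                        mature_id = c("mA", "mB"),
                        start = 8, end = 8 + nchar(shared), arm = "5p")
  ref <- load_reference(fa, ann)
  amb <- classify_read(shared, ref)
  expect_identical(amb$category, "ambiguous")
  expect_true(is.na(amb$mature_id))
  first <- classify_read(
    shared, ref,
    classifier_config(tie_policy = "first_by_reference_order"))
  expect_identical(first$mature_id, "mA")
  # exhaustive enumeration confirms the tie
  cands <- align_candidates(shared, ref, classifier_config())
  zero <- cands[cands$mismatches == 0 & cands$offset5 == 0 &
                  cands$offset3 == 0, ]
  expect_setequal(zero$mature_id, c("mA", "mB"))
})

test_that("round-trip over programmed offsets recovers mature and offsets", {
  ref <- make_reference(8, 22, 10, 5, seed = 201)
  cfg <- classifier_config()
  grid <- expand.grid(i = seq_len(nrow(ref)), o5 = -3:3, o3 = -3:3)
  for (r in seq_len(nrow(grid))) {
    i <- grid$i[r]
    rd <- window_read(ref, ref$mature_id[i], grid$o5[r], grid$o3[r])
    if (nchar(rd) < 8) next
    call <- classify_read(rd, ref, cfg)
    expect_identical(call$mature_id, ref$mature_id[i])
    expect_identical(call$offset5, as.integer(grid$o5[r]))
    expect_identical(call$offset3, as.integer(grid$o3[r]))
    expect_identical(call$mismatches, 0L)
    if (grid$o5[r] > 0) expect_identical(call$templated5, "templated")
  }
})

test_that("classifier agrees with the brute-force placement oracle", {
  set.seed(77)
  ref <- make_reference(6, 22, 8, 5)
  reads <- character()
  for (i in seq_len(nrow(ref))) {
    for (k in 1:4) {
      o5 <- sample(-4:4, 1); o3 <- sample(-4:4, 1)
      rd <- window_read(ref, ref$mature_id[i], o5, o3)
      if (nchar(rd) >= 10) reads <- c(reads, rd)
    }
  }
  # plus random junk and mutated windows
  rand_read <- function() paste(sample(c("A", "C", "G", "U"), 22,
                                       replace = TRUE), collapse = "")
  mutate1 <- function(s) {
    p <- sample.int(nchar(s), 1)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "U"),
                                      substr(s, p, p)), 1)
    s
  }
  reads <- c(reads, replicate(10, rand_read()),
             vapply(reads[1:8], mutate1, ""))
  cfg <- classifier_config()
  for (rd in reads) {
    got <- classify_read(rd, ref, cfg)
    want <- oracle_classify(rd, ref)
    if (want$status == "assigned") {
      expect_identical(got$mature_id, want$mature_id)
      expect_identical(got$offset5, want$o5)
      expect_identical(got$offset3, want$o3)
    } else {
      expect_identical(got$category, want$status)
    }
  }
})

test_that("assigned reads satisfy the length identity and determinism", {
  set.seed(31)
  ref <- make_reference(5, 22, 10, 5)
  sc <- drosha_loss_scenario(seed = 5, n_matures = 10, depth = 5000)
  rs <- sc$read_sets[["case_1"]]
  calls <- classify_reads(rs, sc$reference, verbose = FALSE)
  assigned <- calls[!is.na(calls$mature_id), ]
  mlen <- nchar(sc$reference$mature_seq[
    match(assigned$mature_id, sc$reference$mature_id)])
  expect_true(all(nchar(assigned$read_sequence) ==
                    mlen + assigned$offset5 + assigned$offset3))
  # shuffling input order never changes any call
  shuf <- rs[sample.int(nrow(rs)), ]
  calls2 <- classify_reads(shuf, sc$reference, verbose = FALSE)
  expect_equal(as.data.frame(calls2), as.data.frame(calls))
})

test_that("classify_reads matches per-read classification and tallies counts", {
  ref <- toy_reference()
  reads <- tibble::tibble(
    sequence = c("UAUGGCACUGGUAGAAUUCACU", window_read(ref, "miR-21-5p",
                                                      1L, 0L),
                 "ACGUACGUACGUACGUACGUA"),
    count = c(10L, 5L, 2L)
  )
  expect_message(calls <- classify_reads(reads, ref),
                 class = "isomirq_tally")
  expect_identical(sum(calls$count), 17L)
  for (i in seq_len(nrow(calls))) {
    single <- classify_read(calls$read_sequence[i], ref)
    expect_equal(as.data.frame(single),
                 as.data.frame(calls[i, names(single)]))
  }
  empty <- classify_reads(reads[0, ], ref, verbose = FALSE)
  expect_identical(nrow(empty), 0L)
})
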