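#' Classifier configuration
#'
#' Tolerances for isomiR classification. The offset model places a read so
#' that its 5' end sits `offset5` nucleotides upstream (positive) or
#' downstream (negative) of the annotated mature start; the 3' offset is
#' then forced by the read length.
#'
#' @param max_shift Maximum absolute 5' and 3' offset considered (default
#'   5 nt; must be >= 2 to cover the 1-2 nt upstream-cleavage shifts the
#'   classifier is built to detect).
#' @param max_mismatch Maximum internal mismatches tolerated (default 0,
#'   i.e. exact matching: terminal-variant isomiRs differ from the
#'   reference only by end nucleotides).
#' @param tie_policy What to do when two different matures achieve the same
#'   best alignment score: `"ambiguous"` (default; no assignment) or
#'   `"first_by_reference_order"`.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(max_shift = 5L, max_mismatch = 0L,
                              tie_policy = c("ambiguous",
                                             "first_by_reference_order")) {
  tie_policy <- match.arg(tie_policy)
  max_shift <- as.integer(max_shift)
  max_mismatch <- as.integer(max_mismatch)
  if (max_shift < 2L) {
    stopf("isomirq_bad_config", "max_shift must be >= 2, got %d", max_shift)
  }
  if (max_mismatch < 0L) {
    stopf("isomirq_bad_config", "max_mismatch must be >= 0")
  }
  structure(list(max_shift = max_shift, max_mismatch = max_mismatch,
                 tie_policy = tie_policy), class = "classifier_config")
}

# All hairpin windows reachable with |offset5|, |offset3| <= max_shift.
# Used as an exact-match index when max_mismatch == 0: a read classifies
# to (mature, o5, o3) with zero mismatches iff it equals the corresponding
# window. Windows overhanging the hairpin are not enumerated because an
# overhanging position counts as a mismatch.
candidate_windows <- function(ref, config) {
  k <- config$max_shift
  grid <- tidyr::expand_grid(
    ref_order = seq_len(nrow(ref)),
    offset5 = seq(-k, k),
    offset3 = seq(-k, k)
  )
  grid <- bind_cols(
    ref[grid$ref_order, c("hairpin_id", "hairpin_seq", "mature_id",
                          "start", "end", "mature_seq")],
    grid
  )
  grid <- grid |>
    mutate(w_start = .data$start - .data$offset5,
           w_end = .data$end + .data$offset3) |>
    filter(.data$w_start >= 0L, .data$w_end > .data$w_start,
           .data$w_end <= nchar(.data$hairpin_seq)) |>
    mutate(window = substr(.data$hairpin_seq, .data$w_start + 1L,
                           .data$w_end)) |>
    select("window", "hairpin_id", "mature_id", "mature_seq",
           "offset5", "offset3", "ref_order")
  grid
}

#' Enumerate alignment candidates for one read
#'
#' For every mature and every 5' offset in `[-max_shift, max_shift]` the
#' read is placed with its 5' end at `mature_start - offset5` on the
#' hairpin; the 3' offset is forced by the read length. Candidates whose
#' 3' offset exceeds `max_shift` are discarded. Mismatches are counted
#' over hairpin-overlapping positions, and read positions overhanging the
#' hairpin each count as one mismatch. A 5' extension (`offset5 > 0`) is
#' `"templated"` when all extension positions lie on the hairpin and match
#' it, `"nontemplated"` when any extension position mismatches or
#' overhangs, and `"not_applicable"` when `offset5 <= 0`. Only candidates
#' with `mismatches <= max_mismatch` are returned.
#'
#' @param read A single RNA sequence (character scalar).
#' @param ref An `isomir_ref` reference.
#' @param config A [classifier_config()].
#' @return A tibble with one row per surviving candidate: `mature_id`,
#'   `hairpin_id`, `offset5`, `offset3`, `mismatches`, `templated5`.
#' @export
align_candidates <- function(read, ref, config = classifier_config()) {
  stopifnot(is.character(read), length(read) == 1L)
  k <- config$max_shift
  len <- nchar(read)
  read_chars <- strsplit(read, "", fixed = TRUE)[[1]]
  out <- vector("list", nrow(ref))
  for (i in seq_len(nrow(ref))) {
    hp <- ref$hairpin_seq[i]
    hlen <- nchar(hp)
    hp_chars <- strsplit(hp, "", fixed = TRUE)[[1]]
    mlen <- ref$end[i] - ref$start[i]
    rows <- list()
    for (o5 in seq(-k, k)) {
      o3 <- len - mlen - o5
      if (abs(o3) > k) next
      start0 <- ref$start[i] - o5
      pos <- start0 + seq_len(len) - 1L          # 0-based hairpin positions
      on_hp <- pos >= 0L & pos < hlen
      mm <- sum(!on_hp)
      if (any(on_hp)) {
        mm <- mm + sum(read_chars[on_hp] != hp_chars[pos[on_hp] + 1L])
      }
      if (mm > config$max_mismatch) next
      if (o5 > 0L) {
        ext <- seq_len(o5)
        ok <- all(on_hp[ext]) &&
          all(read_chars[ext] == hp_chars[pos[ext] + 1L])
        templated5 <- if (ok) "templated" else "nontemplated"
      } else {
        templated5 <- "not_applicable"
      }
      rows[[length(rows) + 1L]] <- tibble(
        mature_id = ref$mature_id[i], hairpin_id = ref$hairpin_id[i],
        mature_seq = ref$mature_seq[i],
        offset5 = as.integer(o5), offset3 = as.integer(o3),
        mismatches = as.integer(mm), templated5 = templated5,
        ref_order = i
      )
    }
    if (length(rows)) out[[i]] <- bind_rows(rows)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(mature_id = character(), hairpin_id = character(),
                  mature_seq = character(), offset5 = integer(),
                  offset3 = integer(), mismatches = integer(),
                  templated5 = character(), ref_order = integer())
  }
  res
}

# Lexicographic candidate selection: (mismatches, |o5|+|o3|, |o5|), with
# deterministic within-mature tie-breaks (prefer larger o5, then larger o3,
# then reference order). Returns list(best = one-row tibble or NULL,
# ambiguous = TRUE/FALSE).
pick_best_candidate <- function(cands, config) {
  if (nrow(cands) == 0L) return(list(best = NULL, ambiguous = FALSE))
  sc <- cands |>
    mutate(aos = abs(.data$offset5) + abs(.data$offset3),
           a5 = abs(.data$offset5)) |>
    arrange(.data$mismatches, .data$aos, .data$a5,
            desc(.data$offset5), desc(.data$offset3), .data$ref_order)
  top <- sc[1L, ]
  at_min <- sc$mismatches == top$mismatches & sc$aos == top$aos &
    sc$a5 == top$a5
  if (n_distinct(sc$mature_id[at_min]) > 1L &&
      config$tie_policy == "ambiguous") {
    return(list(best = NULL, ambiguous = TRUE))
  }
  list(best = top, ambiguous = FALSE)
}

read_seed <- function(x) {
  ifelse(nchar(x) >= 8L, substr(x, 2L, 8L), NA_character_)
}

categorize <- function(offset5, offset3, mismatches) {
  dplyr::case_when(
    offset5 == 0L & offset3 == 0L & mismatches == 0L ~ "canonical",
    offset5 != 0L & offset3 == 0L ~ "iso5",
    offset5 == 0L & offset3 != 0L ~ "iso3",
    offset5 != 0L & offset3 != 0L ~ "iso5_iso3",
    TRUE ~ "other"   # zero offsets with internal mismatches (max_mismatch > 0)
  )
}

call_columns <- function() {
  tibble(read_sequence = character(), hairpin_id = character(),
         mature_id = character(), offset5 = integer(), offset3 = integer(),
         mismatches = integer(), templated5 = character(),
         seed = character(), seed_shifted = logical(),
         category = character())
}

build_call <- function(read, picked) {
  seed <- read_seed(read)
  if (is.null(picked$best)) {
    return(tibble(read_sequence = read, hairpin_id = NA_character_,
                  mature_id = NA_character_, offset5 = NA_integer_,
                  offset3 = NA_integer_, mismatches = NA_integer_,
                  templated5 = "not_applicable", seed = seed,
                  seed_shifted = NA,
                  category = if (picked$ambiguous) "ambiguous"
                             else "unassigned"))
  }
  b <- picked$best
  tibble(read_sequence = read, hairpin_id = b$hairpin_id,
         mature_id = b$mature_id, offset5 = b$offset5, offset3 = b$offset3,
         mismatches = b$mismatches, templated5 = b$templated5, seed = seed,
         seed_shifted = !is.na(seed) & seed != read_seed(b$mature_seq),
         category = categorize(b$offset5, b$offset3, b$mismatches))
}

#' Classify a single read against the reference
#'
#' Among candidates from [align_candidates()], the call minimizing
#' `(mismatches, |offset5| + |offset3|, |offset5|)` lexicographically is
#' chosen. If the minimum is attained by more than one mature, the
#' configured tie policy applies (default: category `"ambiguous"`, no
#' assignment). With no surviving candidate the read is `"unassigned"`.
#' The seed is read positions 2-8 (1-based, the standard miRNA seed);
#' `seed_shifted` flags a seed differing from the assigned mature's.
#'
#' @inheritParams align_candidates
#' @return A one-row tibble (an isomiR call) with columns `read_sequence`,
#'   `hairpin_id`, `mature_id`, `offset5`, `offset3`, `mismatches`,
#'   `templated5`, `seed`, `seed_shifted`, `category`. `category` is
#'   `"canonical"` only for an exact full-length match; `"iso5"`,
#'   `"iso3"`, `"iso5_iso3"` label end variants; `"other"` marks the
#'   (only reachable when `max_mismatch > 0`) case of zero offsets with
#'   internal mismatches.
#' @export
classify_read <- function(read, ref, config = classifier_config()) {
  read <- as_rna(read)
  cands <- align_candidates(read, ref, config)
  build_call(read, pick_best_candidate(cands, config))
}

#' Classify a collapsed read set
#'
#' Vectorized classification: one call per distinct sequence, read counts
#' carried through. With the default `max_mismatch = 0` an exact-match
#' window index over the reference is used; otherwise each sequence goes
#' through [align_candidates()].
#'
#' @param reads Tibble with columns `sequence` and `count`
#'   (e.g. from [load_reads()] or the simulator).
#' @inheritParams align_candidates
#' @param verbose Emit a category tally message (default `TRUE`).
#' @return A tibble with the [classify_read()] columns plus `count`.
#' @export
classify_reads <- function(reads, ref, config = classifier_config(),
                           verbose = TRUE) {
  stopifnot(all(c("sequence", "count") %in% names(reads)))
  if (nrow(reads) == 0L) {
    out <- bind_cols(call_columns(), tibble(count = integer()))
    return(out)
  }
  seqs <- as_rna(reads$sequence)
  uniq <- unique(seqs)

  if (config$max_mismatch == 0L) {
    wins <- candidate_windows(ref, config)
    cands <- tibble(read_sequence = uniq) |>
      inner_join(wins, by = c(read_sequence = "window"),
                 relationship = "many-to-many") |>
      mutate(mismatches = 0L,
             templated5 = ifelse(.data$offset5 > 0L, "templated",
                                 "not_applicable"))
    best <- cands |>
      mutate(aos = abs(.data$offset5) + abs(.data$offset3),
             a5 = abs(.data$offset5)) |>
      arrange(.data$read_sequence, .data$mismatches, .data$aos, .data$a5,
              desc(.data$offset5), desc(.data$offset3), .data$ref_order) |>
      group_by(.data$read_sequence) |>
      summarise(
        n_tie_matures = n_distinct(.data$mature_id[
          .data$aos == first(.data$aos) & .data$a5 == first(.data$a5)]),
        hairpin_id = first(.data$hairpin_id),
        mature_id = first(.data$mature_id),
        mature_seq = first(.data$mature_seq),
        offset5 = first(.data$offset5), offset3 = first(.data$offset3),
        mismatches = first(.data$mismatches),
        templated5 = first(.data$templated5),
        .groups = "drop"
      )
    ambiguous <- best$n_tie_matures > 1L & config$tie_policy == "ambiguous"
    seed <- read_seed(best$read_sequence)
    calls <- tibble(
      read_sequence = best$read_sequence,
      hairpin_id = ifelse(ambiguous, NA_character_, best$hairpin_id),
      mature_id = ifelse(ambiguous, NA_character_, best$mature_id),
      offset5 = ifelse(ambiguous, NA_integer_, best$offset5),
      offset3 = ifelse(ambiguous, NA_integer_, best$offset3),
      mismatches = ifelse(ambiguous, NA_integer_, best$mismatches),
      templated5 = ifelse(ambiguous, "not_applicable", best$templated5),
      seed = seed,
      seed_shifted = ifelse(ambiguous, NA,
                            !is.na(seed) & seed != read_seed(best$mature_seq)),
      category = ifelse(ambiguous, "ambiguous",
                        categorize(best$offset5, best$offset3,
                                   best$mismatches))
    )
    missing <- setdiff(uniq, calls$read_sequence)
    if (length(missing)) {
      miss_seed <- read_seed(missing)
      calls <- bind_rows(
        calls,
        tibble(read_sequence = missing, hairpin_id = NA_character_,
               mature_id = NA_character_, offset5 = NA_integer_,
               offset3 = NA_integer_, mismatches = NA_integer_,
               templated5 = "not_applicable", seed = miss_seed,
               seed_shifted = NA, category = "unassigned")
      )
    }
  } else {
    calls <- bind_rows(lapply(uniq, classify_read, ref = ref,
                              config = config))
  }

  out <- tibble(read_sequence = seqs, count = as.integer(reads$count)) |>
    group_by(.data$read_sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    left_join(calls, by = "read_sequence") |>
    relocate("count", .after = "read_sequence") |>
    arrange(.data$read_sequence)
  if (verbose) {
    tal <- out |>
      group_by(.data$category) |>
      summarise(reads = sum(.data$count), .groups = "drop")
    inform(paste0("classified ", sum(out$count), " reads: ",
                  paste(sprintf("%s=%d", tal$category, tal$reads),
                        collapse = ", ")),
           class = "isomirq_tally")
  }
  out
}
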