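#' Load a hairpin reference with embedded mature annotations
#'
#' Reads hairpin sequences from FASTA and a mature-miRNA annotation table,
#' validates them against each other, and returns one row per annotated
#' mature. Coordinates are 0-based, half-open (`start` inclusive, `end`
#' exclusive), so the mature sequence is the hairpin substring
#' `[start, end)`. DNA input is accepted and converted to RNA (`T -> U`);
#' all downstream sequence comparison happens in RNA space.
#'
#' @param hairpin_fasta Path to a FASTA file of hairpin sequences. The
#'   hairpin id is the first whitespace-delimited token of each header.
#' @param annotation Path to a TSV with columns
#'   `hairpin_id  mature_id  start  end  arm`, or a data frame with those
#'   columns. `arm` is one of `"5p"`, `"3p"`, `"unknown"`.
#' @return A tibble of class `isomir_ref` with columns `hairpin_id`,
#'   `hairpin_seq`, `mature_id`, `start`, `end`, `arm`, `mature_seq`.
#' @details Validation failures raise classed errors:
#'   `isomirq_missing_hairpin` (annotation row names an absent hairpin),
#'   `isomirq_bad_coordinates` (coordinates outside the hairpin),
#'   `isomirq_duplicate_mature` (repeated mature id), and
#'   `isomirq_bad_alphabet` (non-ACGU hairpin after normalization).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hp1", "GGGGUAGCUUAUCAGACUGAUGUUGACCCC"), fa)
#' ann <- data.frame(hairpin_id = "hp1", mature_id = "miR-21-5p",
#'                   start = 4, end = 26, arm = "5p")
#' ref <- load_reference(fa, ann)
#' ref$mature_seq  # "UAGCUUAUCAGACUGAUGUUGA"
#' @export
load_reference <- function(hairpin_fasta, annotation) {
  seqs <- Biostrings::readBStringSet(hairpin_fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  hp <- tibble(hairpin_id = ids, hairpin_seq = as_rna(as.character(seqs)))
  if (anyDuplicated(hp$hairpin_id)) {
    stopf("isomirq_duplicate_hairpin", "duplicate hairpin id in %s",
          hairpin_fasta)
  }
  bad <- !is_rna(hp$hairpin_seq) | !nzchar(hp$hairpin_seq)
  if (any(bad)) {
    stopf("isomirq_bad_alphabet",
          "hairpin(s) with non-ACGU characters or empty sequence: %s",
          paste(hp$hairpin_id[bad], collapse = ", "))
  }

  ann <- if (is.data.frame(annotation)) {
    as_tibble(annotation)
  } else {
    readr::read_tsv(annotation, show_col_types = FALSE)
  }
  req <- c("hairpin_id", "mature_id", "start", "end")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    stopf("isomirq_bad_schema", "annotation lacks column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (!"arm" %in% names(ann)) ann$arm <- "unknown"
  if (anyDuplicated(ann$mature_id)) {
    stopf("isomirq_duplicate_mature", "duplicate mature id(s): %s",
          paste(unique(ann$mature_id[duplicated(ann$mature_id)]),
                collapse = ", "))
  }
  unknown <- setdiff(ann$hairpin_id, hp$hairpin_id)
  if (length(unknown)) {
    stopf("isomirq_missing_hairpin",
          "annotation references absent hairpin id(s): %s",
          paste(unknown, collapse = ", "))
  }

  ref <- ann |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           arm = as.character(.data$arm)) |>
    left_join(hp, by = "hairpin_id")
  oob <- ref$start < 0L | ref$end <= ref$start |
    ref$end > nchar(ref$hairpin_seq)
  if (any(oob)) {
    stopf("isomirq_bad_coordinates",
          "mature coordinate(s) out of bounds for: %s",
          paste(ref$mature_id[oob], collapse = ", "))
  }
  ref <- ref |>
    mutate(mature_seq = substr(.data$hairpin_seq, .data$start + 1L,
                               .data$end)) |>
    select("hairpin_id", "hairpin_seq", "mature_id", "start", "end",
           "arm", "mature_seq")
  class(ref) <- c("isomir_ref", class(ref))
  ref
}

#' Write a hairpin reference back to FASTA + annotation TSV
#'
#' @param ref An `isomir_ref` tibble from [load_reference()] or
#'   [make_reference()].
#' @param hairpin_fasta,annotation Output paths.
#' @return `ref`, invisibly.
#' @export
write_reference <- function(ref, hairpin_fasta, annotation) {
  hp <- distinct(ref, .data$hairpin_id, .data$hairpin_seq)
  set <- Biostrings::BStringSet(setNames(hp$hairpin_seq, hp$hairpin_id))
  Biostrings::writeXStringSet(set, hairpin_fasta)
  ref |>
    select("hairpin_id", "mature_id", "start", "end", "arm") |>
    readr::write_tsv(annotation)
  invisible(ref)
}

#' Load and collapse a small RNA read set
#'
#' Reads FASTQ or collapsed FASTA (fastx `">id_x<count>"` header dialect),
#' normalizes to uppercase RNA, applies length and ambiguity filters, and
#' merges identical sequences by summing their counts. Qualities in FASTQ
#' input are ignored; adapter and quality trimming are assumed done
#' upstream.
#'
#' @param path Input file.
#' @param format `"fastq"` or `"collapsed_fasta"`.
#' @param min_len,max_len Retained read-length window in nucleotides
#'   (defaults 18-26, spanning the usual mature-miRNA size range).
#' @param drop_ambiguous Drop reads containing non-ACGU symbols
#'   (default `TRUE`).
#' @param sample_id,condition Optional labels stored as attributes.
#' @return A tibble with columns `sequence`, `count`, sorted by sequence,
#'   with attributes `sample_id`, `condition` and `total_input_reads`
#'   (read count before filtering).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1_x42", "TAGCTTATCAGACTGATGTTGA"), fa)
#' load_reads(fa, format = "collapsed_fasta")
#' @export
load_reads <- function(path, format = c("collapsed_fasta", "fastq"),
                       min_len = 18L, max_len = 26L, drop_ambiguous = TRUE,
                       sample_id = NA_character_, condition = NA_character_) {
  format <- match.arg(format)
  if (format == "fastq") {
    seqs <- Biostrings::readBStringSet(path, format = "fastq")
    counts <- rep(1L, length(seqs))
  } else {
    seqs <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    m <- regmatches(ids, regexec("_x([0-9]+)$", ids))
    bad <- lengths(m) < 2L
    if (any(bad)) {
      stopf("isomirq_bad_count_header",
            "collapsed FASTA header(s) without '_x<count>' suffix: %s",
            paste(head(ids[bad], 3L), collapse = ", "))
    }
    counts <- as.integer(vapply(m, `[`, "", 2L))
  }
  reads <- tibble(sequence = as_rna(as.character(seqs)), count = counts)
  total_input <- sum(reads$count)
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len
  if (drop_ambiguous) keep <- keep & is_rna(reads$sequence)
  reads <- reads[keep, , drop = FALSE]
  out <- reads |>
    group_by(.data$sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$sequence)
  if (nrow(out) == 0L) {
    warn(sprintf("no reads remain after filtering %s", path),
         class = "isomirq_empty_readset")
  }
  attr(out, "sample_id") <- sample_id
  attr(out, "condition") <- condition
  attr(out, "total_input_reads") <- total_input
  out
}

#' Write a collapsed read set as fastx-style collapsed FASTA
#'
#' @param reads Tibble with `sequence` and `count` columns.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  ids <- sprintf("r%d_x%d", seq_len(nrow(reads)), reads$count)
  set <- Biostrings::BStringSet(setNames(reads$sequence, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an experimental design table
#'
#' A design table maps samples to conditions and (optionally) read files:
#' TSV columns `sample_id  condition  path  format`. Relative `path`
#' entries are resolved against the directory of the design file.
#'
#' @param path TSV file path.
#' @return A tibble with one row per sample.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("sample_id", "condition")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stopf("isomirq_bad_schema", "design lacks column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) {
    stopf("isomirq_bad_schema", "duplicate sample_id in design")
  }
  if ("path" %in% names(d)) {
    rel <- !grepl("^(/|[A-Za-z]:)", d$path)
    d$path[rel] <- file.path(dirname(path), d$path[rel])
  }
  d
}

#' Write / read result tables with a fixed TSV contract
#'
#' `write_isomir_table()` writes a tibble as TSV with a fixed column order
#' and `"-"` for undefined values (e.g. ratios with a zero control mean);
#' `read_isomir_table()` reads such a file back, restoring `"-"` to `NA`.
#' Writing then reading preserves values.
#'
#' @param x A data frame.
#' @param path File path.
#' @param col_types Passed to [readr::read_tsv()].
#' @return `write_isomir_table()` returns `x` invisibly;
#'   `read_isomir_table()` returns a tibble.
#' @export
write_isomir_table <- function(x, path) {
  readr::write_tsv(x, path, na = "-")
  invisible(x)
}

#' @rdname write_isomir_table
#' @export
read_isomir_table <- function(path, col_types = NULL) {
  readr::read_tsv(path, na = c("-", "NA"), col_types = col_types,
                  show_col_types = FALSE)
}
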