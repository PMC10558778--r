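# Fixture builders and an independent brute-force classification oracle.

# A reference built by hand around published mature sequences: each hairpin
# is an arbitrary flank, the mature, and another flank, so expected offsets
# are known by construction.
toy_reference <- function() {
  matures <- c(
    `miR-183-5p` = "UAUGGCACUGGUAGAAUUCACU",
    `miR-21-5p`  = "UAGCUUAUCAGACUGAUGUUGA",
    `miR-96-5p`  = "UUUGGCACUAGCACAUUUUUGCU"
  )
  # upstream flanks end in the observed templated extensions (UG / G / U)
  up <- c("AACCGGUG", "CAAGCCAG", "GGAACCAU")
  down <- c("CAGUCAAG", "UUGCAGGA", "ACCGGAUU")
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(seq_along(matures), function(i) {
    c(paste0(">hp-", names(matures)[i]),
      paste0(up[i], matures[i], down[i]))
  })), fa)
  ann <- tibble::tibble(
    hairpin_id = paste0("hp-", names(matures)),
    mature_id = names(matures),
    start = nchar(up),
    end = nchar(up) + nchar(matures),
    arm = "5p"
  )
  load_reference(fa, ann)
}

# Build the read corresponding to (mature, o5, o3) from the hairpin.
window_read <- function(ref, mature_id, o5, o3) {
  i <- match(mature_id, ref$mature_id)
  substr(ref$hairpin_seq[i], ref$start[i] - o5 + 1L, ref$end[i] + o3)
}

# Independent oracle: enumerate every placement of the read on every
# hairpin (by start position, not by offset), apply the same constraints
# and selection rule, written with plain loops.
oracle_classify <- function(read, ref, max_shift = 5L, max_mismatch = 0L) {
  rd <- strsplit(read, "")[[1]]
  cands <- list()
  for (i in seq_len(nrow(ref))) {
    hp <- strsplit(ref$hairpin_seq[i], "")[[1]]
    mlen <- ref$end[i] - ref$start[i]
    for (pos0 in seq(-length(rd), length(hp))) {
      o5 <- ref$start[i] - pos0
      o3 <- length(rd) - mlen - o5
      if (abs(o5) > max_shift || abs(o3) > max_shift) next
      mm <- 0L
      for (j in seq_along(rd)) {
        hpos <- pos0 + j - 1L
        if (hpos < 0L || hpos >= length(hp) || rd[j] != hp[hpos + 1L]) {
          mm <- mm + 1L
        }
      }
      if (mm <= max_mismatch) {
        cands[[length(cands) + 1L]] <-
          list(mature_id = ref$mature_id[i], o5 = o5, o3 = o3, mm = mm,
               ref_order = i)
      }
    }
  }
  if (!length(cands)) {
    return(list(mature_id = NA_character_, o5 = NA_integer_,
                o3 = NA_integer_, status = "unassigned"))
  }
  score <- vapply(cands, function(x) {
    c(x$mm, abs(x$o5) + abs(x$o3), abs(x$o5), -x$o5, -x$o3, x$ref_order)
  }, numeric(6))
  ord <- do.call(order, as.data.frame(t(score)))
  best <- cands[[ord[1]]]
  at_min <- vapply(cands, function(x) {
    x$mm == best$mm &&
      (abs(x$o5) + abs(x$o3)) == (abs(best$o5) + abs(best$o3)) &&
      abs(x$o5) == abs(best$o5)
  }, TRUE)
  mats <- unique(vapply(cands[at_min], `[[`, "", "mature_id"))
  if (length(mats) > 1L) {
    return(list(mature_id = NA_character_, o5 = NA_integer_,
                o3 = NA_integer_, status = "ambiguous"))
  }
  list(mature_id = best$mature_id, o5 = as.integer(best$o5),
       o3 = as.integer(best$o3), status = "assigned")
}

# Small helper: wide count table straight from a matrix, with a design.
counts_from_matrix <- function(m, conditions) {
  design <- tibble::tibble(sample_id = colnames(m), condition = conditions)
  ct <- tibble::tibble(
    mature_id = rownames(m) %||% sprintf("m%03d", seq_len(nrow(m))),
    sequence = sprintf("SEQ%03d", seq_len(nrow(m))),
    offset5 = 0L
  )
  for (s in colnames(m)) ct[[s]] <- m[, s]
  attr(ct, "design") <- design
  class(ct) <- c("isomir_counts", class(ct))
  ct
}

`%||%` <- function(a, b) if (is.null(a)) b else a

table1_fixture <- function() {
  read_isomir_table(system.file("extdata", "dn_drosha_isomir_rpm.tsv",
                                package = "isomiRq"))
}
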