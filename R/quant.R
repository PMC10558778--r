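#' Build a per-variant count table from classified read sets
#'
#' Rows are the distinct `(mature_id, sequence)` pairs observed in any
#' sample; columns are samples in design order. Ambiguous and unassigned
#' reads are excluded. Absent observations are 0.
#'
#' @param calls A named list of call tibbles from [classify_reads()];
#'   names are sample ids.
#' @param design A design tibble with `sample_id` and `condition` columns
#'   covering the names of `calls`.
#' @return A tibble of class `isomir_counts` with columns `mature_id`,
#'   `sequence`, `offset5` and one integer column per sample; the design
#'   is attached as attribute `"design"`.
#' @export
build_count_table <- function(calls, design) {
  miss <- setdiff(design$sample_id, names(calls))
  if (length(miss)) {
    stopf("isomirq_design_mismatch",
          "design sample(s) missing from call lists: %s",
          paste(miss, collapse = ", "))
  }
  long <- purrr::imap(calls[design$sample_id], function(x, sid) {
    x |>
      filter(!is.na(.data$mature_id)) |>
      mutate(sample_id = sid) |>
      select("sample_id", "mature_id", sequence = "read_sequence",
             "offset5", "count")
  }) |>
    bind_rows()
  if (nrow(long) == 0L) {
    out <- tibble(mature_id = character(), sequence = character(),
                  offset5 = integer())
    for (s in design$sample_id) out[[s]] <- integer()
  } else {
    out <- long |>
      group_by(.data$sample_id, .data$mature_id, .data$sequence,
               .data$offset5) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                         values_fill = 0L)
    for (s in setdiff(design$sample_id, names(out))) out[[s]] <- 0L
    out <- out |>
      select("mature_id", "sequence", "offset5", all_of(design$sample_id)) |>
      arrange(.data$mature_id, desc(.data$offset5), .data$sequence)
  }
  attr(out, "design") <- design
  class(out) <- c("isomir_counts", class(out))
  out
}

# Sample columns of a count/RPM table.
sample_cols <- function(x, design = NULL) {
  design <- design %||% attr(x, "design")
  if (is.null(design)) {
    setdiff(names(x), c("mature_id", "sequence", "offset5"))
  } else {
    intersect(design$sample_id, names(x))
  }
}

table_design <- function(x, design) {
  design <- design %||% attr(x, "design")
  if (is.null(design)) {
    stopf("isomirq_design_mismatch",
          "no design attached to the table and none supplied")
  }
  design
}

#' Reads-per-million normalization
#'
#' Scales each sample column to reads per million, with the denominator
#' being that sample's classified miRNA total (the column sum), so every
#' non-empty column sums to 1e6. An all-zero column is left at zero with
#' a warning.
#'
#' @param counts An `isomir_counts` table from [build_count_table()] (or
#'   any tibble with `mature_id`/`sequence` keys and sample columns).
#' @param design Optional design tibble; defaults to the attached one.
#' @return A tibble of the same shape with RPM values.
#' @export
to_rpm <- function(counts, design = NULL) {
  design <- design %||% attr(counts, "design")
  sc <- sample_cols(counts, design)
  out <- as_tibble(counts)
  for (s in sc) {
    tot <- sum(out[[s]])
    if (tot > 0) {
      out[[s]] <- out[[s]] * 1e6 / tot
    } else {
      warn(sprintf("sample '%s' has zero classified reads; RPM left at 0",
                   s), class = "isomirq_zero_column")
    }
  }
  attr(out, "design") <- design
  class(out) <- c("isomir_rpm", class(out))
  out
}

#' Per-condition mean of an RPM table
#'
#' Arithmetic mean across the replicate samples of each condition
#' (normalize first, then average).
#'
#' @param rpm An RPM table from [to_rpm()].
#' @param design Optional design tibble; defaults to the attached one.
#' @return A tibble with `mature_id`, `sequence`, `offset5` and one mean
#'   column per condition.
#' @export
group_means <- function(rpm, design = NULL) {
  design <- table_design(rpm, design)
  sc <- sample_cols(rpm, design)
  bad <- setdiff(design$sample_id, sc)
  if (length(bad)) {
    stopf("isomirq_design_mismatch",
          "design sample(s) absent from table: %s",
          paste(bad, collapse = ", "))
  }
  rpm |>
    as_tibble() |>
    tidyr::pivot_longer(all_of(sc), names_to = "sample_id",
                        values_to = "value") |>
    left_join(design[, c("sample_id", "condition")], by = "sample_id") |>
    group_by(.data$mature_id, .data$sequence, .data$offset5,
             .data$condition) |>
    summarise(mean_rpm = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_rpm")
}

#' Case/control abundance ratio
#'
#' The between-condition ratio `case / control` of mean RPM values,
#' undefined (`NA`, rendered `"-"` on output) when the control mean is
#' zero. Vectorized.
#'
#' @param mean_rpm_control,mean_rpm_case Non-negative mean RPM values.
#' @return A numeric vector; `NA` where the control mean is 0.
#' @examples
#' isomir_ratio(1566, 2122)    # ~1.36, prints as 1.4 at one decimal
#' isomir_ratio(2641.9, 223.6) # ~0.085
#' isomir_ratio(0, 7)          # NA (undefined)
#' @export
isomir_ratio <- function(mean_rpm_control, mean_rpm_case) {
  if (any(mean_rpm_control < 0, na.rm = TRUE) ||
      any(mean_rpm_case < 0, na.rm = TRUE)) {
    stopf("isomirq_negative_rpm", "mean RPM values must be >= 0")
  }
  ifelse(mean_rpm_control > 0, mean_rpm_case / mean_rpm_control, NA_real_)
}

#' Condition ratio table of isomiR variants
#'
#' One row per `(mature, sequence)` variant with per-condition mean RPM
#' and the case/control ratio, grouped by mature and ordered with 5'
#' extensions first (descending `offset5`).
#'
#' @param rpm An RPM table from [to_rpm()].
#' @param control_condition,case_condition Condition labels in the design.
#' @param design Optional design tibble; defaults to the attached one.
#' @param digits Optional number of decimals to round the ratio to for
#'   reporting (default `NULL`: full precision).
#' @return A tibble with `mature_id`, `sequence`, `offset5`, `length_nt`,
#'   `mean_rpm_control`, `mean_rpm_case`, `ratio`.
#' @export
ratio_table <- function(rpm, control_condition, case_condition,
                        design = NULL, digits = NULL) {
  design <- table_design(rpm, design)
  for (cc in c(control_condition, case_condition)) {
    if (!cc %in% design$condition) {
      stopf("isomirq_unknown_condition", "condition '%s' not in design", cc)
    }
  }
  gm <- group_means(rpm, design)
  out <- gm |>
    mutate(length_nt = nchar(.data$sequence),
           mean_rpm_control = .data[[control_condition]],
           mean_rpm_case = .data[[case_condition]],
           ratio = isomir_ratio(.data$mean_rpm_control,
                                .data$mean_rpm_case)) |>
    select("mature_id", "sequence", "offset5", "length_nt",
           "mean_rpm_control", "mean_rpm_case", "ratio") |>
    arrange(.data$mature_id, desc(.data$offset5), .data$sequence)
  if (!is.null(digits)) out$ratio <- round(out$ratio, digits)
  out
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample scaling factors from the published TMM recipe. For each
#' sample `s` against the reference `r`, over features positive in both:
#' `M = log2((y_s/N_s)/(y_r/N_r))` and `A = (log2(y_s/N_s) +
#' log2(y_r/N_r))/2`; features in the top/bottom `logratio_trim` of M or
#' top/bottom `sum_trim` of A are discarded; the factor is
#' `2^(sum(w*M)/sum(w))` with inverse delta-method variance weights
#' `w = ((N_s - y_s)/(N_s*y_s) + (N_r - y_r)/(N_r*y_r))^(-1)`. The
#' reference defaults to the sample whose upper-quartile count fraction is
#' closest to the mean upper quartile. Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts An `isomir_counts` table or a numeric matrix
#'   (features x samples).
#' @param reference_sample Optional sample id to use as reference.
#' @param logratio_trim,sum_trim Double-trim fractions (published
#'   defaults 0.3 and 0.05).
#' @return A tibble with `sample_id` and `norm_factor`, geometric mean 1,
#'   with the reference sample id in attribute `"reference_sample"`.
#' @export
tmm_factors <- function(counts, reference_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  if (is.data.frame(counts)) {
    sc <- sample_cols(counts)
    mat <- as.matrix(as_tibble(counts)[, sc])
  } else {
    mat <- as.matrix(counts)
    if (is.null(colnames(mat))) {
      colnames(mat) <- paste0("S", seq_len(ncol(mat)))
    }
  }
  if (ncol(mat) < 2L) {
    stopf("isomirq_bad_input", "TMM needs at least two samples")
  }
  lib <- colSums(mat)
  if (any(lib <= 0)) {
    stopf("isomirq_bad_input", "sample(s) with zero total: %s",
          paste(colnames(mat)[lib <= 0], collapse = ", "))
  }
  if (is.null(reference_sample)) {
    f75 <- vapply(seq_len(ncol(mat)),
                  function(j) quantile(mat[, j] / lib[j], 0.75,
                                       names = FALSE),
                  0)
    ref_j <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_j <- match(reference_sample, colnames(mat))
    if (is.na(ref_j)) {
      stopf("isomirq_bad_input", "reference sample '%s' not found",
            reference_sample)
    }
  }
  yr <- mat[, ref_j]
  nr <- lib[ref_j]
  f <- vapply(seq_len(ncol(mat)), function(j) {
    ys <- mat[, j]
    ns <- lib[j]
    pos <- ys > 0 & yr > 0
    if (!any(pos)) {
      stopf("isomirq_no_shared_features",
            "sample '%s' shares no positive features with the reference",
            colnames(mat)[j])
    }
    ys <- ys[pos]; yrp <- yr[pos]
    m <- log2((ys / ns) / (yrp / nr))
    a <- (log2(ys / ns) + log2(yrp / nr)) / 2
    w <- 1 / ((ns - ys) / (ns * ys) + (nr - yrp) / (nr * yrp))
    nn <- length(m)
    lo_m <- floor(nn * logratio_trim) + 1
    hi_m <- nn + 1 - lo_m
    lo_a <- floor(nn * sum_trim) + 1
    hi_a <- nn + 1 - lo_a
    rm <- rank(m); ra <- rank(a)
    keep <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(keep)) return(1)
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }, 0)
  f <- f / exp(mean(log(f)))
  out <- tibble(sample_id = colnames(mat), norm_factor = f)
  attr(out, "reference_sample") <- colnames(mat)[ref_j]
  out
}
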