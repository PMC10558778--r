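#' Run the full isomiR quantitation pipeline
#'
#' Orchestrates classify -> count -> RPM -> ratio table -> TMM ->
#' differential test -> summary and writes every stage's table to
#' `out_dir` together with a manifest (`manifest.json`) recording the
#' configuration hash, seed and per-stage row counts. Reruns with an
#' identical configuration are byte-identical.
#'
#' @param reference_fasta,annotation Reference hairpin FASTA and mature
#'   annotation TSV (see [load_reference()]).
#' @param design Design TSV path (see [read_design()]) or tibble with
#'   `sample_id`, `condition`, `path`, `format` columns.
#' @param out_dir Output directory, created if needed.
#' @param control_condition,case_condition Condition labels.
#' @param config A [classifier_config()].
#' @param min_len,max_len Read-length filter passed to [load_reads()].
#' @param min_count,fold_threshold,fdr_threshold Differential-test
#'   options (see [de_test()] / [de_summary()]).
#' @param ratio_digits Optional decimals for reported ratios.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when upstream simulation is part of
#'   the run).
#' @param verbose Forwarded to [classify_reads()].
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(reference_fasta, annotation, design, out_dir,
                         control_condition, case_condition,
                         config = classifier_config(),
                         min_len = 18L, max_len = 26L,
                         min_count = 10L, fold_threshold = 2,
                         fdr_threshold = 0.05, ratio_digits = NULL,
                         seed = 1L, verbose = FALSE) {
  for (p in c(reference_fasta, annotation)) {
    if (!file.exists(p)) {
      stopf("isomirq_missing_path", "input path does not exist: %s", p)
    }
  }
  design_tbl <- if (is.data.frame(design)) as_tibble(design)
                else read_design(design)
  if (!all(c("path", "format") %in% names(design_tbl))) {
    stopf("isomirq_bad_schema", "design needs 'path' and 'format' columns")
  }
  missing <- design_tbl$path[!file.exists(design_tbl$path)]
  if (length(missing)) {
    stopf("isomirq_missing_path", "read file(s) not found: %s",
          paste(missing, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ref <- load_reference(reference_fasta, annotation)
  calls <- purrr::pmap(design_tbl, function(sample_id, condition, path,
                                            format, ...) {
    reads <- load_reads(path, format = format, min_len = min_len,
                        max_len = max_len, sample_id = sample_id,
                        condition = condition)
    classify_reads(reads, ref, config, verbose = verbose)
  })
  names(calls) <- design_tbl$sample_id

  counts <- build_count_table(calls, design_tbl)
  rpm <- to_rpm(counts)
  ratios <- ratio_table(rpm, control_condition, case_condition,
                        digits = ratio_digits)
  nf <- tmm_factors(counts)
  de <- de_test(counts, case = case_condition,
                control = control_condition, norm_factors = nf,
                min_count = min_count, fdr_threshold = fdr_threshold)
  summ <- de_summary(de, fold_threshold = fold_threshold,
                     fdr_threshold = fdr_threshold)

  outputs <- list(
    counts = as_tibble(counts),
    rpm = as_tibble(rpm),
    ratio_table = ratios,
    norm_factors = nf,
    de_results = as_tibble(de),
    de_summary = summ
  )
  files <- character()
  for (nm in names(outputs)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write_isomir_table(outputs[[nm]], f)
    files[nm] <- basename(f)
  }
  run_cfg <- list(
    control_condition = control_condition,
    case_condition = case_condition,
    classifier = unclass(config), min_len = min_len, max_len = max_len,
    min_count = min_count, fold_threshold = fold_threshold,
    fdr_threshold = fdr_threshold, ratio_digits = ratio_digits
  )
  manifest <- list(
    config_hash = rlang::hash(run_cfg),
    seed = seed,
    reference = basename(reference_fasta),
    n_samples = nrow(design_tbl),
    outputs = as.list(files),
    stage_rows = lapply(outputs, nrow)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(outputs, list(manifest = manifest, reference = ref,
                            calls = calls)))
}

#' Compute assay quantities for measurement tables
#'
#' Applies the assay formulas to tabular inputs, appending computed
#' columns: IVP activity for band-intensity tables, doubling-time
#' summaries for growth curves, and delta-delta-Ct fold changes for Ct
#' tables with a contrast specification.
#'
#' @param ivp Optional tibble with `pre_signal`, `pri_signal`,
#'   `protein_amount` columns (extra columns are carried through).
#' @param growth Optional tibble with `sample`, `time`, `count` columns;
#'   one fit per sample.
#' @param ct Optional long Ct tibble (`sample`, `target`, `ct`, optional
#'   `replicate`), averaged with [summarise_ct()].
#' @param ct_contrasts Tibble describing the folds to compute: columns
#'   `target`, `reference`, `case`, `control`.
#' @param ct_aggregate `"mean"` or `"median"` replicate aggregation.
#' @return A list with the computed tibbles (`ivp`, `growth`, `ct_folds`);
#'   missing inputs are omitted.
#' @export
run_assays <- function(ivp = NULL, growth = NULL, ct = NULL,
                       ct_contrasts = NULL, ct_aggregate = "mean") {
  out <- list()
  if (!is.null(ivp)) {
    need <- c("pre_signal", "pri_signal", "protein_amount")
    miss <- setdiff(need, names(ivp))
    if (length(miss)) {
      stopf("isomirq_bad_schema", "ivp table lacks column(s): %s",
            paste(miss, collapse = ", "))
    }
    out$ivp <- ivp |>
      mutate(activity = ivp_activity(.data$pre_signal, .data$pri_signal,
                                     .data$protein_amount))
  }
  if (!is.null(growth)) {
    need <- c("sample", "time", "count")
    miss <- setdiff(need, names(growth))
    if (length(miss)) {
      stopf("isomirq_bad_schema", "growth table lacks column(s): %s",
            paste(miss, collapse = ", "))
    }
    out$growth <- growth |>
      group_by(.data$sample) |>
      dplyr::group_modify(function(g, key) {
        glance(doubling_time(g$time, g$count))
      }) |>
      ungroup()
  }
  if (!is.null(ct)) {
    if (is.null(ct_contrasts)) {
      stopf("isomirq_bad_schema",
            "ct table supplied without ct_contrasts")
    }
    need <- c("target", "reference", "case", "control")
    miss <- setdiff(need, names(ct_contrasts))
    if (length(miss)) {
      stopf("isomirq_bad_schema", "ct_contrasts lacks column(s): %s",
            paste(miss, collapse = ", "))
    }
    cts <- summarise_ct(ct, method = ct_aggregate)
    lookup <- function(sample, target) {
      v <- cts$ct[cts$sample == sample & cts$target == target]
      if (length(v) != 1L) {
        stopf("isomirq_bad_schema",
              "no unique Ct for sample '%s', target '%s'", sample, target)
      }
      v
    }
    out$ct_folds <- ct_contrasts |>
      mutate(fold = purrr::pmap_dbl(
        list(.data$target, .data$reference, .data$case, .data$control),
        function(tg, rf, cs, cn) {
          ddct_fold(lookup(cs, tg), lookup(cs, rf),
                    lookup(cn, tg), lookup(cn, rf))
        }))
  }
  out
}
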