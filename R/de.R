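#' Differential-abundance test per mature miRNA
#'
#' Counts are aggregated to the mature level, scaled by TMM-adjusted
#' effective library sizes, and each mature is tested with an exact
#' conditional binomial test on the pooled counts: conditional on the
#' total pooled count, the case share is binomial with success probability
#' equal to the case conditions' share of effective library size. This is
#' a deliberately simple substitute for negative-binomial machinery
#' (edgeR-style dispersion modelling is out of scope): it is exactly
#' calibrated under Poisson within-condition variation and anticonservative
#' under biological overdispersion, which the methods vignette discusses.
#'
#' @param counts An `isomir_counts` table from [build_count_table()].
#' @param case,control Condition labels.
#' @param norm_factors Optional TMM factor tibble from [tmm_factors()];
#'   computed from `counts` when `NULL`.
#' @param design Optional design tibble; defaults to the attached one.
#' @param min_count Matures with pooled raw count below this are not
#'   tested (default 10).
#' @param pseudocount RPM-scale pseudocount added to both group means in
#'   the fold change (default 0.5).
#' @param fdr_threshold BH-FDR cutoff used for the `direction` label
#'   (default 0.05).
#' @return A tibble of class `isomir_de` with `mature_id`, `base_rpm`,
#'   `log2fc` (case vs control), `p_value`, `fdr`, `direction`
#'   (`"down"`, `"up"`, `"unchanged"`).
#' @export
de_test <- function(counts, case, control, norm_factors = NULL,
                    design = NULL, min_count = 10L, pseudocount = 0.5,
                    fdr_threshold = 0.05) {
  design <- table_design(counts, design)
  for (cc in c(case, control)) {
    if (!cc %in% design$condition) {
      stopf("isomirq_unknown_condition", "condition '%s' not in design", cc)
    }
  }
  case_ids <- design$sample_id[design$condition == case]
  ctrl_ids <- design$sample_id[design$condition == control]
  if (!length(case_ids) || !length(ctrl_ids)) {
    stopf("isomirq_degenerate_design", "a group has no samples")
  }
  sc <- c(ctrl_ids, case_ids)
  mat <- as.matrix(as_tibble(counts)[, sc, drop = FALSE])
  lib <- colSums(mat)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  nf <- norm_factors$norm_factor[match(sc, norm_factors$sample_id)]
  eff <- lib * nf

  agg <- rowsum(mat, group = as_tibble(counts)$mature_id)
  mature_id <- rownames(agg)
  total <- rowSums(agg)
  tested <- total >= min_count
  agg <- agg[tested, , drop = FALSE]
  mature_id <- mature_id[tested]
  if (nrow(agg) == 0L) {
    out <- tibble(mature_id = character(), base_rpm = double(),
                  log2fc = double(), p_value = double(), fdr = double(),
                  direction = character())
    class(out) <- c("isomir_de", class(out))
    return(out)
  }

  rpm <- sweep(agg, 2, eff, "/") * 1e6
  mean_case <- rowMeans(rpm[, case_ids, drop = FALSE])
  mean_ctrl <- rowMeans(rpm[, ctrl_ids, drop = FALSE])
  log2fc <- unname(log2((mean_case + pseudocount) /
                          (mean_ctrl + pseudocount)))

  y_case <- rowSums(agg[, case_ids, drop = FALSE])
  y_tot <- rowSums(agg)
  p0 <- sum(eff[match(case_ids, sc)]) / sum(eff)
  p_value <- vapply(seq_along(y_tot), function(i) {
    if (y_tot[i] == 0) return(1)
    binom.test(y_case[i], y_tot[i], p = p0)$p.value
  }, 0)
  fdr <- p.adjust(p_value, method = "BH")
  out <- tibble(
    mature_id = mature_id,
    base_rpm = unname((mean_case + mean_ctrl) / 2),
    log2fc = log2fc, p_value = p_value, fdr = fdr,
    direction = dplyr::case_when(
      fdr < fdr_threshold & log2fc < 0 ~ "down",
      fdr < fdr_threshold & log2fc > 0 ~ "up",
      TRUE ~ "unchanged"
    )
  ) |>
    arrange(.data$p_value)
  attr(out, "case") <- case
  attr(out, "control") <- control
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("isomir_de", class(out))
  out
}

#' Summarise a differential-abundance result
#'
#' Tallies significant matures by direction and fold-change magnitude:
#' `n_de` at `fdr < fdr_threshold`, split into `n_down`/`n_up` by the
#' sign of `log2fc`, with `n_down_gt2fold`/`n_up_gt2fold` counting those
#' also beyond `fold_threshold`. `pct_down`/`pct_up` are percentages of
#' `n_de`; `pct_down_gt2fold` is a percentage of `n_down`.
#'
#' @param de An `isomir_de` tibble from [de_test()] (any tibble with
#'   `log2fc` and `fdr` columns works).
#' @param fold_threshold Fold-change magnitude cutoff (default 2).
#' @param fdr_threshold BH-FDR significance cutoff (default 0.05).
#' @return A one-row tibble with `n_tested`, `n_de`, `n_down`, `n_up`,
#'   `n_down_gt2fold`, `n_up_gt2fold`, `pct_down`, `pct_up`,
#'   `pct_down_gt2fold`.
#' @export
de_summary <- function(de, fold_threshold = 2, fdr_threshold = 0.05) {
  lfc_cut <- log2(fold_threshold)
  sig <- !is.na(de$fdr) & de$fdr < fdr_threshold
  down <- sig & de$log2fc < 0
  up <- sig & de$log2fc > 0
  n_de <- sum(down) + sum(up)
  n_down <- sum(down)
  n_up <- sum(up)
  n_down_gt <- sum(down & abs(de$log2fc) >= lfc_cut)
  n_up_gt <- sum(up & abs(de$log2fc) >= lfc_cut)
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  tibble(
    n_tested = nrow(de), n_de = n_de, n_down = n_down, n_up = n_up,
    n_down_gt2fold = n_down_gt, n_up_gt2fold = n_up_gt,
    pct_down = pct(n_down, n_de), pct_up = pct(n_up, n_de),
    pct_down_gt2fold = pct(n_down_gt, n_down)
  )
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @rdname de_test
#' @param x An `isomir_de` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.isomir_de <- function(x, ...) {
  as_tibble(x)
}

#' @rdname de_test
#' @exportS3Method generics::glance
glance.isomir_de <- function(x, ...) {
  de_summary(x, fdr_threshold = attr(x, "fdr_threshold") %||% 0.05)
}
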