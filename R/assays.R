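#' Relative quantification by the delta-delta-Ct method
#'
#' `fold = 2^(-[(ct_target_case - ct_ref_case) -
#' (ct_target_ctrl - ct_ref_ctrl)])`. The reference target is the
#' normalizer (e.g. GAPDH for mRNA, U6 snRNA for miRNA TaqMan assays).
#' Adding a constant to every Ct leaves the result unchanged. Vectorized.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference in the
#'   case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference in the
#'   control sample.
#' @return Fold change(s), positive reals.
#' @examples
#' ddct_fold(20, 15, 24, 15)  # 16
#' @export
ddct_fold <- function(ct_target_case, ct_ref_case,
                      ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  2^(-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)))
}

#' In vitro processing (IVP) activity
#'
#' Relative Microprocessor activity from gel band intensities: the
#' pre-miRNA product over total substrate plus product, normalized to the
#' enzyme amount: `(pre / (pre + pri)) / protein_amount`. Vectorized.
#'
#' @param pre_signal Pre-miRNA band intensity (>= 0).
#' @param pri_signal Pri-miRNA band intensity (>= 0).
#' @param protein_amount Drosha band intensity (> 0).
#' @return Relative processing activity, in `[0, 1/protein_amount]`.
#' @examples
#' ivp_activity(5, 5, 1)  # 0.5
#' @export
ivp_activity <- function(pre_signal, pri_signal, protein_amount = 1) {
  if (any(pre_signal < 0) || any(pri_signal < 0)) {
    stopf("isomirq_bad_measurement", "band intensities must be >= 0")
  }
  if (any(pre_signal + pri_signal <= 0) || any(protein_amount <= 0)) {
    stopf("isomirq_undefined_measurement",
          "pre + pri must be > 0 and protein amount > 0")
  }
  (pre_signal / (pre_signal + pri_signal)) / protein_amount
}

#' RIP fold enrichment (RBP IP over IgG IP)
#'
#' Target Ct is first normalized to the reference (e.g. GAPDH) within
#' each immunoprecipitate, then the specific-antibody IP is compared with
#' the nonspecific IgG IP: `2^(-[(ct_target_rbp - ct_ref_rbp) -
#' (ct_target_igg - ct_ref_igg)])`. Vectorized.
#'
#' @param ct_target_rbp_ip,ct_ref_rbp_ip Target/reference Ct in the RBP IP.
#' @param ct_target_igg_ip,ct_ref_igg_ip Target/reference Ct in the IgG IP.
#' @return Fold enrichment(s).
#' @export
rip_enrichment <- function(ct_target_rbp_ip, ct_ref_rbp_ip,
                           ct_target_igg_ip, ct_ref_igg_ip) {
  ddct_fold(ct_target_rbp_ip, ct_ref_rbp_ip,
            ct_target_igg_ip, ct_ref_igg_ip)
}

#' ChIP fold enrichment over input
#'
#' The input Ct is first adjusted for the fraction of chromatin saved as
#' input (`ct_input - log2(input_fraction)` represents 100% of input),
#' then `2^(-(ct_ip - adjusted_input))`. The default fraction 0.1 matches
#' the common practice of keeping 1/10 volume as input.
#'
#' @param ct_ip Ct of the immunoprecipitate.
#' @param ct_input Ct of the saved input aliquot.
#' @param input_fraction Fraction of material saved as input, in (0, 1].
#' @return Fold enrichment over input.
#' @export
chip_enrichment <- function(ct_ip, ct_input, input_fraction = 0.1) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stopf("isomirq_bad_measurement", "input_fraction must be in (0, 1]")
  }
  2^(-(ct_ip - (ct_input - log2(input_fraction))))
}

#' Doubling time from a cell-count time course
#'
#' Ordinary least squares of `ln(count)` on time; the growth rate is the
#' slope and the doubling time `Td = ln(2) / rate` when the rate is
#' positive (undefined, `NA`, otherwise). Exact on noiseless exponentials
#' and invariant to rescaling all counts by a constant.
#'
#' @param times Strictly increasing time points in hours (>= 2).
#' @param counts Positive cell counts, same length.
#' @return An object of class `growth_fit`: a list with `rate` (per
#'   hour), `td` (hours or `NA`), `r_squared`, the underlying `lm` fit
#'   and the data. [tidy()] returns the coefficient table, [glance()] a
#'   one-row summary, and `autoplot()` the semi-log growth curve.
#' @examples
#' g <- doubling_time(c(8, 16, 24, 32, 40), 1e5 * 2^(c(8, 16, 24, 32, 40) / 20))
#' glance(g)$td  # 20
#' @export
doubling_time <- function(times, counts) {
  if (length(times) < 2L || length(times) != length(counts)) {
    stopf("isomirq_bad_measurement",
          "need >= 2 time points with matching counts")
  }
  if (any(diff(times) <= 0)) {
    stopf("isomirq_bad_measurement", "times must be strictly increasing")
  }
  if (any(counts <= 0)) {
    stopf("isomirq_bad_measurement", "counts must be positive")
  }
  d <- tibble(time = as.numeric(times), count = as.numeric(counts))
  fit <- lm(log(count) ~ time, data = d)
  rate <- unname(stats::coef(fit)[["time"]])
  # computed directly: summary.lm() warns on the noiseless (perfect) fits
  # this function is routinely applied to
  y <- log(d$count)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  if (!is.finite(r2)) r2 <- NA_real_
  structure(
    list(rate = rate,
         td = if (rate > 0) log(2) / rate else NA_real_,
         r_squared = r2, fit = fit, data = d),
    class = "growth_fit"
  )
}

#' @rdname doubling_time
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname doubling_time
#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tibble(rate = x$rate, td = x$td, r_squared = x$r_squared,
         n = nrow(x$data))
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth fit: rate = %.4g /h, Td = %s h, R2 = %s\n",
              x$rate,
              if (is.na(x$td)) "undefined" else sprintf("%.3g", x$td),
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f",
                                                        x$r_squared)))
  invisible(x)
}

#' Relative distribution between two fractions
#'
#' Splits a signal measured in two compartments (e.g. nucleus vs
#' cytoplasm) into percentages that sum to exactly 100.
#'
#' @param signal_a,signal_b Non-negative signals, not both zero.
#' @return A tibble with `pct_a` and `pct_b` (`pct_b = 100 - pct_a`
#'   exactly).
#' @examples
#' fraction_distribution(36.3, 63.7)
#' @export
fraction_distribution <- function(signal_a, signal_b) {
  if (any(signal_a < 0) || any(signal_b < 0)) {
    stopf("isomirq_bad_measurement", "signals must be >= 0")
  }
  if (any(signal_a + signal_b <= 0)) {
    stopf("isomirq_undefined_measurement", "both signals are zero")
  }
  pct_a <- 100 * signal_a / (signal_a + signal_b)
  tibble(pct_a = pct_a, pct_b = 100 - pct_a)
}

#' Average technical qPCR replicates
#'
#' Collapses a long Ct table (`sample`, `target`, `replicate`, `ct`) to
#' one Ct per sample x target, warning on Ct values outside the usual
#' 5-40 cycle range.
#'
#' @param ct_records A tibble with `sample`, `target` and `ct` columns.
#' @param method `"mean"` (default) or `"median"`.
#' @return A tibble with one `ct` per `(sample, target)`.
#' @export
summarise_ct <- function(ct_records, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(all(c("sample", "target", "ct") %in% names(ct_records)))
  if (any(!is.finite(ct_records$ct))) {
    stopf("isomirq_bad_measurement", "non-finite Ct value(s)")
  }
  if (any(ct_records$ct < 5 | ct_records$ct > 40)) {
    warn("Ct value(s) outside the typical 5-40 cycle range",
         class = "isomirq_ct_range")
  }
  agg <- if (method == "mean") mean else stats::median
  ct_records |>
    group_by(.data$sample, .data$target) |>
    summarise(ct = agg(.data$ct), .groups = "drop")
}
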