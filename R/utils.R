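#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols distinct across
#'   all_of any_of n n_distinct first row_number desc slice rename relocate
#'   pull count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats quantile rbinom rlnorm rmultinom rnbinom rnorm rpois
#'   runif lm p.adjust binom.test setNames
#' @importFrom utils head
NULL

# Uppercase and convert DNA to RNA space (T -> U); all internal sequence
# comparison happens on the result.
as_rna <- function(x) {
  unname(gsub("T", "U", toupper(x), fixed = TRUE))
}

is_rna <- function(x) !grepl("[^ACGU]", x)

stopf <- function(class, msg, ...) {
  abort(sprintf(msg, ...), class = c(class, "isomirq_error"))
}

seed_guard <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(seed)
}
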