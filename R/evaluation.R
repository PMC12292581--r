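#' Final Average Accuracy
#'
#' The unweighted mean of the accuracy matrix's last row: the average
#' test accuracy over all learned tasks after the final task is
#' trained.
#'
#' @param acc lower-triangular accuracy matrix in percent (`NA` above
#'   the diagonal), rows = after-task, columns = on-task.
#' @return scalar FAA in percent.
#' @export
final_average_accuracy <- function(acc) {
  if (is.null(dim(acc))) acc <- matrix(acc, 1)
  if (nrow(acc) == 0L) stop("empty accuracy matrix")
  last <- acc[nrow(acc), ]
  mean(last[!is.na(last)])
}

#' Selection purity
#'
#' Percentage of a selected subset whose stored (noisy) label equals
#' the true label; computable only when truth is available (synthetic
#' mode).
#'
#' @param selected logical or integer selection over the samples.
#' @param clean logical per-sample label-correctness indicator.
#' @return purity in percent; `NA` with a warning for an empty
#'   selection.
#' @export
purity <- function(selected, clean) {
  picked <- clean[selected]
  if (length(picked) == 0L) {
    warning("empty selection: purity undefined")
    return(NA_real_)
  }
  100 * mean(picked)
}

#' Noise-reduction summary
#'
#' Per-level relative reduction of the equivalent (post-selection)
#' noise ratio against the original injected ratio, plus its mean and
#' maximum.
#'
#' @param original,equivalent equal-length positive rate vectors (any
#'   common unit).
#' @return list with `per_level`, `mean`, `max`, all in percent.
#' @export
noise_reduction <- function(original, equivalent) {
  if (length(original) != length(equivalent))
    stop("rate vectors must have equal length")
  if (any(original <= 0)) stop("original rates must be positive")
  per <- 100 * (original - equivalent) / original
  list(per_level = per, mean = mean(per), max = max(per))
}

#' Method-comparison improvement summary
#'
#' Element-wise difference of two FAA curves over a shared noise-rate
#' grid, summarised by mean and maximum improvement.
#'
#' @param faa_a,faa_b FAA values of methods A and B on the same grid.
#' @return list with `diff`, `mean`, `max` (A minus B, percent points).
#' @export
improvement_summary <- function(faa_a, faa_b) {
  if (length(faa_a) != length(faa_b))
    stop("noise-rate grids do not match")
  d <- faa_a - faa_b
  list(diff = d, mean = mean(d), max = max(d))
}

#' Load a packaged benchmark result table
#'
#' The reference benchmark's printed result tables ship as versioned
#' fixture CSVs so aggregate numbers (improvement summaries, purity
#' means, noise-reduction rates) can be recomputed without any
#' training.
#'
#' @param table table number (1-12).
#' @return a data frame (`NA` where the source prints `-`).
#' @export
result_table <- function(table) {
  path <- system.file("extdata",
                      sprintf("table%d.csv", as.integer(table)),
                      package = "dscnl", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

# FAA row of a method in a table-2-style fixture
method_row <- function(tab, method) {
  row <- tab[tab$method == method, -1]
  if (nrow(row) != 1L) stop("method not found: ", method)
  as.numeric(row)
}
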