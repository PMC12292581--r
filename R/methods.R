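#' @export
print.dscnl <- function(x, ...) {
  cat(sprintf("<dscnl> %s run, %d tasks, %d classes\n", x$mode,
              nrow(x$accuracy), length(x$classes_seen)))
  cat(sprintf("  final average accuracy: %.2f%%\n", x$faa))
  if (x$mode == "dscnl")
    cat(sprintf("  mean selection purity: %.2f%%\n",
                mean(x$purity$selection_purity)))
  invisible(x)
}

#' Summarise an incremental run
#'
#' Prints the lower-triangular task-accuracy matrix (rows: state after
#' each task; columns: test accuracy on each earlier task), the final
#' average accuracy, and, for filtered runs, the per-task selection and
#' buffer purities.
#'
#' @param object a fitted [dscnl()] object.
#' @param ... unused.
#' @export
summary.dscnl <- function(object, ...) {
  cat(sprintf("Class-incremental %s run (seed %s)\n", object$mode,
              object$seed))
  cat("\nTask-accuracy matrix (%):\n")
  print(round(object$accuracy, 2), na.print = "-")
  cat(sprintf("\nFinal average accuracy: %.2f%%\n", object$faa))
  if (object$mode == "dscnl") {
    cat("\nPer-task purity:\n")
    print(transform(object$purity,
                    selection_purity = round(selection_purity, 2),
                    buffer_purity = round(buffer_purity, 2)),
          row.names = FALSE)
  }
  invisible(object)
}

#' Predict classes for new images
#'
#' @param object a fitted [dscnl()] object.
#' @param newdata a [labeled_image_dataset()] or an `N x H x W x C`
#'   array.
#' @param type `"class"` for 0-based labels, `"prob"` for the
#'   probability matrix.
#' @param ... unused.
#' @export
predict.dscnl <- function(object, newdata,
                          type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "labeled_image_dataset"))
    as_image_matrix(newdata)
  else matrix(newdata, nrow = dim(newdata)[1])
  p <- predict_backbone(object$model, x, object$classes_seen)
  if (type == "prob") p else max.col(p, ties.method = "first") - 1L
}

#' Plot accuracy trajectories across tasks
#'
#' One line per task: its test accuracy after each subsequent task is
#' learned.  Falling lines show forgetting; flat high lines show
#' retention.
#'
#' @param x a fitted [dscnl()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dscnl <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$accuracy)), x$accuracy, type = "b",
                    pch = 19, lty = 1, xlab = "after task",
                    ylab = "test accuracy (%)", ylim = c(0, 100), ...)
  graphics::legend("bottomleft",
                   legend = paste("task", seq_len(ncol(x$accuracy))),
                   col = seq_len(ncol(x$accuracy)), lty = 1, pch = 19,
                   cex = 0.8)
  invisible(x)
}

#' @export
coef.dscnl <- function(object, ...) object$model$par
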