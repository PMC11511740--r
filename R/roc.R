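#' ROC analysis of a scalar biomarker
#'
#' Every observed score is a candidate cut-off.  The orientation (whether
#' the positive class lies above or below the threshold) is chosen
#' automatically so the area under the curve is at least 0.5, unless given
#' explicitly.  The area is computed by the trapezoidal rule over the full
#' scan, and the optimal cut-off maximises Youden's J = sensitivity +
#' specificity - 1 (ties broken toward higher sensitivity).
#'
#' @param scores numeric biomarker values.
#' @param labels class labels, same length as `scores`.
#' @param positive_class label counted as positive (e.g. the diabetic
#'   nephropathy group).
#' @param direction `">"` if positives score at or above the threshold,
#'   `"<"` if at or below, `"auto"` to pick the orientation with
#'   AUC >= 0.5.
#' @return an object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity` (per threshold), `auc`, `direction`,
#'   `positive_class` and `best` (cut-off value, sensitivity, specificity,
#'   Youden J).
#' @export
roc_analysis <- function(scores, labels, positive_class,
                         direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) stop("both classes must be non-empty")
  scan <- function(dir) {
    th <- sort(unique(scores))
    sens <- spec <- numeric(length(th))
    for (i in seq_along(th)) {
      called_pos <- if (dir == ">") scores >= th[i] else scores <= th[i]
      sens[i] <- mean(called_pos[pos])
      spec[i] <- mean(!called_pos[!pos])
    }
    # close the curve at both ends for the trapezoid
    fpr <- 1 - spec
    ord <- order(fpr, sens)
    x <- c(0, fpr[ord], 1)
    y <- c(0, sens[ord], 1)
    auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    list(th = th, sens = sens, spec = spec, auc = auc, dir = dir)
  }
  sc <- if (direction == "auto") {
    a <- scan(">")
    if (a$auc >= 0.5) a else scan("<")
  } else {
    scan(direction)
  }
  j <- sc$sens + sc$spec - 1
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  best <- cand[which.max(sc$sens[cand])]
  structure(list(thresholds = sc$th, sensitivity = sc$sens,
                 specificity = sc$spec, auc = sc$auc, direction = sc$dir,
                 positive_class = positive_class,
                 best = list(cutoff = sc$th[best],
                             sensitivity = sc$sens[best],
                             specificity = sc$spec[best],
                             youden_j = j[best])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC %.3f (direction %s, positive = %s); ",
                     "best cut-off %.4g (sens %.2f, spec %.2f, J %.2f)\n"),
              x$auc, x$direction, x$positive_class, x$best$cutoff,
              x$best$sensitivity, x$best$specificity, x$best$youden_j))
  invisible(x)
}

#' Descriptive statistics with Tukey outliers per group
#'
#' Mean, population SD, median, linear-interpolation (type-7) quartiles,
#' IQR and the outliers outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#'
#' @param values numeric vector.
#' @param groups optional grouping (factor/character); a single group when
#'   omitted.
#' @return data.frame with one row per group and a list-column `outliers`.
#' @export
summarize_groups <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(values))
  stopifnot(length(values) == length(groups), length(values) > 0)
  out <- lapply(split(values, groups), function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    outl <- x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr]
    data.frame(n = length(x), mean = mean(x),
               sd = sqrt(mean((x - mean(x))^2)),
               median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
               n_outliers = length(outl),
               outliers = I(list(outl)))
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}
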