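# Task losses and evaluation metrics for nutrition and depth estimation.
#
# Conventions: nutrition predictions and ground truths are numeric vectors
# aligned by dish; depth maps are numeric matrices/arrays in centimeters,
# the ground truth strictly positive on the valid mask. PMAE normalizes MAE
# by the mean ground-truth value and is reported in percent; depth accuracy
# uses the usual max-ratio thresholds 1.25, 1.25^2, 1.25^3.

NUTRIENTS <- c("calories", "mass", "fat", "carb", "protein")

#' Mean absolute error task loss
#'
#' Per-task L1 loss: the mean absolute difference between estimated and
#' ground-truth nutrient values over a batch.
#'
#' @param pred numeric vector of predictions
#' @param truth numeric vector of ground truths, same length
#' @return non-negative scalar
#' @examples
#' l1_task_loss(c(1, 2, 3), c(1, 2, 3))   # 0
#' l1_task_loss(c(4, 5), c(1, 2))         # 3
#' @export
l1_task_loss <- function(pred, truth) {
  if (length(pred) == 0L || length(truth) == 0L)
    stop("l1_task_loss: empty input")
  if (length(pred) != length(truth))
    stop("l1_task_loss: length mismatch")
  mean(abs(pred - truth))
}

#' Geometric combination of task losses
#'
#' The k-th root of the product of k per-task losses (k = 5 for the five
#' nutrition tasks), computed in log space for numerical stability. The
#' geometric mean is invariant to the relative scale of the individual
#' losses, so no task can dominate training merely because its target has
#' larger units. Losses at or below `eps` are clamped to `eps` with a
#' warning: an exactly zero factor would zero the gradient of every other
#' task through the product.
#'
#' @param losses numeric vector of per-task losses (typically length 5)
#' @param eps clamp floor, default 1e-8
#' @return scalar geometric mean
#' @examples
#' geometric_loss(c(1, 2, 4, 8, 16))  # 4
#' @export
geometric_loss <- function(losses, eps = 1e-8) {
  if (length(losses) == 0L) stop("geometric_loss: empty input")
  if (any(losses <= eps)) {
    warning("geometric_loss: task loss clamped to ", eps, call. = FALSE)
    losses <- pmax(losses, eps)
  }
  exp(mean(log(losses)))
}

#' Mean absolute error
#'
#' @param pred numeric vector of predictions
#' @param truth numeric vector of ground truths
#' @return scalar MAE in the units of the inputs (kCal or g)
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("mae: length mismatch")
  if (length(pred) == 0L) stop("mae: empty input")
  mean(abs(pred - truth))
}

#' Percentage mean absolute error
#'
#' MAE divided by the mean ground-truth value, in percent. Unitless, so
#' errors on calories (hundreds of kCal) and fat (a few grams) are
#' comparable.
#'
#' @param pred numeric vector of predictions
#' @param truth numeric vector of ground truths with positive mean
#' @return scalar PMAE in percent
#' @examples
#' pmae(c(110, 190), c(100, 200))  # 6.6667
#' @export
pmae <- function(pred, truth) {
  m <- mean(truth)
  if (!is.finite(m) || m <= 0) stop("pmae: mean of ground truth must be > 0")
  100 * mae(pred, truth) / m
}

#' Depth evaluation metrics
#'
#' Computes the standard monocular-depth metrics between predicted and
#' ground-truth depth over a valid mask: absolute relative error
#' (mean |d - d'| / d, normalized by the ground truth d), root mean squared
#' error, and threshold accuracies (the fraction of pixels whose
#' max(d/d', d'/d) is strictly below each threshold; pixels exactly at a
#' threshold do not count as accurate).
#'
#' @param pred predicted depth (numeric array/matrix, cm)
#' @param gt ground-truth depth, same shape, positive on the mask
#' @param mask logical array of valid pixels (default: all)
#' @param thresholds accuracy thresholds, default 1.25^(1:3)
#' @return list with `absrel`, `rmse` and `delta` (named numeric vector)
#' @export
depth_metrics <- function(pred, gt, mask = NULL, thresholds = 1.25^(1:3)) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt)))
    stop("depth_metrics: shape mismatch")
  p <- as.vector(pred)
  d <- as.vector(gt)
  keep <- if (is.null(mask)) rep(TRUE, length(d)) else as.vector(mask)
  if (!any(keep)) stop("depth_metrics: empty valid mask")
  p <- p[keep]; d <- d[keep]
  if (any(d <= 0)) stop("depth_metrics: ground truth must be positive on the mask")
  absrel <- mean(abs(d - p) / d)
  rmse <- sqrt(mean((d - p)^2))
  ratio <- pmax(d / p, p / d)
  delta <- vapply(thresholds, function(thr) mean(ratio < thr), 0)
  names(delta) <- paste0("delta_", seq_along(thresholds))
  list(absrel = absrel, rmse = rmse, delta = delta)
}

#' Build a nutrition (and optional depth) metrics report
#'
#' Computes per-nutrient MAE and PMAE, their mean PMAE, and optionally the
#' depth metrics block, laid out in the conventional reporting order
#' (calories, mass, fat, carb, protein).
#'
#' @param predictions matrix/data.frame with one row per dish and columns
#'   calories, mass, fat, carb, protein
#' @param truths same layout as `predictions`; row order must align. If both
#'   carry a `dish_id` column/rownames they are checked for alignment.
#' @param depth_pairs optional list of `list(pred = , gt = , mask = )` depth
#'   map pairs to aggregate into a depth metrics block
#' @return object of class `nutrition_report`: list with `table` (data.frame
#'   rows = nutrients, columns mae/pmae), `mean_pmae`, and optionally `depth`
#' @export
build_report <- function(predictions, truths, depth_pairs = NULL) {
  predictions <- as.data.frame(predictions)
  truths <- as.data.frame(truths)
  if ("dish_id" %in% names(predictions) && "dish_id" %in% names(truths)) {
    if (!identical(as.character(predictions$dish_id), as.character(truths$dish_id)))
      stop("build_report: dish ids are misaligned")
  }
  missing_cols <- setdiff(NUTRIENTS, names(predictions))
  if (length(missing_cols))
    stop("build_report: missing prediction columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(predictions) != nrow(truths))
    stop("build_report: row count mismatch")
  tab <- data.frame(
    nutrient = NUTRIENTS,
    mae = vapply(NUTRIENTS, function(k) mae(predictions[[k]], truths[[k]]), 0),
    pmae = vapply(NUTRIENTS, function(k) pmae(predictions[[k]], truths[[k]]), 0),
    row.names = NULL
  )
  rep <- list(table = tab, mean_pmae = mean(tab$pmae))
  if (!is.null(depth_pairs)) {
    pr <- unlist(lapply(depth_pairs, function(d) {
      keep <- if (is.null(d$mask)) rep(TRUE, length(d$pred)) else as.vector(d$mask)
      as.vector(d$pred)[keep]
    }))
    gt <- unlist(lapply(depth_pairs, function(d) {
      keep <- if (is.null(d$mask)) rep(TRUE, length(d$gt)) else as.vector(d$mask)
      as.vector(d$gt)[keep]
    }))
    rep$depth <- depth_metrics(pr, gt)
  }
  class(rep) <- "nutrition_report"
  rep
}

#' @export
print.nutrition_report <- function(x, ...) {
  cat("Nutrition estimation report\n")
  tab <- x$table
  tab$mae <- sprintf("%.2f", tab$mae)
  tab$pmae <- sprintf("%.1f%%", tab$pmae)
  print(tab, row.names = FALSE)
  cat(sprintf("mean PMAE: %.1f%%\n", x$mean_pmae))
  if (!is.null(x$depth)) {
    cat(sprintf("depth: AbsRel %.3f  RMSE %.3f  delta %.3f/%.3f/%.3f\n",
                x$depth$absrel, x$depth$rmse,
                x$depth$delta[1], x$depth$delta[2], x$depth$delta[3]))
  }
  invisible(x)
}

#' Flatten a report into a single named row (reporting column order)
#' @param report a `nutrition_report`
#' @return named numeric vector calories_mae, calories_pmae, ..., mean_pmae
#' @export
report_row <- function(report) {
  tab <- report$table
  out <- numeric(0)
  for (i in seq_len(nrow(tab))) {
    v <- c(tab$mae[i], tab$pmae[i])
    names(v) <- paste0(tab$nutrient[i], c("_mae", "_pmae"))
    out <- c(out, v)
  }
  c(out, mean_pmae = report$mean_pmae)
}

#' Write a report to CSV and JSON
#' @param report a `nutrition_report`
#' @param path output path without extension; writes `<path>.csv` and
#'   `<path>.json`
#' @return invisible paths written
#' @export
write_report <- function(report, path) {
  row <- report_row(report)
  csv <- paste0(path, ".csv")
  df <- as.data.frame(as.list(row), check.names = FALSE)
  utils::write.csv(df, csv, row.names = FALSE)
  js <- paste0(path, ".json")
  payload <- as.list(row)
  if (!is.null(report$depth)) {
    payload$depth <- list(absrel = report$depth$absrel, rmse = report$depth$rmse,
                          delta = as.list(report$depth$delta))
  }
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
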