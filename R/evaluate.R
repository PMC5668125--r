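# Evaluation machinery: expert-vote aggregation, per-class one-vs-rest
# metrics, per-stratum (cell-line style) breakdowns, detector-vs-truth
# agreement.

#' Aggregate multi-rater labels for one item
#'
#' The most frequent label wins; if several labels tie for the top count,
#' the lowest-quality one among them is chosen (conservative rule: a
#' disputed region is graded down).
#'
#' @param ratings vector of quality labels (>= 1) for one item.
#' @return ordered factor of length 1.
#' @export
#' @examples
#' aggregateLabels(c("good", "good", "mod", "poor"))  # good
#' aggregateLabels(c("good", "good", "mod", "mod"))   # mod (tie -> lower)
aggregateLabels <- function(ratings) {
  y <- qualityFactor(ratings)
  if (length(y) == 0L || anyNA(y)) stop("need at least one valid rating")
  counts <- table(y)
  counts <- counts[counts > 0]
  top <- names(counts)[counts == max(counts)]
  qualityFactor(top[which.min(match(top, qualityLevels()))])
}

#' Aggregate a multi-rater label table
#'
#' Applies [aggregateLabels()] per `tile_id` of a `tile_id,rater,label`
#' table.
#'
#' @param ratings data.frame with columns `tile_id` and `label`.
#' @return data.frame `tile_id,label` with one aggregated label per item,
#'   in first-appearance order of `tile_id`.
#' @export
aggregateLabelTable <- function(ratings) {
  stopifnot(all(c("tile_id", "label") %in% names(ratings)))
  ids <- unique(ratings$tile_id)
  lab <- vapply(ids, function(id) {
    as.character(aggregateLabels(ratings$label[ratings$tile_id == id]))
  }, character(1))
  data.frame(tile_id = ids, label = qualityFactor(lab))
}

#' Confusion matrix and per-class metrics
#'
#' Builds the 3 x 3 confusion matrix (rows = truth, columns = prediction,
#' class order poor/mod/good) and per-class one-vs-rest metrics:
#' precision, recall, F-measure and one-vs-rest accuracy
#' `(TP + TN) / N`. Metrics with a zero denominator are reported as 0
#' with a warning so batch evaluation never aborts.
#'
#' @param truth,pred aligned label vectors.
#' @return list with `confusion` (3 x 3 integer matrix) and `metrics`
#'   (data.frame `class,support,accuracy,precision,recall,f_measure`).
#' @export
confusionAndMetrics <- function(truth, pred) {
  truth <- qualityFactor(truth)
  pred <- qualityFactor(pred)
  if (length(truth) != length(pred))
    stop("truth (", length(truth), ") and pred (", length(pred),
         ") must have equal length")
  lev <- qualityLevels()
  cm <- table(truth = truth, pred = pred)
  cm <- unclass(cm)[lev, lev]
  n <- length(truth)
  rows <- lapply(lev, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    tn <- n - tp - fp - fn
    div <- function(num, den, what) {
      if (den == 0) {
        warning(what, " undefined for class '", cl, "' (zero denominator); ",
                "reported as 0", call. = FALSE)
        return(0)
      }
      num / den
    }
    p <- div(tp, tp + fp, "precision")
    r <- div(tp, tp + fn, "recall")
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = cl, support = tp + fn, accuracy = (tp + tn) / n,
               precision = p, recall = r, f_measure = f)
  })
  list(confusion = cm, metrics = do.call(rbind, rows))
}

#' Per-stratum evaluation
#'
#' Applies [confusionAndMetrics()] within each stratum (the strata stand
#' in for cell lines in the original design).
#'
#' @param truth,pred aligned label vectors.
#' @param strata per-item stratum identifiers.
#' @return named list of [confusionAndMetrics()] results, one per
#'   stratum, in first-appearance order.
#' @export
stratifiedMetrics <- function(truth, pred, strata) {
  if (length(strata) != length(truth))
    stop("strata must align with truth/pred")
  if (anyNA(strata)) stop("unknown (NA) stratum id")
  out <- list()
  for (s in unique(strata)) {
    i <- strata == s
    out[[as.character(s)]] <- confusionAndMetrics(truth[i], pred[i])
  }
  out
}

#' Detector-vs-truth agreement
#'
#' Coefficient of determination (R^2) of the least-squares regression of
#' detected values on true values — the agreement statistic between an
#' automatic detector and the reference annotation. (For a simple linear
#' regression this equals the squared Pearson correlation; the regression
#' formulation is stated for clarity.)
#'
#' @param detected,truth aligned numeric vectors, length >= 3.
#' @return R^2 in [0, 1], or NA (with a warning) when the truth has zero
#'   variance.
#' @export
detectorAgreement <- function(detected, truth) {
  if (length(detected) != length(truth)) stop("lengths must match")
  if (length(truth) < 3L) stop("need at least 3 pairs")
  if (var(truth) == 0) {
    warning("truth has zero variance; R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  if (var(detected) == 0) return(0)
  fit <- lm(detected ~ truth)
  1 - sum(fit$residuals^2) / sum((detected - mean(detected))^2)
}

#' Write an evaluation report as JSON
#'
#' Pooled and (optionally) per-stratum confusion matrices and per-class
#' metric blocks.
#'
#' @param truth,pred aligned label vectors.
#' @param strata optional per-item stratum ids.
#' @param path output JSON path.
#' @return the report list, invisibly.
#' @export
writeEvaluationReport <- function(truth, pred, path, strata = NULL) {
  pooled <- confusionAndMetrics(truth, pred)
  report <- list(pooled = list(confusion = pooled$confusion,
                               metrics = pooled$metrics))
  if (!is.null(strata)) {
    report$strata <- lapply(stratifiedMetrics(truth, pred, strata),
                            function(x) list(confusion = x$confusion,
                                             metrics = x$metrics))
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(report)
}
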