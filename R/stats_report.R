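#' Aggregate fold metrics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' metric column across folds.
#'
#' @param rows data.frame of per-fold metrics with a \code{fold} column and
#'   one column per metric (e.g. \code{acc_p}, \code{iou}, \code{dsc}).
#' @return data.frame with columns \code{metric}, \code{mean}, \code{sd}.
#' @examples
#' rows <- data.frame(fold = 1:5, iou = c(72.4, 76.3, 75.2, 73.0, 74.8))
#' aggregateFolds(rows)  # mean 74.34
#' @export
aggregateFolds <- function(rows) {
  if (nrow(rows) < 2) stop("need at least 2 folds to aggregate")
  metrics <- setdiff(names(rows), c("fold", "model"))
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(rows[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(rows[[m]]), numeric(1)),
    row.names = NULL)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired test on \code{a - b}. Zero differences are dropped (with a
#' warning); absolute differences are ranked (average ranks for ties) and
#' the p-value is computed exactly by enumerating all \code{2^n} sign
#' assignments of the rank statistic — no normal approximation. For n = 5
#' with all differences of one sign the one-sided p is 1/32 = 0.03125.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param alternative "greater" (default; tests whether \code{a} exceeds
#'   \code{b}), "less", or "two.sided".
#' @return List with the signed-rank statistic \code{statistic} (sum of
#'   positive-difference ranks), \code{n} used, and \code{p.value}.
#' @export
wilcoxonExact <- function(a, b, alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  if (any(d == 0)) {
    warning(sum(d == 0), " zero difference(s) dropped")
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0) stop("degenerate data: all differences are zero")
  if (n > 20) stop("exact enumeration limited to n <= 20")
  r <- rank(abs(d))
  wPlus <- sum(r[d > 0])
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)  # all 2^n subset sums
  pGreater <- mean(sums >= wPlus)
  pLess <- mean(sums <= wPlus)
  p <- switch(alternative,
    greater = pGreater,
    less = pLess,
    two.sided = min(1, 2 * min(pGreater, pLess)))
  list(statistic = wPlus, n = n, p.value = p)
}

#' Compare fold tables of several models
#'
#' Produces per-model mean +/- sd for every metric and, for every model
#' pair, the exact one-sided Wilcoxon signed-rank p-value on the fold-wise
#' metric values (alternative: the later-listed model exceeds the earlier).
#'
#' @param tables Named list of per-fold metric data.frames (same metric
#'   columns, same fold count).
#' @param alternative Passed to \code{\link{wilcoxonExact}}; the first
#'   argument of each test is the later model in list order.
#' @return List with data.frames \code{summary} (model, metric, mean, sd)
#'   and \code{tests} (model_a, model_b, metric, p_value; empty with a
#'   single table).
#' @export
comparisonReport <- function(tables, alternative = "greater") {
  if (length(tables) < 1) stop("need at least one fold table")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("model", seq_along(tables))
  summ <- do.call(rbind, lapply(names(tables), function(nm) {
    agg <- aggregateFolds(tables[[nm]])
    cbind(model = nm, agg)
  }))
  tests <- data.frame(model_a = character(), model_b = character(),
    metric = character(), p_value = numeric())
  nms <- names(tables)
  if (length(nms) >= 2) {
    metrics <- setdiff(names(tables[[1]]), c("fold", "model"))
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      for (m in metrics) {
        wt <- wilcoxonExact(tables[[nms[j]]][[m]], tables[[nms[i]]][[m]],
                            alternative)
        tests <- rbind(tests, data.frame(model_a = nms[j],
          model_b = nms[i], metric = m, p_value = wt$p.value))
      }
    }
  }
  list(summary = summ, tests = tests)
}

#' Published per-fold benchmark metrics
#'
#' Per-fold pixel accuracy, IoU and DSC (percent) reported for the BUSI
#' benchmark by the five desk-reproducible configurations: the GSU-Net
#' baseline, the Roberts-based DBU-Net with the hybrid loss, the Prewitt and
#' Sobel DBU-Net variants, and the Roberts DBU-Net trained with dice loss
#' alone. Shipped so the aggregation and testing arithmetic can be verified
#' without any training run.
#'
#' @return data.frame with columns \code{model}, \code{fold}, \code{acc_p},
#'   \code{iou}, \code{dsc}.
#' @export
busiFoldMetrics <- function() {
  path <- system.file("extdata", "busi_fold_metrics.csv", package = "dbunet",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
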