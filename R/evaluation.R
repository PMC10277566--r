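# Metrics and statistical comparison: accuracy, confusion matrices, the
# Wilcoxon signed-rank test for paired per-subject accuracies, and report
# tables.

#' Classification accuracy (percent)
#'
#' @param pred,truth equal-length 0-based label vectors.
#' @return `100 * correct / total`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0) stop("empty prediction vector")
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  100 * mean(pred == truth)
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, entries counts.
#'
#' @param pred,truth 0-based label vectors.
#' @param n_classes number of classes.
#' @return Integer `n_classes` x `n_classes` matrix.
#' @export
confusion <- function(pred, truth, n_classes) {
  if (any(c(pred, truth) < 0 | c(pred, truth) >= n_classes))
    stop("labels outside [0, n_classes)")
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1),
                              pred = 0:(n_classes - 1)))
  for (i in seq_along(pred))
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  m
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test on `a - b`. Zero differences are dropped; ranks of
#' `|d|` use midranks for ties. The p-value is exact for n <= 25 (the full
#' signed-rank null distribution, ties included, by convolution), and a
#' normal approximation with tie correction and continuity correction
#' beyond. With all differences zero the test is degenerate and no p-value
#' is produced.
#'
#' @param a,b equal-length paired numeric vectors.
#' @return list with `statistic` (V, sum of positive ranks), `p_value`
#'   (NA when degenerate), `n_used` and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = 0L,
                method = "degenerate: all differences zero"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    # exact two-sided p, ties allowed: the null distribution of V over all
    # 2^n sign assignments via a convolution over doubled midranks
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1)  # counts[v+1] = #assignments with 2V = v
    counts[1] <- 1
    for (ri in r2)
      counts <- counts + c(numeric(ri), counts[seq_len(length(counts) - ri)])
    v_all <- seq_along(counts) - 1
    mu2 <- n * (n + 1) / 2          # doubled mean
    p <- sum(counts[abs(v_all - mu2) >= abs(2 * V - mu2) - 1e-9]) / 2^n
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n_used = n, method = method)
}

#' Per-seed evaluation result
#'
#' @param subject subject identifier.
#' @param method method label (e.g. `"backbone"`, `"lrp"`).
#' @param seed_accuracies per-seed test accuracies in percent.
#' @param confusion confusion matrix summed over seeds (optional).
#' @param extra optional list of additional fields (e.g. backbone-only
#'   accuracies).
#' @return An `eval_result` list with `mean` and `sd` filled in.
#' @export
eval_result <- function(subject, method, seed_accuracies, confusion = NULL,
                        extra = list()) {
  if (any(seed_accuracies < 0 | seed_accuracies > 100))
    stop("accuracies must lie in [0, 100]")
  structure(c(list(subject = subject, method = method,
                   seed_accuracies = seed_accuracies,
                   mean = mean(seed_accuracies),
                   sd = stats::sd(seed_accuracies),
                   confusion = confusion), extra),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> subject %s, %s: %.2f +/- %.2f %% (%d seeds)\n",
              x$subject, x$method, x$mean,
              if (is.na(x$sd)) 0 else x$sd, length(x$seed_accuracies)))
  invisible(x)
}

#' Report tables across subjects and methods
#'
#' Builds the per-subject accuracy table (subjects in columns, methods in
#' rows, cells are seed means), appends the across-subject mean, and computes
#' pairwise Wilcoxon signed-rank p-values between methods on the paired
#' per-subject seed means. Missing (subject, method) cells are flagged.
#'
#' @param results list of `eval_result` objects.
#' @param out_file optional path; the accuracy table is written there as
#'   tab-delimited text.
#' @return list with `table` (data.frame), `p_values` (method x method
#'   matrix), `missing` (character vector of absent cells).
#' @export
report_tables <- function(results, out_file = NULL) {
  subjects <- unique(vapply(results, `[[`, character(1), "subject"))
  methods <- unique(vapply(results, `[[`, character(1), "method"))
  acc <- matrix(NA_real_, length(methods), length(subjects),
                dimnames = list(methods, subjects))
  for (r in results) acc[r$method, r$subject] <- r$mean
  missing <- character(0)
  for (m in methods) for (s in subjects)
    if (is.na(acc[m, s])) missing <- c(missing, paste(m, s, sep = "/"))
  if (length(missing) > 0)
    warning("missing cells: ", paste(missing, collapse = ", "))
  tab <- data.frame(method = methods, acc,
                    mean = rowMeans(acc, na.rm = TRUE),
                    check.names = FALSE, row.names = NULL)
  p <- matrix(NA_real_, length(methods), length(methods),
              dimnames = list(methods, methods))
  if (length(subjects) >= 2) {
    for (i in seq_along(methods)) for (j in seq_along(methods)) {
      if (i == j) next
      ok <- !is.na(acc[i, ]) & !is.na(acc[j, ])
      if (sum(ok) >= 2)
        p[i, j] <- wilcoxon_signed_rank(acc[i, ok], acc[j, ok])$p_value
    }
  }
  if (!is.null(out_file)) {
    dir.create(dirname(out_file), recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab, out_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  list(table = tab, p_values = p, missing = missing)
}
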