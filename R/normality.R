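#' Standard errors of skewness and kurtosis
#'
#' Exact small-sample standard errors used alongside the SPSS-convention
#' adjusted skewness (G1) and excess kurtosis (G2):
#' `SE_skew = sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))` and
#' `SE_kurt = 2 SE_skew sqrt((n^2 - 1) / ((n-3)(n+5)))`.
#'
#' @param n sample size (`n >= 3` for skewness, `n >= 4` for kurtosis).
#' @return numeric standard error (`NA` below the minimum `n`).
#' @export
skewness_se <- function(n) {
  ifelse(n >= 3, sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3))), NA_real_)
}

#' @rdname skewness_se
#' @export
kurtosis_se <- function(n) {
  ifelse(n >= 4,
         2 * skewness_se(n) * sqrt((n^2 - 1) / ((n - 3) * (n + 5))), NA_real_)
}

#' Per-time-point normality diagnostics
#'
#' For each time point, computes the Shapiro-Wilk statistic and p-value,
#' the adjusted sample skewness and excess kurtosis (SPSS convention,
#' via \pkg{e1071} type 2) with their small-sample standard errors and
#' z-values (statistic / SE), across entities. This mirrors the usual
#' pre-correlation sanity check on time-series omics data: the report is a
#' diagnostic gate only; the pipeline records it and proceeds regardless.
#'
#' @param x a [fold_change()] object (log2 fold changes are tested), a
#'   [timecourse()] object (replicate means are tested) or a numeric
#'   matrix with time columns.
#' @param plot_dir optional directory; when given, histogram, normal Q-Q
#'   and box plots are written there as PNG files per time point.
#' @return data frame of class `normality_report`: `time`, `n`,
#'   `shapiro_W`, `shapiro_p`, `skewness`, `se_skew`, `z_skew`,
#'   `kurtosis`, `se_kurt`, `z_kurt`, `note`. Fields that cannot be
#'   computed (n too small, or outside the 3..5000 Shapiro-Wilk range) are
#'   `NA` with the reason in `note`.
#' @export
normality_report <- function(x, plot_dir = NULL) {
  m <- if (inherits(x, "foldchange")) x$log2fc
       else if (inherits(x, "timecourse")) tc_means(x)
       else as.matrix(x)
  times <- suppressWarnings(as.numeric(colnames(m) %||% seq_len(ncol(m))))
  if (!is.null(plot_dir)) dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]; v <- v[is.finite(v)]
    n <- length(v)
    note <- ""
    sw <- c(NA_real_, NA_real_)
    if (n >= 3 && n <= 5000) {
      t <- shapiro.test(v); sw <- c(unname(t$statistic), t$p.value)
    } else note <- "n outside Shapiro-Wilk range"
    sk <- if (n >= 3) e1071::skewness(v, type = 2) else NA_real_
    ku <- if (n >= 4) e1071::kurtosis(v, type = 2) else NA_real_
    if (n < 4 && !nzchar(note)) note <- "n too small for kurtosis"
    ses <- skewness_se(n); sek <- kurtosis_se(n)
    if (!is.null(plot_dir)) {
      fn <- file.path(plot_dir, sprintf("normality_t%s.png", times[j]))
      grDevices::png(fn, width = 900, height = 320)
      op <- graphics::par(mfrow = c(1, 3))
      graphics::hist(v, main = sprintf("t = %s h", times[j]), xlab = "value")
      stats::qqnorm(v, main = "normal Q-Q"); stats::qqline(v)
      graphics::boxplot(v, main = "box plot")
      graphics::par(op)
      grDevices::dev.off()
    }
    data.frame(time = times[j], n = n, shapiro_W = sw[1], shapiro_p = sw[2],
               skewness = sk, se_skew = ses, z_skew = sk / ses,
               kurtosis = ku, se_kurt = sek, z_kurt = ku / sek,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("normality_report", "data.frame")
  out
}
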