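#' Time-lagged Pearson correlation between two series
#'
#' For each candidate lag `l` (in sampling steps; positive means `x`
#' leads `y`), pairs `x[i]` with `y[i + l]` over the overlapping indices,
#' computes the Pearson correlation on complete pairs, and returns the lag
#' maximising `|r|` (ties broken towards the smaller absolute lag, then
#' the smaller lag). The p-value is the usual two-sided t transform,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom;
#' perfectly collinear pairs get `p = 0`.
#'
#' Lags act on grid positions, not hours: the sampling grid of this kind
#' of experiment is deliberately uneven (dense early, sparse late), so a
#' one-step lag spans half an hour early on and twelve hours late. This
#' is the intended reading of a "time-lagged" correlation on such grids.
#'
#' @param x,y numeric series on a shared time grid.
#' @param lag_set integer lags to evaluate.
#' @param min_overlap minimum complete pairs for a lag to be eligible.
#' @return list with `r`, `lag`, `n_pairs`, `p`.
#' @examples
#' lagged_pearson(1:7, (1:7) * 2 + 1)           # r = 1 at lag 0
#' lagged_pearson(1:7, c(NA, 1:6), lag_set = 0:1) # forced lag 1
#' @export
lagged_pearson <- function(x, y, lag_set = c(0L, 1L), min_overlap = 5L) {
  stopifnot(length(x) == length(y))
  if (sd(x, na.rm = TRUE) == 0 || sd(y, na.rm = TRUE) == 0 ||
      is.na(sd(x, na.rm = TRUE)) || is.na(sd(y, na.rm = TRUE)))
    stop_("zero variance")
  n <- length(x)
  best <- NULL
  for (l in as.integer(lag_set)) {
    i <- seq_len(n - abs(l))
    xi <- if (l >= 0) i else i - l
    yi <- if (l >= 0) i + l else i
    ok <- complete.cases(x[xi], y[yi])
    np <- sum(ok)
    if (np < min_overlap) next
    xs <- x[xi][ok]; ys <- y[yi][ok]
    if (sd(xs) == 0 || sd(ys) == 0) next
    r <- cor(xs, ys)
    cand <- list(r = r, lag = l, n_pairs = np, p = cor_pvalue(r, np))
    if (is.null(best) ||
        abs(cand$r) > abs(best$r) + 1e-15 ||
        (abs(abs(cand$r) - abs(best$r)) <= 1e-15 &&
         (abs(l) < abs(best$lag) || (abs(l) == abs(best$lag) && l < best$lag))))
      best <- cand
  }
  if (is.null(best)) stop_("overlap below minimum")
  best
}

## two-sided p for a Pearson r on np pairs; exact collinearity -> 0
cor_pvalue <- function(r, np) {
  if (np < 3) return(NA_real_)
  d <- 1 - r^2
  if (d <= 0) return(0)
  2 * pt(-abs(r) * sqrt((np - 2) / d), np - 2)
}

#' Correlate all regulator-target pairs and call signed edges
#'
#' Computes the best-lag Pearson correlation (see [lagged_pearson()]) for
#' every (regulator, target) pair on log2 fold changes restricted to the
#' correlation window, and retains the pairs passing both thresholds:
#' `|r| >= r_min` and `p <= p_max`. Comparisons are strictly bipartite
#' (regulator versus metabolic gene/protein or metabolite); the regulator
#' and target sets must be disjoint. A Benjamini-Hochberg adjusted column
#' accompanies the audit table for reference, but plays no part in the
#' filter, which reproduces the raw-p criterion used in this analysis
#' tradition.
#'
#' @param fc a [fold_change()] object holding both sets of series.
#' @param tf_ids character, regulator entity ids.
#' @param target_ids character, target entity ids.
#' @param config a [lagnet_config()].
#' @param ann optional [annotations()] used to attach `target_class`.
#' @param keep_audit logical; attach the full unfiltered pair table as
#'   attribute `"audit"` (columns as below plus `retained` and `note`).
#' @return data frame of class `correlation_edges`: `tf`, `target`,
#'   `target_class`, `r`, `lag`, `n_pairs`, `p`, `sign`.
#' @export
correlate_all <- function(fc, tf_ids, target_ids, config = lagnet_config(),
                          ann = NULL, keep_audit = FALSE) {
  stopifnot(inherits(fc, "foldchange"))
  if (length(intersect(tf_ids, target_ids)))
    stop_("regulator and target sets must be disjoint")
  keep <- in_corr_window(fc$time_grid, config)
  l2 <- fc$log2fc[, keep, drop = FALSE]
  tf_ids <- intersect(tf_ids, rownames(l2))
  target_ids <- intersect(target_ids, rownames(l2))
  empty <- data.frame(tf = character(), target = character(),
                      target_class = character(), r = numeric(),
                      lag = integer(), n_pairs = integer(), p = numeric(),
                      sign = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("correlation_edges", "data.frame")
  if (!length(tf_ids) || !length(target_ids)) {
    if (keep_audit) attr(empty, "audit") <- cbind(empty[0, ], retained = logical())
    return(empty)
  }
  X <- t(l2[tf_ids, , drop = FALSE])     # time x tf
  Y <- t(l2[target_ids, , drop = FALSE]) # time x target
  n <- nrow(X)
  bestR <- bestP <- matrix(NA_real_, length(tf_ids), length(target_ids))
  bestL <- matrix(NA_integer_, length(tf_ids), length(target_ids))
  bestN <- matrix(NA_integer_, length(tf_ids), length(target_ids))
  ## evaluate lags in tie-break preference order so later lags must strictly win
  lags <- as.integer(config$lag_set)
  lags <- lags[order(abs(lags), lags)]
  for (l in lags) {
    if (abs(l) >= n) next
    i <- seq_len(n - abs(l))
    xi <- if (l >= 0) i else i - l
    yi <- if (l >= 0) i + l else i
    Xs <- X[xi, , drop = FALSE]; Ys <- Y[yi, , drop = FALSE]
    np <- crossprod(!is.na(Xs), !is.na(Ys))
    suppressWarnings(R <- cor(Xs, Ys, use = "pairwise.complete.obs"))
    R[np < config$min_overlap] <- NA
    upd <- !is.na(R) & (is.na(bestR) | abs(R) > abs(bestR) + 1e-15)
    bestR[upd] <- R[upd]; bestL[upd] <- l; bestN[upd] <- np[upd]
  }
  idx <- which(!is.na(bestR))
  p <- vapply(idx, function(k) cor_pvalue(bestR[k], bestN[k]), 0)
  tfv <- tf_ids[row(bestR)[idx]]
  tgv <- target_ids[col(bestR)[idx]]
  audit <- data.frame(
    tf = tfv, target = tgv,
    target_class = if (!is.null(ann)) ann_class(ann, tgv) else NA_character_,
    r = bestR[idx], lag = bestL[idx], n_pairs = bestN[idx], p = p,
    sign = ifelse(bestR[idx] >= 0, 1L, -1L), stringsAsFactors = FALSE)
  audit$p_adj <- p.adjust(audit$p, method = "BH")
  audit$retained <- abs(audit$r) >= config$r_min & audit$p <= config$p_max
  edges <- audit[audit$retained,
                 c("tf", "target", "target_class", "r", "lag", "n_pairs",
                   "p", "sign")]
  rownames(edges) <- NULL
  class(edges) <- c("correlation_edges", "data.frame")
  if (keep_audit) attr(edges, "audit") <- audit
  attr(edges, "n_pairs_tested") <- length(tf_ids) * length(target_ids)
  attr(edges, "n_pairs_evaluated") <- nrow(audit)
  edges
}

#' @export
print.correlation_edges <- function(x, ...) {
  cat(sprintf("correlation edges: %d retained (of %s pairs tested)\n",
              nrow(x), attr(x, "n_pairs_tested") %||% "?"))
  if (nrow(x)) print.data.frame(head(x, 10))
  invisible(x)
}
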