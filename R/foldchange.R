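#' Fold changes relative to the time-zero control
#'
#' For every entity, replicates are averaged per time point and each
#' post-baseline mean is divided by the entity's time-zero mean. Entities
#' with a zero baseline cannot be expressed as fold changes; they are
#' excluded and listed in the exclusion report rather than silently
#' dropped.
#'
#' @param tc a [timecourse()] object.
#' @return An object of class `foldchange`: list with `fc` and `log2fc`
#'   (matrices, entities x post-baseline times), `time_grid` (the
#'   post-baseline times), and `exclusions` (data frame `entity`,
#'   `reason`).
#' @examples
#' tc <- timecourse(data.frame(entity = "g1", time = c(0, 1), replicate = 1L,
#'                             value = c(2, 8)))
#' fold_change(tc)$fc
#' @export
fold_change <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  means <- tc_means(tc)
  t0 <- which(tc$time_grid == 0)
  base <- means[, t0]
  bad <- is.na(base) | base == 0
  excl <- data.frame(entity = rownames(means)[bad],
                     reason = rep("zero baseline", sum(bad)))
  fc <- means[!bad, -t0, drop = FALSE] / base[!bad]
  structure(list(fc = fc, log2fc = log2(fc),
                 time_grid = tc$time_grid[-t0], exclusions = excl),
            class = "foldchange")
}

#' @export
print.foldchange <- function(x, ...) {
  cat(sprintf("fold changes: %d entities x %d time points (%s h); %d excluded\n",
              nrow(x$fc), ncol(x$fc), paste(x$time_grid, collapse = ", "),
              nrow(x$exclusions)))
  invisible(x)
}

#' Classify each entity's response direction and timing
#'
#' An entity responds when its absolute log2 fold change reaches
#' `log2(fc_threshold)` at some time inside the correlation window; the
#' first such time is the onset. Direction is the sign of the fold change
#' at onset; timing is `early_BTS` when the onset falls in the early
#' window, `late_ATS` when it falls in the late window (and `NA` for an
#' onset in neither, possible only on unusual grids). Non-responders are
#' `unchanged` / `unaltered` with no onset.
#'
#' @param fc a [fold_change()] object.
#' @param config a [lagnet_config()].
#' @return data frame of class `response_calls`: `entity`, `direction`
#'   (`up`/`down`/`unchanged`), `timing` (`early_BTS`/`late_ATS`/
#'   `unaltered`), `onset_time` (hours, `NA` for non-responders),
#'   `max_abs_log2fc`.
#' @export
classify_response <- function(fc, config = lagnet_config()) {
  stopifnot(inherits(fc, "foldchange"))
  keep <- in_corr_window(fc$time_grid, config)
  l2 <- fc$log2fc[, keep, drop = FALSE]
  times <- fc$time_grid[keep]
  thr <- log2(config$fc_threshold)
  one <- function(v) {
    hit <- which(!is.na(v) & abs(v) >= thr)
    if (!length(hit))
      return(list(direction = "unchanged", timing = "unaltered",
                  onset = NA_real_, mx = max(abs(v), 0, na.rm = TRUE)))
    o <- hit[1]
    timing <- if (in_bts(times[o], config)) "early_BTS"
              else if (in_ats(times[o], config)) "late_ATS"
              else NA_character_
    list(direction = if (v[o] > 0) "up" else "down", timing = timing,
         onset = times[o], mx = max(abs(v), na.rm = TRUE))
  }
  rows <- apply(l2, 1, one)
  out <- data.frame(
    entity = rownames(l2),
    direction = vapply(rows, `[[`, "", "direction"),
    timing = vapply(rows, function(r) r$timing %||% NA_character_, ""),
    onset_time = vapply(rows, `[[`, 0, "onset"),
    max_abs_log2fc = vapply(rows, `[[`, 0, "mx"),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("response_calls", "data.frame")
  out
}

#' Select differentially responding entities, partitioned by class
#'
#' Keeps entities whose response direction is not `unchanged` and splits
#' them into the regulator set, the metabolite set, the metabolic
#' gene/protein set, and per-process gene sets.
#'
#' @param fc a [fold_change()] object.
#' @param ann a [annotations()] table covering the entities.
#' @param config a [lagnet_config()].
#' @param calls optional precomputed [classify_response()] result.
#' @return list with `regulators`, `metabolites`, `genes` (ids),
#'   `genes_by_process` (named list over [process_vocabulary()]), `all`,
#'   and the `calls` used.
#' @export
select_differential <- function(fc, ann, config = lagnet_config(), calls = NULL) {
  stopifnot(inherits(ann, "lagnet_annotations"))
  calls <- calls %||% classify_response(fc, config)
  diffs <- calls$entity[calls$direction != "unchanged"]
  cls <- ann_class(ann, diffs)
  regs <- diffs[is_regulator_class(cls)]
  mets <- diffs[cls == "metabolite"]
  genes <- diffs[cls %in% c("metabolic_gene", "protein")]
  prs <- ann_processes(ann, genes)
  by_proc <- lapply(setNames(nm = process_vocabulary()), function(p)
    genes[vapply(prs, function(x) p %in% x, TRUE)])
  list(regulators = regs, metabolites = mets, genes = genes,
       genes_by_process = by_proc, all = diffs, calls = calls)
}
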