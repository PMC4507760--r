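#' Replicate-resolved time-course abundance matrix
#'
#' Container for non-negative abundances measured for a set of entities
#' (regulator transcripts, metabolic genes, proteins, metabolites) over a
#' shared time grid with one or more replicates per time point. The grid
#' must contain the time-zero control, every entity must be measured at
#' time zero (it is the fold-change baseline), and abundances must be
#' finite and non-negative. Missing replicates are simply absent rows, not
#' zeros; downstream operations average over the replicates present.
#'
#' @param data a data frame with columns `entity`, `time`, `replicate`,
#'   `value` (long format). Extra columns are ignored except an optional
#'   `class` column giving the entity class.
#' @param entity_class optional named character vector mapping entity ids
#'   to one of `r paste(entity_classes(), collapse = ", ")`; overrides any
#'   `class` column.
#'
#' @return An object of class `timecourse`: a list with elements `data`
#'   (the long table), `entity_ids`, `entity_class` (named vector, `NA`
#'   where unknown) and `time_grid` (strictly increasing, starts at 0).
#' @seealso [read_timecourse()], [tc_means()], [fold_change()]
#' @export
timecourse <- function(data, entity_class = NULL) {
  need <- c("entity", "time", "replicate", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_("missing column(s): ", paste(miss, collapse = ", "))
  data$entity <- as.character(data$entity)
  data$time <- as.numeric(data$time)
  data$replicate <- as.integer(data$replicate)
  data$value <- as.numeric(data$value)
  if (anyNA(data$time) || anyNA(data$replicate))
    stop_("time and replicate must be numeric")
  if (anyNA(data$value) || any(!is.finite(data$value)) || any(data$value < 0))
    stop_("invalid abundance: values must be finite and non-negative")
  key <- paste(data$entity, data$time, data$replicate)
  if (anyDuplicated(key))
    stop_("duplicate record: ", key[anyDuplicated(key)])
  grid <- sort(unique(data$time))
  if (!0 %in% grid) stop_("no time-zero baseline")
  ids <- unique(data$entity)
  at0 <- unique(data$entity[data$time == 0])
  if (length(setdiff(ids, at0)))
    stop_("no time-zero baseline for entity: ",
          paste(head(setdiff(ids, at0), 5), collapse = ", "))
  cls <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(data$class)) {
    m <- tapply(as.character(data$class), data$entity, function(v) v[1])
    cls[names(m)] <- unname(m)
  }
  if (!is.null(entity_class)) cls[names(entity_class)] <- entity_class
  bad <- stats::na.omit(setdiff(unique(cls), entity_classes()))
  if (length(bad)) stop_("unknown entity class: ", paste(bad, collapse = ", "))
  structure(list(data = data[need], entity_ids = ids, entity_class = cls,
                 time_grid = grid),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  reps <- range(table(paste(x$data$entity, x$data$time)))
  cat(sprintf("timecourse: %d entities x %d time points (%s h), %s replicate(s)\n",
              length(x$entity_ids), length(x$time_grid),
              paste(x$time_grid, collapse = ", "),
              if (reps[1] == reps[2]) reps[1] else paste(reps, collapse = "-")))
  cls <- table(x$entity_class, useNA = "ifany")
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' Replicate-mean abundance matrix
#'
#' Averages replicates for each (entity, time) pair. Combinations with no
#' measured replicate are `NA`.
#'
#' @param tc a [timecourse()] object.
#' @return numeric matrix, entities in rows, time points in columns.
#' @export
tc_means <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  m <- tapply(tc$data$value,
              list(factor(tc$data$entity, tc$entity_ids),
                   factor(tc$data$time, tc$time_grid)),
              mean)
  mm <- matrix(as.numeric(m), nrow = length(tc$entity_ids),
               dimnames = list(tc$entity_ids, as.character(tc$time_grid)))
  mm
}

#' Read a time-course table
#'
#' Reads either a long table (columns `entity`/`id`, `time`, `replicate`,
#' `value`, optional `class`) or a wide table (one `entity`/`id` column
#' plus measurement columns named `t<time>_r<replicate>`, e.g. `t0.5_r2`).
#' The dialect is auto-detected from the header unless forced; the
#' delimiter follows the file extension (comma for `.csv`, tab otherwise).
#'
#' @param path file to read.
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @param entity_class optional named class vector passed to [timecourse()].
#' @return a [timecourse()] object.
#' @export
read_timecourse <- function(path, format = c("auto", "long", "wide"),
                            entity_class = NULL) {
  format <- match.arg(format)
  df <- read_delim_table(path)
  names(df)[names(df) %in% c("id", "entity_id")] <- "entity"
  if (format == "auto")
    format <- if (all(c("time", "value") %in% names(df))) "long" else "wide"
  if (format == "wide") {
    if (!"entity" %in% names(df)) stop_("wide table needs an entity/id column")
    mcols <- grep("^t[0-9.]+_r[0-9]+$", names(df), value = TRUE)
    if (!length(mcols)) stop_("no t<time>_r<replicate> measurement columns found")
    tm <- as.numeric(sub("^t([0-9.]+)_r[0-9]+$", "\\1", mcols))
    rp <- as.integer(sub("^t[0-9.]+_r([0-9]+)$", "\\1", mcols))
    long <- data.frame(
      entity = rep(df$entity, times = length(mcols)),
      time = rep(tm, each = nrow(df)),
      replicate = rep(rp, each = nrow(df)),
      value = unlist(df[mcols], use.names = FALSE))
    if ("class" %in% names(df))
      long$class <- rep(df$class, times = length(mcols))
    long <- long[!is.na(long$value), , drop = FALSE]
    if (!0 %in% long$time) stop_("no time-zero baseline")
    return(timecourse(long, entity_class))
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!0 %in% df$time) stop_("no time-zero baseline")
  timecourse(df, entity_class)
}

#' Write a time-course table
#'
#' @param tc a [timecourse()] object.
#' @param path output file; delimiter follows the extension.
#' @param format `"long"` (default) or `"wide"` (`t<time>_r<rep>` columns).
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path, format = c("long", "wide")) {
  stopifnot(inherits(tc, "timecourse"))
  format <- match.arg(format)
  if (format == "long") {
    out <- tc$data
    out$class <- tc$entity_class[out$entity]
    return(write_delim_table(out, path))
  }
  d <- tc$data
  col <- sprintf("t%s_r%d", format(d$time, trim = TRUE), d$replicate)
  wide <- tapply(d$value, list(factor(d$entity, tc$entity_ids), col), mean)
  ## order columns by time then replicate
  tm <- as.numeric(sub("^t([0-9.]+)_r[0-9]+$", "\\1", colnames(wide)))
  rp <- as.integer(sub("^t[0-9.]+_r([0-9]+)$", "\\1", colnames(wide)))
  wide <- wide[, order(tm, rp), drop = FALSE]
  out <- data.frame(entity = rownames(wide),
                    class = unname(tc$entity_class[rownames(wide)]),
                    wide, check.names = FALSE)
  write_delim_table(out, path)
}
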