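#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. The defaults are the
#' stringent criteria used for nitrogen-deprivation regulatory network
#' inference: correlation magnitude at least 0.9 with a two-sided p-value
#' at most 0.05, a 2-fold differential-response cutoff, an early response
#' window of (0, 4] hours (before storage-lipid synthesis begins, "BTS")
#' and a late window of [6, 24] hours ("ATS"), correlations computed on
#' the 0.5-24 h points, regulator-leads lags of 0 or 1 sampling steps, and
#' hubs defined as the top 5% highest-degree regulators.
#'
#' @param r_min minimum correlation magnitude for a retained edge, in (0, 1].
#' @param p_max maximum two-sided p-value for a retained edge, in (0, 1).
#' @param fc_threshold fold-change cutoff for calling a response; an entity
#'   responds when `|log2 fc| >= log2(fc_threshold)` at some time point.
#'   Down-regulation is symmetric in log space (fc `<= 1/fc_threshold`).
#' @param bts_window numeric length-2, the early-response onset window in
#'   hours, interpreted as the half-open interval `(lo, hi]`.
#' @param ats_window numeric length-2, the late-response onset window in
#'   hours, interpreted as the closed interval `[lo, hi]`.
#' @param correlation_window numeric length-2, the closed interval of time
#'   points (hours) used for response classification and correlation. The
#'   default excludes a trailing 48 h point when present.
#' @param lag_set integer vector of allowed lags in sampling steps
#'   (positive = regulator leads the target). Lags count grid positions,
#'   not hours, because the grid is unevenly spaced.
#' @param hub_fraction fraction of top-degree regulators called hubs.
#' @param min_overlap minimum number of paired observations for a
#'   correlation to be considered (at least 3).
#' @param hub_rule whether a hub must rank in the top fraction of `"any"`
#'   (default) or `"all"` process subnetworks, in addition to the whole
#'   network.
#' @param phase_scheme how an edge is assigned to a response phase when
#'   typing hubs: `"target"` (default) uses the target's onset window;
#'   `"both_endpoints"` requires both endpoints' onsets to share a window
#'   and otherwise calls the edge mixed. See [assign_edge_phase()].
#' @param sim_min_processes minimum number of distinct biological processes
#'   a hub's single-input-motif targets must span for the hub to qualify
#'   as phase-specific.
#' @param seed optional integer seed recorded with the configuration.
#'
#' @return An object of class `lagnet_config` (a validated named list).
#' @seealso [read_config()], [write_config()], [lagnet()]
#' @examples
#' cfg <- lagnet_config()
#' cfg$r_min
#' @export
lagnet_config <- function(r_min = 0.9, p_max = 0.05, fc_threshold = 2,
                          bts_window = c(0, 4), ats_window = c(6, 24),
                          correlation_window = c(0.5, 24),
                          lag_set = c(0L, 1L), hub_fraction = 0.05,
                          min_overlap = 5L,
                          hub_rule = c("any", "all"),
                          phase_scheme = c("target", "both_endpoints"),
                          sim_min_processes = 2L,
                          seed = NULL) {
  hub_rule <- match.arg(hub_rule)
  phase_scheme <- match.arg(phase_scheme)
  if (!is.numeric(r_min) || length(r_min) != 1 || r_min <= 0 || r_min > 1)
    stop_("r_min must be in (0, 1]")
  if (!is.numeric(p_max) || length(p_max) != 1 || p_max <= 0 || p_max >= 1)
    stop_("p_max must be in (0, 1)")
  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    stop_("fc_threshold must exceed 1")
  if (!is.numeric(hub_fraction) || hub_fraction <= 0 || hub_fraction >= 1)
    stop_("hub_fraction must be in (0, 1)")
  if (!is.numeric(min_overlap) || min_overlap < 3)
    stop_("min_overlap must be at least 3")
  chk_win <- function(w, nm) {
    if (!is.numeric(w) || length(w) != 2 || w[1] >= w[2])
      stop_(nm, " must be an increasing numeric interval")
    as.numeric(w)
  }
  bts_window <- chk_win(bts_window, "bts_window")
  ats_window <- chk_win(ats_window, "ats_window")
  correlation_window <- chk_win(correlation_window, "correlation_window")
  if (bts_window[2] >= ats_window[1] && ats_window[2] >= bts_window[1] &&
      max(bts_window[1], ats_window[1]) < min(bts_window[2], ats_window[2]))
    stop_("bts_window and ats_window must be disjoint")
  if (!length(lag_set) || anyDuplicated(lag_set))
    stop_("lag_set must be a set of distinct integer lags")
  structure(list(
    r_min = r_min, p_max = p_max, fc_threshold = fc_threshold,
    bts_window = bts_window, ats_window = ats_window,
    correlation_window = correlation_window,
    lag_set = as.integer(lag_set), hub_fraction = hub_fraction,
    min_overlap = as.integer(min_overlap), hub_rule = hub_rule,
    phase_scheme = phase_scheme,
    sim_min_processes = as.integer(sim_min_processes),
    seed = if (!is.null(seed)) as.integer(seed)
  ), class = "lagnet_config")
}

#' @export
print.lagnet_config <- function(x, ...) {
  cat("lagnet analysis configuration\n")
  cat(sprintf("  edge filter     : |r| >= %g, p <= %g\n", x$r_min, x$p_max))
  cat(sprintf("  response cutoff : %g-fold\n", x$fc_threshold))
  cat(sprintf("  windows (h)     : early (%g, %g], late [%g, %g], correlation [%g, %g]\n",
              x$bts_window[1], x$bts_window[2], x$ats_window[1],
              x$ats_window[2], x$correlation_window[1], x$correlation_window[2]))
  cat(sprintf("  lags (steps)    : {%s}, min overlap %d\n",
              paste(x$lag_set, collapse = ", "), x$min_overlap))
  cat(sprintf("  hubs            : top %g%% of regulator degrees (%s subnetwork), phase scheme '%s'\n",
              100 * x$hub_fraction, x$hub_rule, x$phase_scheme))
  invisible(x)
}

#' Read or write an analysis configuration as YAML
#'
#' The file mirrors [lagnet_config()] field for field; unknown fields are
#' rejected so that a run configuration cannot silently drift.
#'
#' @param path file path of a YAML configuration.
#' @return `read_config()` returns a `lagnet_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(lagnet_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop_("unknown configuration field(s): ",
                           paste(extra, collapse = ", "))
  do.call(lagnet_config, vals)
}

#' @rdname read_config
#' @param config a `lagnet_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "lagnet_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## window membership helpers: BTS is (lo, hi], ATS is [lo, hi]
in_bts <- function(t, config) !is.na(t) & t > config$bts_window[1] & t <= config$bts_window[2]
in_ats <- function(t, config) !is.na(t) & t >= config$ats_window[1] & t <= config$ats_window[2]
in_corr_window <- function(t, config)
  t >= config$correlation_window[1] & t <= config$correlation_window[2]
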