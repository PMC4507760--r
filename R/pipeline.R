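#' Fit the full regulatory-network model to a time course
#'
#' Runs the whole inference chain: fold changes against the time-zero
#' control, response classification (direction, early/late timing),
#' normality diagnostics, selection of differential entities, time-lagged
#' correlation of every regulator against every differential metabolic
#' gene/protein and metabolite, edge filtering at the configured
#' thresholds, network assembly, the ten process subnetworks, single-input
#' motif mining and merging, degree/scale-free diagnostics, hub calling by
#' the top-degree rule, and hub phase typing.
#'
#' @param tc a [timecourse()] object.
#' @param ann an [annotations()] table covering the entities.
#' @param config a [lagnet_config()].
#' @param keep_audit keep the full unfiltered correlation table (attribute
#'   `"audit"` of `$edges`).
#' @param normality compute the per-time-point [normality_report()]
#'   (diagnostic only; the pipeline proceeds regardless).
#' @return An object of class `lagnet`: a list with components `config`,
#'   `fold_change`, `response_calls`, `normality`, `differential`,
#'   `edges`, `network`, `subnetworks`, `sims`, `sim_network`,
#'   `degree_stats`, `hubs`, `process_table` and `counts` (the per-stage
#'   filter ledger). Has `print`, `summary` and `plot` methods.
#' @examples
#' d <- generate_dataset(synth_config(n_tf = 8, n_gene = 10, n_metabolite = 6,
#'                                    hubs = list(list(phase = "BTS",
#'                                                     n_targets = 4, lag = 0L)),
#'                                    n_minor_regulators = 3,
#'                                    noise_sigma = 0), seed = 1)
#' fit <- lagnet(d$timecourse, d$annotations)
#' fit
#' @export
lagnet <- function(tc, ann, config = lagnet_config(), keep_audit = FALSE,
                   normality = TRUE) {
  stopifnot(inherits(tc, "timecourse"), inherits(ann, "lagnet_annotations"))
  fc <- fold_change(tc)
  calls <- classify_response(fc, config)
  norm <- if (normality) normality_report(fc) else NULL
  sel <- select_differential(fc, ann, config, calls)
  targets <- c(sel$genes, sel$metabolites)
  edges <- correlate_all(fc, sel$regulators, targets, config, ann, keep_audit)
  net <- build_network(edges, ann)
  subs <- lapply(setNames(nm = process_vocabulary()),
                 function(p) process_subnetwork(net, p))
  sims <- find_sims(net)
  sim_net <- merge_motifs(sims, net)
  dstats <- if (igraph::vcount(net)) degree_stats(net) else NULL
  hubs <- call_hubs(net, subs, config$hub_fraction, config$hub_rule)
  hubs <- type_hubs(hubs, net, calls, config, sims)
  ptab <- hub_process_table(hubs, net)
  counts <- c(
    n_entities = length(tc$entity_ids),
    n_excluded_baseline = nrow(fc$exclusions),
    n_responders = sum(calls$direction != "unchanged"),
    n_regulators_tested = length(sel$regulators),
    n_targets_tested = length(targets),
    n_pairs_tested = attr(edges, "n_pairs_tested") %||% 0L,
    n_edges = nrow(edges),
    n_nodes = igraph::vcount(net),
    n_sims = length(sims),
    n_hubs = nrow(hubs))
  structure(list(config = config, fold_change = fc, response_calls = calls,
                 normality = norm, differential = sel, edges = edges,
                 network = net, subnetworks = subs, sims = sims,
                 sim_network = sim_net, degree_stats = dstats, hubs = hubs,
                 process_table = ptab, counts = counts),
            class = "lagnet")
}

#' @export
print.lagnet <- function(x, ...) {
  cat("lagnet regulatory network fit\n")
  cat(sprintf("  %d entities -> %d responders; %d regulators x %d targets tested\n",
              x$counts["n_entities"], x$counts["n_responders"],
              x$counts["n_regulators_tested"], x$counts["n_targets_tested"]))
  cat(sprintf("  %d edges (|r| >= %g, p <= %g) over %d nodes; %d SIM(s); %d hub(s)\n",
              x$counts["n_edges"], x$config$r_min, x$config$p_max,
              x$counts["n_nodes"], x$counts["n_sims"], x$counts["n_hubs"]))
  if (nrow(x$hubs)) {
    tb <- table(x$hubs$hub_type)
    cat("  hub types:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.lagnet <- function(object, ...) {
  structure(list(fit = object), class = "summary.lagnet")
}

#' @export
print.summary.lagnet <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nfilter ledger:\n")
  for (nm in names(f$counts)) cat(sprintf("  %-22s %d\n", nm, f$counts[nm]))
  if (!is.null(f$degree_stats)) { cat("\n"); print(f$degree_stats) }
  if (nrow(f$hubs)) { cat("\nhubs:\n"); print(f$hubs) }
  invisible(x)
}

#' @export
plot.lagnet <- function(x, ...) {
  if (is.null(x$degree_stats)) stop_("empty network: nothing to plot")
  plot(x$degree_stats, ...)
}

## ---- file-driven pipeline ------------------------------------------------

#' Run the pipeline from a configuration, writing a run directory
#'
#' Drives [lagnet()] from either input files or the synthetic generator
#' and writes every stage product plus a machine-readable manifest.
#' `config` may be a YAML file or a list with sections:
#' `analysis` ([lagnet_config()] fields), `input` (`timecourse`,
#' `annotations` paths), `synthetic` (logical `enabled` plus
#' [synth_config()] fields), and `output` (`keep_audit`, `plots`).
#' Identical configuration and seed reproduce identical stage outputs.
#'
#' @param config path to a YAML run configuration, or an equivalent list.
#' @param out_dir run directory (created if needed).
#' @param seed integer seed for the synthetic generator.
#' @return the [lagnet()] fit, invisibly, with attribute `"run_dir"`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  acfg <- do.call(lagnet_config, cfg$analysis %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()
  if (isTRUE(cfg$synthetic$enabled %||% FALSE) || is.null(cfg$input)) {
    sc <- do.call(synth_config,
                  cfg$synthetic[setdiff(names(cfg$synthetic), "enabled")] %||%
                    list())
    ds <- generate_dataset(sc, seed)
    tc <- ds$timecourse; ann <- ds$annotations
    write_timecourse(tc, file.path(out_dir, "timecourse.tsv"))
    write_annotations(ann, file.path(out_dir, "annotations.csv"))
    write.csv(ds$truth$edges, file.path(out_dir, "truth_edges.csv"),
              row.names = FALSE)
    write.csv(ds$truth$hubs, file.path(out_dir, "truth_hubs.csv"),
              row.names = FALSE)
    inputs <- c(timecourse = file.path(out_dir, "timecourse.tsv"),
                annotations = file.path(out_dir, "annotations.csv"))
  } else {
    tc <- read_timecourse(cfg$input$timecourse,
                          format = cfg$input$format %||% "auto")
    ann <- read_annotations(cfg$input$annotations)
    inputs <- c(timecourse = cfg$input$timecourse,
                annotations = cfg$input$annotations)
  }
  keep_audit <- isTRUE(cfg$output$keep_audit %||% FALSE)
  fit <- lagnet(tc, ann, acfg, keep_audit = keep_audit)

  write.csv(fit$response_calls, file.path(out_dir, "response_calls.csv"),
            row.names = FALSE)
  write.csv(fit$fold_change$exclusions, file.path(out_dir, "exclusions.csv"),
            row.names = FALSE)
  if (!is.null(fit$normality))
    write.csv(fit$normality, file.path(out_dir, "normality.csv"),
              row.names = FALSE)
  write.csv(fit$edges, file.path(out_dir, "edges.csv"), row.names = FALSE)
  if (keep_audit)
    write.csv(attr(fit$edges, "audit"), file.path(out_dir, "audit.csv"),
              row.names = FALSE)
  export_network(fit$network, out_dir, "network")
  export_network(fit$sim_network, out_dir, "sim_network")
  hub_flat <- fit$hubs
  hub_flat$subnetwork_degrees <- vapply(hub_flat$subnetwork_degrees,
                                        function(d) paste(d, collapse = ";"), "")
  hub_flat$qualifying_subnetworks <- vapply(hub_flat$qualifying_subnetworks,
                                            paste, "", collapse = ";")
  write.csv(hub_flat, file.path(out_dir, "hubs.csv"), row.names = FALSE)
  write.csv(cbind(row = rownames(fit$process_table), fit$process_table),
            file.path(out_dir, "participation.csv"), row.names = FALSE)
  if (isTRUE(cfg$output$plots %||% FALSE) && !is.null(fit$degree_stats)) {
    grDevices::png(file.path(out_dir, "degree_distribution.png"), 600, 600)
    plot(fit$degree_stats)
    grDevices::dev.off()
  }
  write_config(acfg, file.path(out_dir, "analysis_config.yaml"))

  outputs <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "lagnet",
    version = as.character(packageVersion("lagnet")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    config = cfg,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(setNames(nm = basename(outputs)), function(b)
      list(path = file.path(out_dir, b),
           md5 = unname(tools::md5sum(file.path(out_dir, b))))),
    counts = as.list(fit$counts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(fit, "run_dir") <- out_dir
  invisible(fit)
}
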