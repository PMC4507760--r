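## top hub_fraction of regulator degrees in one network, boundary ties included
top_regulator_set <- function(net, hub_fraction) {
  regs <- regulator_vertices(net)
  deg <- igraph::degree(net, regs)
  deg <- deg[deg >= 1]
  if (!length(deg)) return(character())
  k <- ceiling(hub_fraction * length(deg))
  thr <- sort(deg, decreasing = TRUE)[k]
  names(deg)[deg >= thr]
}

#' Call regulatory hubs by the top-degree rule
#'
#' A regulator is a hub when it ranks in the top `hub_fraction` of
#' regulator degrees in the whole network and in at least one process
#' subnetwork (`hub_rule = "any"`; `"all"` requires every subnetwork in
#' which the regulator has any edge). `k = ceiling(hub_fraction * m)`
#' where `m` counts regulators with degree at least one, and all ties at
#' the k-th degree value are included, making the call deterministic and
#' invariant to node relabelling.
#'
#' @param whole_net the whole network from [build_network()].
#' @param subnetworks list of process subnetworks
#'   ([process_subnetwork()]).
#' @param hub_fraction fraction of top-degree regulators retained
#'   (default 0.05).
#' @param hub_rule `"any"` (default) or `"all"`, see above.
#' @return data frame of class `hub_calls`: `tf_id`, `degree`,
#'   `rank_percentile` (share of regulators with degree not exceeding the
#'   hub's), list columns `subnetwork_degrees` and
#'   `qualifying_subnetworks`, and placeholder typing columns (`hub_type`,
#'   `n_bts`, `n_ats`, `n_mixed`) filled by [type_hubs()].
#' @export
call_hubs <- function(whole_net, subnetworks, hub_fraction = 0.05,
                      hub_rule = c("any", "all")) {
  hub_rule <- match.arg(hub_rule)
  whole_top <- top_regulator_set(whole_net, hub_fraction)
  sub_tops <- lapply(subnetworks, top_regulator_set, hub_fraction = hub_fraction)
  regs <- regulator_vertices(whole_net)
  deg <- igraph::degree(whole_net, regs)
  deg <- deg[deg >= 1]
  qual <- lapply(setNames(nm = whole_top), function(id) {
    names(subnetworks)[vapply(sub_tops, function(s) id %in% s, TRUE)]
  })
  present <- lapply(setNames(nm = whole_top), function(id) {
    names(subnetworks)[vapply(subnetworks, function(s)
      id %in% igraph::V(s)$name && igraph::degree(s, id) >= 1, TRUE)]
  })
  is_hub <- vapply(whole_top, function(id) {
    if (hub_rule == "any") length(qual[[id]]) >= 1
    else length(present[[id]]) >= 1 && all(present[[id]] %in% qual[[id]])
  }, TRUE)
  ids <- whole_top[is_hub]
  ids <- ids[order(-deg[ids], ids)]
  out <- data.frame(tf_id = ids, degree = as.integer(deg[ids]),
                    rank_percentile = 100 * vapply(ids, function(i)
                      mean(deg <= deg[i]), 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$subnetwork_degrees <- lapply(ids, function(id)
    vapply(subnetworks, function(s)
      if (id %in% igraph::V(s)$name) igraph::degree(s, id) else 0L,
      numeric(1)))
  out$qualifying_subnetworks <- unname(qual[ids])
  out$hub_type <- rep(NA_character_, nrow(out))
  out$n_bts <- out$n_ats <- out$n_mixed <- rep(NA_integer_, nrow(out))
  class(out) <- c("hub_calls", "data.frame")
  out
}

#' Assign a response phase to each network edge
#'
#' Classifies edges as early (`BTS`), late (`ATS`), `mixed` or `none`
#' from the response onsets of their endpoints. With the default
#' `"target"` scheme an edge takes the phase of its target's onset window
#' (the regulator must itself respond, otherwise `none`): a correlation
#' constrains the partner shapes so tightly that the target's onset is
#' what distinguishes when the regulation acts. The `"both_endpoints"`
#' scheme is stricter: both onsets must share a window, otherwise the
#' edge is `mixed`. Either endpoint without a response gives `none`.
#'
#' @param edges data frame with columns `tf`, `target` (e.g. from
#'   [correlate_all()] or [edge_table()]).
#' @param calls a [classify_response()] table covering the endpoints.
#' @param config a [lagnet_config()]; `config$phase_scheme` supplies the
#'   default scheme.
#' @param scheme `"target"` or `"both_endpoints"` (overrides the config).
#' @return character vector, one of `"BTS"`, `"ATS"`, `"mixed"`,
#'   `"none"` per edge.
#' @export
assign_edge_phase <- function(edges, calls, config = lagnet_config(),
                              scheme = NULL) {
  scheme <- scheme %||% config$phase_scheme
  scheme <- match.arg(scheme, c("target", "both_endpoints"))
  i_tf <- match(edges$tf, calls$entity)
  i_tg <- match(edges$target, calls$entity)
  if (anyNA(i_tf) || anyNA(i_tg)) stop_("unclassified endpoint")
  phase_of <- function(t) ifelse(in_bts(t, config), "BTS",
                          ifelse(in_ats(t, config), "ATS", NA))
  o_tf <- calls$onset_time[i_tf]
  o_tg <- calls$onset_time[i_tg]
  altered <- calls$direction[i_tf] != "unchanged" &
             calls$direction[i_tg] != "unchanged"
  p_tf <- phase_of(o_tf); p_tg <- phase_of(o_tg)
  out <- if (scheme == "target") ifelse(is.na(p_tg), "mixed", p_tg)
         else ifelse(!is.na(p_tf) & !is.na(p_tg) & p_tf == p_tg, p_tf, "mixed")
  out[!altered] <- "none"
  out
}

#' Type hubs as early-specific, late-specific or permanent
#'
#' Uses the clear-phase edges (`BTS`/`ATS`) incident to each hub: early
#' edges only gives `BTS_specific`, late only `ATS_specific`, both gives
#' `permanent`, neither `unclassified`. Mixed and phaseless edges are
#' ignored. A phase-specific hub must additionally drive a single-input
#' motif whose exclusive targets span at least
#' `config$sim_min_processes` distinct biological processes; specific
#' candidates failing that test stay `unclassified`.
#'
#' @param hubs a [call_hubs()] result.
#' @param net the whole network.
#' @param calls a [classify_response()] table.
#' @param config a [lagnet_config()].
#' @param sims optional precomputed [find_sims()] result for `net`.
#' @return `hubs` with `hub_type`, `n_bts`, `n_ats`, `n_mixed` filled in.
#' @export
type_hubs <- function(hubs, net, calls, config = lagnet_config(), sims = NULL) {
  stopifnot(inherits(hubs, "hub_calls"))
  if (!nrow(hubs)) return(hubs)
  sims <- sims %||% find_sims(net)
  et <- edge_table(net)
  phases <- assign_edge_phase(et, calls, config)
  procs <- strsplit(igraph::V(net)$processes %||%
                    rep("", igraph::vcount(net)), ";")
  names(procs) <- igraph::V(net)$name
  sim_ok <- vapply(hubs$tf_id, function(id) {
    m <- Filter(function(s) s$regulator == id, sims)
    if (!length(m)) return(FALSE)
    length(unique(unlist(procs[m[[1]]$targets]))) >= config$sim_min_processes
  }, TRUE)
  for (i in seq_len(nrow(hubs))) {
    ph <- phases[et$tf == hubs$tf_id[i]]
    nb <- sum(ph == "BTS"); na_ <- sum(ph == "ATS"); nm <- sum(ph == "mixed")
    hubs$n_bts[i] <- nb; hubs$n_ats[i] <- na_; hubs$n_mixed[i] <- nm
    hubs$hub_type[i] <-
      if (nb > 0 && na_ > 0) "permanent"
      else if (nb > 0 && sim_ok[i]) "BTS_specific"
      else if (na_ > 0 && sim_ok[i]) "ATS_specific"
      else "unclassified"
  }
  hubs
}

#' @export
print.hub_calls <- function(x, ...) {
  cat(sprintf("%d regulatory hub(s)\n", nrow(x)))
  if (nrow(x))
    print.data.frame(x[c("tf_id", "degree", "hub_type", "n_bts", "n_ats",
                         "n_mixed")])
  invisible(x)
}

#' Hub-by-process participation table
#'
#' Lays hubs out in columns (grouped early-specific, late-specific,
#' permanent, then unclassified), biological processes in rows; a cell is
#' 1 when the hub has at least one partner annotated with that process.
#' The final row repeats each hub's whole-network degree, mirroring the
#' usual published presentation of top regulatory hubs.
#'
#' @param hubs a typed [type_hubs()] result.
#' @param net the whole network.
#' @return data frame, rows = processes plus `"degree"`, columns = hubs.
#' @export
hub_process_table <- function(hubs, net) {
  ord <- order(match(hubs$hub_type,
                     c("BTS_specific", "ATS_specific", "permanent",
                       "unclassified")), -hubs$degree)
  h <- hubs[ord, , drop = FALSE]
  procs <- strsplit(igraph::V(net)$processes %||%
                    rep("", igraph::vcount(net)), ";")
  names(procs) <- igraph::V(net)$name
  cell <- vapply(h$tf_id, function(id) {
    nb <- igraph::neighbors(net, id)$name
    touched <- unique(unlist(procs[nb]))
    as.integer(process_vocabulary() %in% touched)
  }, integer(length(process_vocabulary())))
  out <- as.data.frame(rbind(cell, degree = h$degree))
  rownames(out) <- c(process_vocabulary(), "degree")
  colnames(out) <- h$tf_id
  attr(out, "hub_type") <- setNames(h$hub_type, h$tf_id)
  out
}
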