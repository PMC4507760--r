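# Brute-force reference implementations, deliberately independent of the
# package internals (no igraph, no vectorised correlation): these define
# the expected behaviour that the optimised code paths must reproduce.

## plain double-loop time-lagged Pearson correlation
oracle_lagged_pearson <- function(x, y, lag_set = c(0L, 1L), min_overlap = 5L) {
  n <- length(x)
  best <- NULL
  for (l in sort(lag_set)[order(abs(sort(lag_set)), sort(lag_set))]) {
    xs <- c(); ys <- c()
    for (i in seq_len(n)) {
      j <- i + l
      if (j >= 1 && j <= n && !is.na(x[i]) && !is.na(y[j])) {
        xs <- c(xs, x[i]); ys <- c(ys, y[j])
      }
    }
    np <- length(xs)
    if (np < min_overlap) next
    mx <- sum(xs) / np; my <- sum(ys) / np
    vx <- sum((xs - mx)^2); vy <- sum((ys - my)^2)
    if (vx == 0 || vy == 0) next
    r <- sum((xs - mx) * (ys - my)) / sqrt(vx * vy)
    p <- if (1 - r^2 <= 0) 0 else
      2 * stats::pt(-abs(r) * sqrt((np - 2) / (1 - r^2)), np - 2)
    if (is.null(best) || abs(r) > abs(best$r) + 1e-15)
      best <- list(r = r, lag = l, n_pairs = np, p = p)
  }
  best
}

## exhaustive single-input-motif enumeration from a raw edge list
oracle_find_sims <- function(edges, reg_ids) {
  out <- list()
  for (reg in sort(unique(edges$tf))) {
    excl <- c()
    tgts <- unique(edges$target[edges$tf == reg])
    for (t in tgts) {
      regs_of_t <- unique(edges$tf[edges$target == t])
      if (length(regs_of_t) == 1 && regs_of_t == reg) excl <- c(excl, t)
    }
    if (length(excl) >= 2)
      out[[reg]] <- sort(excl)
  }
  out
}

## sort-and-intersect hub oracle on raw edge lists
oracle_call_hubs <- function(whole_edges, sub_edge_list, hub_fraction = 0.05) {
  top_of <- function(edges) {
    if (!nrow(edges)) return(character())
    deg <- table(edges$tf)
    k <- ceiling(hub_fraction * length(deg))
    thr <- sort(as.integer(deg), decreasing = TRUE)[k]
    names(deg)[as.integer(deg) >= thr]
  }
  whole_top <- top_of(whole_edges)
  in_any_sub <- unique(unlist(lapply(sub_edge_list, top_of)))
  sort(intersect(whole_top, in_any_sub))
}

## random bipartite edge list + matching annotations, built in code
random_network <- function(n_tf = 8, n_target = 22, p = 0.15, seed = 1) {
  set.seed(seed)
  tfs <- sprintf("tf%02d", seq_len(n_tf))
  tgts <- sprintf("tg%02d", seq_len(n_target))
  pick <- which(runif(n_tf * n_target) < p)
  edges <- data.frame(
    tf = tfs[(pick - 1) %% n_tf + 1],
    target = tgts[(pick - 1) %/% n_tf + 1],
    r = round(runif(length(pick), -1, 1), 3), lag = 0L,
    n_pairs = 7L, p = 0.01, stringsAsFactors = FALSE)
  edges$r[abs(edges$r) < 0.9] <- sign(edges$r[abs(edges$r) < 0.9] + 1e-9) *
    (0.9 + abs(edges$r[abs(edges$r) < 0.9]) / 10)
  edges$sign <- ifelse(edges$r >= 0, 1L, -1L)
  pv <- process_vocabulary()
  ann <- annotations(data.frame(
    id = c(tfs, tgts),
    class = c(rep("TF", n_tf),
              rep(c("metabolic_gene", "metabolite"), length.out = n_target)),
    family = c(rep("bHLH", n_tf), rep(NA, n_target)),
    processes = c(rep("", n_tf), pv[seq_len(n_target) %% 10 + 1]),
    stringsAsFactors = FALSE))
  list(edges = edges, ann = ann, tfs = tfs, targets = tgts)
}

## small hand-rolled timecourse: values is entities x times matrix of means,
## expanded to `reps` identical replicates
make_tc <- function(values, times, classes = NULL, reps = 1L) {
  ids <- rownames(values)
  long <- expand.grid(replicate = seq_len(reps), time = times, entity = ids,
                      stringsAsFactors = FALSE)
  long$value <- values[cbind(long$entity, as.character(long$time))]
  timecourse(long[c("entity", "time", "replicate", "value")],
             entity_class = classes)
}

## quick annotation table builder
make_ann <- function(ids, classes, families = NULL, processes = NULL) {
  annotations(data.frame(
    id = ids, class = classes,
    family = families %||% ifelse(classes %in% c("TF", "TR"), "bHLH", NA),
    processes = processes %||% "", stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## canonical ordering for named lists (stable for the empty case too)
sort_named <- function(l) {
  if (!length(l)) return(structure(list(), names = character(0)))
  l[order(names(l))]
}

## shared small synthetic configs (kept tiny for speed)
small_synth <- function(noise = 0, ...) {
  synth_config(n_tf = 12, n_gene = 16, n_metabolite = 10,
               hubs = list(list(phase = "BTS", n_targets = 5, lag = 0L)),
               n_minor_regulators = 6, background_responder_fraction = 0.25,
               noise_sigma = noise, ...)
}
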