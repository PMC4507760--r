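#' Configuration for the synthetic time-course generator
#'
#' Describes a benchmark dataset with planted regulatory structure: a few
#' high-degree regulators ("hubs") whose targets respond in the early
#' window, the late window, or both; many minor regulators with one
#' exclusive target each (the long tail of a scale-free-like degree
#' distribution, and the reason the top-5% hub rule has a meaningful
#' denominator); background responders with no planted partner; and
#' non-responders that fluctuate within +/-0.3 log2 units.
#'
#' Planted targets are lag-shifted, sign-scaled copies of their
#' regulator's log2 fold-change profile, so at zero noise every planted
#' pair correlates at exactly +/-1 at its planted lag. Regulator profiles
#' are drawn to be mutually decorrelated (greedy rejection sampling with a
#' refinement pass, absolute correlation capped well below the 0.9 edge
#' threshold at all lags in use), reflecting the premise that distinct
#' regulons follow distinct temporal programs; this makes the planted
#' truth identifiable by construction. The truth topology and all base
#' profiles derive from `truth_seed` only, so different simulation seeds
#' redraw measurement noise around an identical ground truth.
#'
#' Replicate noise is multiplicative log-normal on the abundance scale,
#' `exp(N(0, sigma^2))`, i.e. symmetric in log space.
#'
#' @param n_tf,n_gene,n_metabolite entity counts per class.
#' @param times sampling grid in hours, must start at 0; the default is
#'   the usual nitrogen-deprivation design with a trailing 48 h point
#'   that the analysis window excludes.
#' @param replicates replicates per (entity, time).
#' @param hubs list of hub specifications, each a list with `phase`
#'   (`"BTS"`, `"ATS"` or `"both"`), `n_targets`, `lag` (0 or 1; ignored
#'   for `"both"`, whose targets alternate lags 0 and 1 to realise both
#'   phases) and optional `effect` (max |log2 fc|).
#' @param n_minor_regulators number of single-target regulators.
#' @param background_responder_fraction fraction of the remaining
#'   (non-planted) entities that respond without a planted partner.
#' @param noise_sigma replicate noise standard deviation (natural-log
#'   scale).
#' @param effect_size default max |log2 fc| of planted regulators; must
#'   exceed `log2(fc_threshold)`.
#' @param fc_threshold fold-change cutoff the responders are planted to
#'   cross.
#' @param scale_range magnitude range of the signed coefficient linking a
#'   target to its regulator.
#' @param baseline_range range of time-zero abundances (arbitrary units).
#' @param truth_seed integer seed for the truth topology and profiles.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_tf = 50, n_gene = 60, n_metabolite = 40,
                         times = c(0, 0.5, 1, 2, 4, 6, 12, 24, 48),
                         replicates = 2,
                         hubs = list(
                           list(phase = "BTS", n_targets = 10, lag = 0L),
                           list(phase = "ATS", n_targets = 10, lag = 0L),
                           list(phase = "both", n_targets = 10, lag = 0L)),
                         n_minor_regulators = 45,
                         background_responder_fraction = 0.3,
                         noise_sigma = 0.15, effect_size = 2.5,
                         fc_threshold = 2, scale_range = c(1, 1.6),
                         baseline_range = c(50, 500),
                         truth_seed = 20200408) {
  if (n_tf < 1 || n_gene < 1 || n_metabolite < 1 || replicates < 1)
    stop_("config infeasible: counts must be positive")
  if (noise_sigma < 0) stop_("config infeasible: noise_sigma must be >= 0")
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop_("config infeasible: times must start at 0 and increase")
  if (effect_size <= log2(fc_threshold))
    stop_("config infeasible: effect_size must exceed log2(fc_threshold)")
  n_targets <- sum(vapply(hubs, function(h) h$n_targets, 0)) + n_minor_regulators
  if (n_targets > n_gene + n_metabolite)
    stop_("config infeasible: targets exceed available entities")
  if (length(hubs) + n_minor_regulators > n_tf)
    stop_("config infeasible: regulators exceed n_tf")
  for (h in hubs)
    if (!h$phase %in% c("BTS", "ATS", "both") || h$n_targets < 1)
      stop_("config infeasible: bad hub specification")
  structure(list(n_tf = n_tf, n_gene = n_gene, n_metabolite = n_metabolite,
                 times = as.numeric(times), replicates = as.integer(replicates),
                 hubs = hubs, n_minor_regulators = as.integer(n_minor_regulators),
                 background_responder_fraction = background_responder_fraction,
                 noise_sigma = noise_sigma, effect_size = effect_size,
                 fc_threshold = fc_threshold, scale_range = scale_range,
                 baseline_range = baseline_range,
                 truth_seed = as.integer(truth_seed)),
            class = "synth_config")
}

## ---- decorrelated profile pool ------------------------------------------
## Profiles live on the post-baseline grid; constraints and conflicts are
## evaluated on the correlation-window points (0.5-24 h by default).

shift1 <- function(v) c(0, v[-length(v)])

## the six distinct |cor| checks between a candidate and the accepted pool,
## covering target shifts {0,1} x analysis lags {0,1} in both roles
profile_conflict <- function(cand, pool) {
  if (!length(pool$M00)) return(0)
  W <- length(cand)
  m <- suppressWarnings(c(
    abs(cor(cand, pool$M00)), abs(cor(cand, pool$M10)),
    abs(cor(shift1(cand), pool$M00)),
    abs(cor(cand[-W], pool$M01)), abs(cor(cand[-W], pool$M11)),
    abs(cor(cand[-1], pool$M11))))
  max(m, na.rm = TRUE)
}

pool_add <- function(pool, v) {
  W <- length(v)
  pool$M00 <- cbind(pool$M00, v)
  pool$M10 <- cbind(pool$M10, shift1(v))
  pool$M01 <- cbind(pool$M01, v[-1])
  pool$M11 <- cbind(pool$M11, v[-W])
  pool
}

pool_build <- function(profiles) {
  pool <- list(M00 = NULL, M10 = NULL, M01 = NULL, M11 = NULL)
  for (v in profiles) pool <- pool_add(pool, v)
  pool
}

## per-phase profile samplers on the window grid (times within the window);
## wiggly directions scaled to full amplitude keep profiles identifiable
## (high variance) yet mutually decorrelatable (full-rank diversity)
sampler_for <- function(kind, wt, eff) {
  W <- length(wt)
  early <- wt < 6       # before the late window
  pre_pivot <- wt < max(wt[wt <= 4])  # strictly before the last early point
  pivot <- which(wt == max(wt[wt <= 4]))
  switch(kind,
    bts = function() {
      v <- runif(W, -1, 1)
      v[1] <- sample(c(-1, 1), 1) * runif(1, 0.8, 1)
      v * eff / max(abs(v))
    },
    ats = function() {
      s <- sample(c(-1, 1), 1)
      v <- numeric(W)
      v[early] <- runif(sum(early), -0.55, 0.55)
      late <- which(!early)
      v[late] <- s * runif(length(late), 0.8, 0.88 * eff)
      v[late[1]] <- s * runif(1, 1.1, 1.6)
      v[W] <- s * runif(1, 0.6 * eff, eff)
      v
    },
    perm = function() {
      s <- sample(c(-1, 1), 1)
      v <- numeric(W)
      v[pre_pivot] <- runif(sum(pre_pivot), -0.55, 0.55)
      v[pivot] <- s * runif(1, 1.05, 1.35)
      aft <- which(!pre_pivot & seq_len(W) != pivot)
      v[aft] <- s * runif(length(aft), 0.48 * eff, eff)
      v
    },
    free = function() {
      v <- runif(W, -1, 1)
      v * runif(1, 0.6 * eff, eff) / max(abs(v))
    })
}

## greedy packing with a refinement sweep over the worst-conflicted slots
pack_profiles <- function(kinds, wt, eff, cap = 0.8, tries = 400L) {
  profs <- vector("list", length(kinds))
  pool <- pool_build(list())
  for (i in seq_along(kinds)) {
    gen <- sampler_for(kinds[i], wt, eff)
    best <- NULL; bestm <- Inf
    for (k in seq_len(tries)) {
      cand <- gen()
      m <- profile_conflict(cand, pool)
      if (m < bestm) { bestm <- m; best <- cand }
      if (m <= cap) break
    }
    profs[[i]] <- best
    pool <- pool_add(pool, best)
  }
  ## refinement: try to replace the most-conflicted profiles
  conf_of <- function(i) profile_conflict(profs[[i]], pool_build(profs[-i]))
  for (sweep in 1:2) {
    conf <- vapply(seq_along(profs), conf_of, 0)
    for (i in order(conf, decreasing = TRUE)) {
      if (conf[i] <= 0.75) break
      others <- pool_build(profs[-i])
      gen <- sampler_for(kinds[i], wt, eff)
      cur <- conf[i]
      for (k in seq_len(tries)) {
        cand <- gen()
        m <- profile_conflict(cand, others)
        if (m < cur - 0.01) { profs[[i]] <- cand; cur <- m }
        if (cur <= 0.75) break
      }
      conf[i] <- cur
    }
  }
  worst <- if (length(profs) > 1)
    max(vapply(seq_along(profs), conf_of, 0)) else 0
  list(profiles = profs, worst_conflict = worst)
}

## onset/direction bookkeeping on a profile (window points only)
profile_response <- function(v, wt, cfg) {
  thr <- log2(cfg$fc_threshold)
  hit <- which(abs(v) >= thr)
  if (!length(hit))
    return(list(direction = "unchanged", timing = "unaltered", onset = NA_real_))
  o <- hit[1]
  timing <- if (wt[o] > 0 && wt[o] <= 4) "early_BTS"
            else if (wt[o] >= 6 && wt[o] <= 24) "late_ATS" else NA_character_
  list(direction = if (v[o] > 0) "up" else "down", timing = timing,
       onset = wt[o])
}

## ---- truth construction (depends on cfg only, via truth_seed) -----------
build_truth <- function(cfg) {
  wt <- cfg$times[cfg$times >= 0.5 & cfg$times <= 24]   # analysis window
  post <- cfg$times[-1]
  if (length(wt) < 5) stop_("config infeasible: too few window time points")
  if (!any(wt > 0 & wt <= 4) || !any(wt >= 6 & wt <= 24))
    stop_("config infeasible: grid must cover both response windows")
  fam <- c("GNAT", "bHLH", "MYB", "RWP-RK", "SBP", "TRAF", "HB", "VARL",
           "AP2", "GATA", "bZIP", "PHD")
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tf))
  g_ids <- sprintf("G%03d", seq_len(cfg$n_gene))
  m_ids <- sprintf("M%03d", seq_len(cfg$n_metabolite))
  tf_class <- ifelse(seq_len(cfg$n_tf) %% 5 == 0, "TR", "TF")

  n_hub <- length(cfg$hubs)
  hub_ids <- tf_ids[seq_len(n_hub)]
  minor_ids <- tf_ids[n_hub + seq_len(cfg$n_minor_regulators)]
  rest_tf <- setdiff(tf_ids, c(hub_ids, minor_ids))

  ## interleave gene/metabolite ids for target assignment
  pool_ids <- c(rbind(c(g_ids, rep(NA, max(0, cfg$n_metabolite - cfg$n_gene))),
                      c(m_ids, rep(NA, max(0, cfg$n_gene - cfg$n_metabolite)))))
  pool_ids <- pool_ids[!is.na(pool_ids)]
  take <- function(n) {
    out <- pool_ids[seq_len(n)]
    pool_ids <<- pool_ids[-seq_len(n)]
    out
  }
  hub_targets <- lapply(cfg$hubs, function(h) take(h$n_targets))
  minor_targets <- if (cfg$n_minor_regulators)
    as.list(take(cfg$n_minor_regulators)) else list()
  rest_targets <- pool_ids
  n_bg_t <- round(cfg$background_responder_fraction * length(rest_targets))
  bg_targets <- rest_targets[seq_len(n_bg_t)]
  n_bg_tf <- round(cfg$background_responder_fraction * length(rest_tf))
  bg_tf <- rest_tf[seq_len(n_bg_tf)]

  ## decorrelated profile pool for every planted/responding series
  kinds <- c(vapply(cfg$hubs, function(h)
               switch(h$phase, BTS = "bts", ATS = "ats", both = "perm"), ""),
             rep("free", length(minor_ids) + length(bg_tf) + length(bg_targets)))
  pk <- pack_profiles(kinds, wt, cfg$effect_size)
  owners <- c(hub_ids, minor_ids, bg_tf, bg_targets)
  base_prof <- setNames(pk$profiles, owners)

  ## assemble full post-baseline profiles (window + any trailing points)
  full_prof <- function(v) {
    out <- numeric(length(post))
    iw <- match(wt, post)
    out[iw] <- v
    if (max(iw) < length(post)) out[(max(iw) + 1):length(post)] <- v[length(v)]
    out
  }
  profiles <- matrix(0, length(c(tf_ids, g_ids, m_ids)), length(post),
                     dimnames = list(c(tf_ids, g_ids, m_ids), as.character(post)))
  for (id in owners) profiles[id, ] <- full_prof(base_prof[[id]])

  ## non-responders fluctuate within +/-0.3 log2 units
  nonresp <- setdiff(rownames(profiles), owners)
  for (id in nonresp)
    profiles[id, ] <- runif(length(post), -0.3, 0.3)

  ## planted edges: targets are lag-shifted, sign-scaled regulator copies
  shift_full <- function(v, lag) if (lag == 0) v else c(0, v[-length(v)])
  edges <- list(); sgn <- 1
  plant <- function(reg, tgt, lag) {
    s <- sgn; sgn <<- -sgn
    c0 <- s * runif(1, cfg$scale_range[1], cfg$scale_range[2])
    profiles[tgt, ] <<- shift_full(c0 * profiles[reg, ], lag)
    edges[[length(edges) + 1]] <<- data.frame(
      tf = reg, target = tgt, lag = as.integer(lag), sign = as.integer(s))
  }
  for (h in seq_len(n_hub)) {
    spec <- cfg$hubs[[h]]
    tg <- hub_targets[[h]]
    for (j in seq_along(tg)) {
      lag <- if (spec$phase == "both") (j - 1) %% 2 else spec$lag %||% 0L
      plant(hub_ids[h], tg[j], lag)
    }
  }
  for (j in seq_along(minor_ids))
    plant(minor_ids[j], minor_targets[[j]], (j - 1) %% 2)

  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(tf = character(), target = character(), lag = integer(),
               sign = integer())

  ## responder truth from the final profiles
  resp <- lapply(rownames(profiles), function(id) {
    r <- profile_response(profiles[id, match(wt, post)], wt, cfg)
    data.frame(entity = id, direction = r$direction, timing = r$timing,
               onset_time = r$onset, stringsAsFactors = FALSE)
  })
  resp <- do.call(rbind, resp)

  hubs_truth <- data.frame(
    tf_id = hub_ids,
    phase = vapply(cfg$hubs, function(h) h$phase, ""),
    expected_type = vapply(cfg$hubs, function(h)
      switch(h$phase, BTS = "BTS_specific", ATS = "ATS_specific",
             both = "permanent"), ""),
    stringsAsFactors = FALSE)

  ann <- data.frame(
    id = rownames(profiles),
    class = c(tf_class, rep("metabolic_gene", cfg$n_gene),
              rep("metabolite", cfg$n_metabolite)),
    family = c(fam[(seq_len(cfg$n_tf) - 1) %% length(fam) + 1],
               rep(NA_character_, cfg$n_gene + cfg$n_metabolite)),
    stringsAsFactors = FALSE)
  ## round-robin process labels over non-regulator entities; every third
  ## entity carries a second label so multi-process membership is exercised
  nonreg <- which(!is_regulator_class(ann$class))
  pv <- process_vocabulary()
  prs <- vector("list", nrow(ann))
  for (k in seq_along(nonreg)) {
    p <- pv[(k - 1) %% length(pv) + 1]
    if (k %% 3 == 0) p <- c(p, pv[k %% length(pv) + 1])
    prs[[nonreg[k]]] <- p
  }
  ann$processes <- prs

  list(profiles = profiles, annotations = annotations(ann), edges = edges,
       hubs = hubs_truth, responders = resp, worst_conflict = pk$worst_conflict,
       window_times = wt)
}

.truth_cache <- new.env(parent = emptyenv())

#' Generate a synthetic multi-omics time course with planted regulators
#'
#' Produces a replicate-resolved [timecourse()], its [annotations()] table
#' and the generating truth. Identical `(cfg, seed)` give byte-identical
#' output; different seeds redraw only the measurement noise around the
#' same truth (see [synth_config()]).
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed for replicate noise and baselines.
#' @return list of class `synth_dataset` with elements `timecourse`,
#'   `annotations` and `truth` (class `synth_truth`: `edges`, `hubs`,
#'   `responders`, `profiles`, `worst_conflict`).
#' @examples
#' d <- generate_dataset(synth_config(n_tf = 6, n_gene = 8, n_metabolite = 4,
#'                                    hubs = list(list(phase = "BTS",
#'                                                     n_targets = 3, lag = 0L)),
#'                                    n_minor_regulators = 2), seed = 1)
#' d$timecourse
#' @export
generate_dataset <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  key <- paste(deparse(unclass(cfg)), collapse = "")
  truth <- .truth_cache[[key]]
  if (is.null(truth)) {
    truth <- with_seed(cfg$truth_seed, build_truth(cfg))
    .truth_cache[[key]] <- truth
  }
  post <- cfg$times[-1]
  ids <- rownames(truth$profiles)
  long <- with_seed(seed, {
    baseline <- runif(length(ids), cfg$baseline_range[1], cfg$baseline_range[2])
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      mu <- baseline[i] * 2^c(0, truth$profiles[i, ])
      noise <- exp(rnorm(length(mu) * cfg$replicates, 0, cfg$noise_sigma))
      rows[[i]] <- data.frame(
        entity = ids[i],
        time = rep(cfg$times, each = cfg$replicates),
        replicate = rep(seq_len(cfg$replicates), length(cfg$times)),
        value = rep(mu, each = cfg$replicates) * noise)
    }
    do.call(rbind, rows)
  })
  cls <- setNames(truth$annotations$class, truth$annotations$id)
  tc <- timecourse(long, entity_class = cls)
  truth_obj <- structure(
    list(edges = truth$edges, hubs = truth$hubs, responders = truth$responders,
         profiles = truth$profiles, worst_conflict = truth$worst_conflict,
         config = cfg, seed = as.integer(seed)),
    class = "synth_truth")
  structure(list(timecourse = tc, annotations = truth$annotations,
                 truth = truth_obj),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d entities, %d planted edges, %d planted hub(s)\n",
              length(x$timecourse$entity_ids), nrow(x$truth$edges),
              nrow(x$truth$hubs)))
  invisible(x)
}

#' Score recovery of the planted truth
#'
#' Standard set precision/recall (and Jaccard for edges) comparing called
#' edges and hubs with the planted truth, plus the fraction of recovered
#' planted hubs whose phase type matches. Undefined ratios (empty calls)
#' are reported as `NA`.
#'
#' @param called_edges data frame with columns `tf`, `target`.
#' @param called_hubs data frame with columns `tf_id` and (optionally)
#'   `hub_type`; e.g. a [type_hubs()] result.
#' @param truth a `synth_truth` from [generate_dataset()].
#' @return list of class `recovery_score`: `edge_precision`,
#'   `edge_recall`, `edge_jaccard`, `hub_precision`, `hub_recall`,
#'   `type_accuracy`, and the underlying counts.
#' @export
score_recovery <- function(called_edges, called_hubs, truth) {
  stopifnot(inherits(truth, "synth_truth"))
  tkey <- paste(truth$edges$tf, truth$edges$target)
  ckey <- unique(paste(called_edges$tf, called_edges$target))
  tp <- length(intersect(ckey, tkey))
  ep <- if (length(ckey)) tp / length(ckey) else NA_real_
  er <- if (length(tkey)) tp / length(tkey) else NA_real_
  ej <- if (length(union(ckey, tkey))) tp / length(union(ckey, tkey)) else NA_real_
  th <- truth$hubs$tf_id
  ch <- unique(called_hubs$tf_id)
  htp <- length(intersect(ch, th))
  hp <- if (length(ch)) htp / length(ch) else NA_real_
  hr <- if (length(th)) htp / length(th) else NA_real_
  ta <- NA_real_
  if (htp && !is.null(called_hubs$hub_type)) {
    common <- intersect(ch, th)
    got <- called_hubs$hub_type[match(common, called_hubs$tf_id)]
    want <- truth$hubs$expected_type[match(common, th)]
    ta <- mean(got == want)
  }
  structure(list(edge_precision = ep, edge_recall = er, edge_jaccard = ej,
                 hub_precision = hp, hub_recall = hr, type_accuracy = ta,
                 n_called_edges = length(ckey), n_true_edges = length(tkey),
                 n_called_hubs = length(ch), n_true_hubs = length(th)),
            class = "recovery_score")
}

#' @export
print.recovery_score <- function(x, ...) {
  cat(sprintf("edges: precision %s recall %s jaccard %s (called %d / true %d)\n",
              format(x$edge_precision, digits = 3),
              format(x$edge_recall, digits = 3),
              format(x$edge_jaccard, digits = 3),
              x$n_called_edges, x$n_true_edges))
  cat(sprintf("hubs : precision %s recall %s type accuracy %s (called %d / true %d)\n",
              format(x$hub_precision, digits = 3),
              format(x$hub_recall, digits = 3),
              format(x$type_accuracy, digits = 3),
              x$n_called_hubs, x$n_true_hubs))
  invisible(x)
}
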