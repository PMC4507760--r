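## build a network + one subnetwork from explicit degree targets
hub_fixture <- function(deg, n_proc = 2) {
  tfs <- names(deg)
  tgts <- sprintf("g%03d", seq_len(sum(deg)))
  edges <- data.frame(tf = rep(tfs, deg), target = tgts, r = 0.95, lag = 0L,
                      n_pairs = 7L, p = 0.001, sign = 1L)
  ann <- make_ann(c(tfs, tgts), c(rep("TF", length(tfs)),
                                  rep("metabolic_gene", length(tgts))),
                  processes = c(rep("", length(tfs)),
                                process_vocabulary()[seq_along(tgts) %% n_proc + 1]))
  net <- build_network(edges, ann)
  subs <- lapply(setNames(nm = process_vocabulary()),
                 function(p) process_subnetwork(net, p))
  list(net = net, subs = subs, edges = edges, ann = ann)
}

test_that("hubs are the top 5% by degree in whole network and a subnetwork", {
  deg <- setNames(c(10, rep(1, 19)), sprintf("tf%02d", 1:20))
  fx <- hub_fixture(deg)
  hubs <- call_hubs(fx$net, fx$subs)
  expect_equal(hubs$tf_id, "tf01")
  expect_equal(hubs$degree, 10L)
  ## all regulators tied: everyone is at the k-th degree value
  deg2 <- setNames(rep(3, 20), sprintf("tf%02d", 1:20))
  fx2 <- hub_fixture(deg2)
  hubs2 <- call_hubs(fx2$net, fx2$subs)
  expect_setequal(hubs2$tf_id, names(deg2))
})

test_that("hub calling equals the sort-and-intersect oracle on random nets", {
  for (s in 1:30) {
    rn <- random_network(12, 40, 0.12, seed = 300 + s)
    if (!nrow(rn$edges)) next
    net <- build_network(rn$edges, rn$ann)
    subs <- lapply(setNames(nm = process_vocabulary()),
                   function(p) process_subnetwork(net, p))
    got <- sort(call_hubs(net, subs)$tf_id)
    sub_edges <- lapply(subs, lagnet:::edge_table)
    ref <- oracle_call_hubs(lagnet:::edge_table(net), sub_edges)
    expect_equal(got, ref)
  }
})

test_that("hub calling is monotone in the fraction and label-invariant", {
  rn <- random_network(12, 40, 0.15, seed = 999)
  net <- build_network(rn$edges, rn$ann)
  subs <- lapply(setNames(nm = process_vocabulary()),
                 function(p) process_subnetwork(net, p))
  prev <- character()
  for (f in c(0.05, 0.1, 0.25, 0.5)) {
    cur <- call_hubs(net, subs, hub_fraction = f)$tf_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  ## relabelling the nodes relabels the hubs and nothing else
  perm <- setNames(sprintf("X%02d", sample(seq_along(rn$tfs))), rn$tfs)
  edges2 <- rn$edges; edges2$tf <- unname(perm[edges2$tf])
  ann2 <- rn$ann; ann2$id[match(names(perm), ann2$id)] <- unname(perm)
  net2 <- build_network(edges2, ann2)
  subs2 <- lapply(setNames(nm = process_vocabulary()),
                  function(p) process_subnetwork(net2, p))
  expect_setequal(call_hubs(net2, subs2)$tf_id,
                  unname(perm[call_hubs(net, subs)$tf_id]))
})

test_that("edge phases follow onset windows under both schemes", {
  cfg <- lagnet_config()
  calls <- data.frame(
    entity = c("tf_e", "tf_l", "tf_u", "g_e1", "g_e2", "g_l", "g_u"),
    direction = c("up", "up", "unchanged", "up", "down", "up", "unchanged"),
    timing = c("early_BTS", "late_ATS", "unaltered", "early_BTS", "early_BTS",
               "late_ATS", "unaltered"),
    onset_time = c(1, 12, NA, 1, 2, 12, NA), stringsAsFactors = FALSE)
  ed <- function(tf, tg) data.frame(tf = tf, target = tg)
  ## strict two-endpoint rule
  expect_equal(assign_edge_phase(ed("tf_e", "g_e2"), calls, cfg,
                                 scheme = "both_endpoints"), "BTS")
  expect_equal(assign_edge_phase(ed("tf_e", "g_l"), calls, cfg,
                                 scheme = "both_endpoints"), "mixed")
  expect_equal(assign_edge_phase(ed("tf_l", "g_l"), calls, cfg,
                                 scheme = "both_endpoints"), "ATS")
  expect_equal(assign_edge_phase(ed("tf_e", "g_u"), calls, cfg,
                                 scheme = "both_endpoints"), "none")
  ## default target-onset rule: the target's window decides
  expect_equal(assign_edge_phase(ed("tf_e", "g_l"), calls, cfg), "ATS")
  expect_equal(assign_edge_phase(ed("tf_l", "g_e1"), calls, cfg), "BTS")
  expect_equal(assign_edge_phase(ed("tf_u", "g_e1"), calls, cfg), "none")
  expect_error(assign_edge_phase(ed("tf_e", "nowhere"), calls, cfg),
               "unclassified endpoint")
})

test_that("hub typing partitions by clear-phase edges plus the SIM test", {
  deg <- setNames(c(6, 6, 6, rep(1, 57)), sprintf("tf%02d", 1:60))
  fx <- hub_fixture(deg, n_proc = 3)
  ## craft onsets: tf01's targets early, tf02's late, tf03's split
  tgts_of <- function(tf) fx$edges$target[fx$edges$tf == tf]
  ents <- c(sprintf("tf%02d", 1:60), fx$edges$target)
  onset <- setNames(rep(1, length(ents)), ents)
  onset[tgts_of("tf02")] <- 12
  onset[tgts_of("tf03")] <- c(1, 1, 1, 12, 12, 12)
  calls <- data.frame(entity = ents, direction = "up", timing = "early_BTS",
                      onset_time = unname(onset), stringsAsFactors = FALSE)
  hubs <- call_hubs(fx$net, fx$subs)
  typed <- type_hubs(hubs, fx$net, calls)
  ty <- setNames(typed$hub_type, typed$tf_id)
  expect_equal(unname(ty[c("tf01", "tf02", "tf03")]),
               c("BTS_specific", "ATS_specific", "permanent"))
  expect_equal(typed$n_bts[typed$tf_id == "tf03"], 3L)
  expect_equal(typed$n_ats[typed$tf_id == "tf03"], 3L)
  ## every hub gets exactly one type
  expect_true(all(typed$hub_type %in%
                  c("BTS_specific", "ATS_specific", "permanent", "unclassified")))

  ## a specific candidate that is no SIM regulator stays unclassified:
  ## give each tf01 target a second regulator
  extra <- data.frame(tf = "tf04", target = tgts_of("tf01"), r = 0.92,
                      lag = 0L, n_pairs = 7L, p = 0.01, sign = 1L)
  net2 <- build_network(rbind(fx$edges, extra), fx$ann)
  subs2 <- lapply(setNames(nm = process_vocabulary()),
                  function(p) process_subnetwork(net2, p))
  calls2 <- calls  # tf04 and every target are already classified
  hubs2 <- call_hubs(net2, subs2)
  typed2 <- type_hubs(hubs2, net2, calls2)
  expect_equal(typed2$hub_type[typed2$tf_id == "tf01"], "unclassified")
})

test_that("the participation table marks processes and repeats degrees", {
  deg <- setNames(c(5, rep(1, 19)), sprintf("tf%02d", 1:20))
  fx <- hub_fixture(deg, n_proc = 2)  # targets alternate two processes
  hubs <- call_hubs(fx$net, fx$subs)
  ents <- c(names(deg), fx$edges$target)
  calls <- data.frame(entity = ents, direction = "up", timing = "early_BTS",
                      onset_time = 1, stringsAsFactors = FALSE)
  typed <- type_hubs(hubs, fx$net, calls)
  tab <- hub_process_table(typed, fx$net)
  expect_equal(colnames(tab), typed$tf_id)
  marks <- tab[process_vocabulary(), 1]
  expect_equal(sum(marks), 2)  # the hub touches exactly two processes
  expect_equal(unname(unlist(tab["degree", ])), typed$degree)
  ## column sums equal per-hub process counts plus the degree row
  for (j in seq_len(ncol(tab)))
    expect_equal(sum(tab[process_vocabulary(), j]),
                 length(unique(unlist(
                   strsplit(igraph::V(fx$net)[igraph::neighbors(
                     fx$net, colnames(tab)[j])]$processes, ";")))))
})

test_that("planted hub phenotypes are recovered and typed at zero noise", {
  cfg <- synth_config(noise_sigma = 0)
  d <- generate_dataset(cfg, seed = 4)
  fit <- lagnet(d$timecourse, d$annotations, normality = FALSE)
  sc <- score_recovery(fit$edges, fit$hubs, d$truth)
  expect_equal(sc$hub_precision, 1)
  expect_equal(sc$hub_recall, 1)
  expect_equal(sc$type_accuracy, 1)
})
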