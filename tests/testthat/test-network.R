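test_that("networks assemble with the tripartite constraint enforced", {
  ann <- make_ann(c("TF1", "TF2", "g1", "g2", "m1"),
                  c("TF", "TF", "metabolic_gene", "metabolic_gene", "metabolite"),
                  processes = c("", "", "lipid", "nitrogen", "lipid"))
  edges <- data.frame(tf = "TF1", target = c("g1", "g2", "m1"),
                      r = c(0.95, -0.92, 0.99), lag = 0L, n_pairs = 7L,
                      p = 0.01, sign = c(1L, -1L, 1L))
  net <- build_network(edges, ann)
  expect_equal(igraph::vcount(net), 4)
  expect_equal(igraph::ecount(net), 3)
  expect_error(build_network(data.frame(tf = "TF1", target = "TF2", r = 1),
                             ann), "bipartite violation")
  expect_error(build_network(data.frame(tf = "g1", target = "g2", r = 1),
                             ann), "bipartite violation")
  expect_error(build_network(data.frame(tf = "TF1", target = "unknown", r = 1),
                             ann), "unannotated node")
})

test_that("duplicate edges collapse to the strongest correlation", {
  rn <- random_network(6, 18, 0.2, seed = 5)
  dup <- rbind(rn$edges, rn$edges[rep(1:3, 2), ])
  dup$r[nrow(rn$edges) + (1:6)] <- 0.901  # weaker duplicates
  net <- build_network(dup, rn$ann)
  expect_equal(igraph::ecount(net), nrow(rn$edges))
  expect_equal(igraph::vcount(net),
               length(unique(c(rn$edges$tf, rn$edges$target))))
  ## idempotence: rebuilding from the edge table changes nothing
  net2 <- build_network(lagnet:::edge_table(net), rn$ann)
  expect_equal(igraph::ecount(net2), igraph::ecount(net))
  expect_setequal(igraph::V(net2)$name, igraph::V(net)$name)
})

test_that("process subnetworks induce on regulators plus labelled nodes", {
  ann <- make_ann(c("TF1", "g1", "g2"),
                  c("TF", "metabolic_gene", "metabolic_gene"),
                  processes = c("", "lipid", "nitrogen"))
  edges <- data.frame(tf = "TF1", target = c("g1", "g2"), r = c(0.95, 0.91),
                      lag = 0L, n_pairs = 7L, p = 0.01, sign = 1L)
  net <- build_network(edges, ann)
  lip <- process_subnetwork(net, "lipid")
  expect_setequal(igraph::V(lip)$name, c("TF1", "g1"))
  expect_equal(igraph::ecount(lip), 1)
  ## empty process: regulator-only, zero-edge network
  chl <- process_subnetwork(net, "chlorophyll")
  expect_equal(igraph::V(chl)$name, "TF1")
  expect_equal(igraph::ecount(chl), 0)
  expect_error(process_subnetwork(net, "glycolysis"), "unknown process label")
})

test_that("subnetworks partition the whole network when labels cover it", {
  rn <- random_network(7, 25, 0.18, seed = 8)  # every target has a process
  net <- build_network(rn$edges, rn$ann)
  key <- function(g) {
    et <- lagnet:::edge_table(g)
    paste(et$tf, et$target)
  }
  all_edges <- unlist(lapply(process_vocabulary(), function(p)
    key(process_subnetwork(net, p))))
  expect_setequal(all_edges, key(net))
  ## and every subnetwork is contained in its parent
  for (p in c("lipid", "oppp")) {
    sub <- process_subnetwork(net, p)
    expect_true(all(igraph::V(sub)$name %in% igraph::V(net)$name))
    expect_true(all(key(sub) %in% key(net)))
  }
})

test_that("single-input motifs require exclusivity and two targets", {
  ann <- make_ann(c("A", "B", "g1", "g2", "g3"),
                  c("TF", "TF", rep("metabolic_gene", 3)),
                  processes = c("", "", "lipid", "nitrogen", "oppp"))
  star <- data.frame(tf = "A", target = c("g1", "g2", "g3"), r = 0.95,
                     lag = 0L, n_pairs = 7L, p = 0.01, sign = 1L)
  sims <- find_sims(build_network(star, ann))
  expect_length(sims, 1)
  expect_equal(sims[[1]]$regulator, "A")
  expect_equal(sims[[1]]$targets, c("g1", "g2", "g3"))
  ## g2 gains a second regulator: it leaves the motif
  shared <- rbind(star, data.frame(tf = "B", target = "g2", r = 0.93,
                                   lag = 0L, n_pairs = 7L, p = 0.01, sign = 1L))
  sims2 <- find_sims(build_network(shared, ann))
  expect_length(sims2, 1)
  expect_equal(sims2[[1]]$targets, c("g1", "g3"))
})

test_that("motif mining matches exhaustive enumeration on random graphs", {
  for (s in 1:20) {
    rn <- random_network(8, 22, 0.12, seed = 100 + s)
    if (!nrow(rn$edges)) next
    net <- build_network(rn$edges, rn$ann)
    got <- find_sims(net)
    got_l <- setNames(lapply(got, `[[`, "targets"),
                      vapply(got, `[[`, "", "regulator"))
    ref <- oracle_find_sims(lagnet:::edge_table(net), rn$tfs)
    expect_equal(sort_named(got_l), sort_named(ref))
    ## no target in two motifs
    tg <- unlist(got_l)
    expect_equal(anyDuplicated(tg), 0)
  }
})

test_that("merged SIM subnetworks contain exactly the motif edges", {
  ann <- make_ann(c("A", "g1", "g2"), c("TF", "metabolic_gene", "metabolic_gene"),
                  processes = c("", "lipid", "nitrogen"))
  star <- data.frame(tf = "A", target = c("g1", "g2"), r = 0.95, lag = 0L,
                     n_pairs = 7L, p = 0.01, sign = 1L)
  net <- build_network(star, ann)
  sims <- find_sims(net)
  merged <- merge_motifs(sims, net)
  expect_setequal(igraph::V(merged)$name, c("A", "g1", "g2"))
  expect_equal(igraph::ecount(merged), 2)
  ## zero motifs give an empty network
  empty <- merge_motifs(structure(list(), class = "sim_motifs"), net)
  expect_equal(igraph::vcount(empty), 0)
  ## edge count equals the sum of motif target-set sizes
  rn <- random_network(8, 25, 0.15, seed = 77)
  net2 <- build_network(rn$edges, rn$ann)
  sims2 <- find_sims(net2)
  merged2 <- merge_motifs(sims2, net2)
  expect_equal(igraph::ecount(merged2),
               sum(vapply(sims2, function(m) length(m$targets), 0)))
})

test_that("degree statistics summarise hubs and fit binned power laws", {
  ann <- make_ann(c("H", sprintf("g%02d", 1:50)),
                  c("TF", rep("metabolic_gene", 50)),
                  processes = c("", rep("lipid", 50)))
  star <- data.frame(tf = "H", target = sprintf("g%02d", 1:50), r = 0.95,
                     lag = 0L, n_pairs = 7L, p = 0.01, sign = 1L)
  ds <- degree_stats(build_network(star, ann))
  expect_equal(max(ds$histogram_all$degree), 50)
  expect_equal(median(rep(ds$histogram_all$degree, ds$histogram_all$count)), 1)
  expect_true(is.na(ds$scale_free_like))  # two occupied bins: undetermined

  ## configuration model with a planted exponent is recovered within +/-0.4
  set.seed(2024)
  dseq <- sample(1:100, 2000, replace = TRUE, prob = (1:100)^-2.5)
  if (sum(dseq) %% 2) dseq[1] <- dseq[1] + 1
  g <- igraph::sample_degseq(dseq)
  ds2 <- degree_stats(g)
  expect_lt(abs(ds2$exponent - 2.5), 0.4)
  expect_true(ds2$scale_free_like)
  ## an Erdos-Renyi graph is not scale-free-like
  set.seed(2025)
  er <- igraph::sample_gnm(2000, 4000)
  ds3 <- degree_stats(er)
  expect_false(ds3$scale_free_like)
})
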