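times8 <- c(0, 0.5, 1, 2, 4, 6, 12, 24)

test_that("fold changes are ratios to the time-zero replicate mean", {
  times <- c(0, 1, 2)
  vals <- rbind(g1 = c(2, 8, 1), flat = c(5, 5, 5), zero = c(0, 3, 3))
  colnames(vals) <- times
  tc <- make_tc(vals, times)
  fc <- fold_change(tc)
  expect_equal(fc$fc["g1", ], c("1" = 4, "2" = 0.5))
  expect_equal(fc$log2fc["g1", "1"], 2)
  expect_equal(unname(fc$fc["flat", ]), c(1, 1))
  expect_equal(unname(fc$log2fc["flat", ]), c(0, 0))
  ## zero baseline: excluded with a report entry, not silently dropped
  expect_false("zero" %in% rownames(fc$fc))
  expect_equal(fc$exclusions,
               data.frame(entity = "zero", reason = "zero baseline"))
})

test_that("fold change is invariant to rescaling an entity's abundances", {
  set.seed(7)
  for (k in 1:5) {
    v <- matrix(runif(8, 0.5, 20), 1, 8, dimnames = list("e", times8))
    fc1 <- fold_change(make_tc(v, times8))
    fc2 <- fold_change(make_tc(v * runif(1, 0.01, 100), times8))
    expect_equal(fc1$fc, fc2$fc, tolerance = 1e-12)
  }
})

test_that("responses are classified by first 2-fold crossing and window", {
  cfg <- lagnet_config()
  mk_fc <- function(l2) {
    v <- matrix(2^c(0, l2), 1, 8, dimnames = list("e", times8))
    fold_change(make_tc(v, times8))
  }
  ## strong early induction: up, early window
  early <- classify_response(mk_fc(c(2.5, 2.6, 2.4, 2.2, 2.0, 1.8, 1.6)), cfg)
  expect_equal(early$direction, "up")
  expect_equal(early$timing, "early_BTS")
  expect_equal(early$onset_time, 0.5)
  ## never crossing 2-fold in either direction: unchanged/unaltered
  flat <- classify_response(mk_fc(c(0.3, -0.4, 0.6, 0.9, -0.9, 0.5, 0.2)), cfg)
  expect_equal(flat$direction, "unchanged")
  expect_equal(flat$timing, "unaltered")
  expect_true(is.na(flat$onset_time))
  ## slow ramp crossing at 6 h: up, late window
  ramp <- classify_response(mk_fc(c(0.1, 0.4, 0.6, 0.9, 1.2, 1.6, 1.8)), cfg)
  expect_equal(ramp$direction, "up")
  expect_equal(ramp$timing, "late_ATS")
  expect_equal(ramp$onset_time, 6)
  ## early repression: down
  down <- classify_response(mk_fc(c(-1.4, -1.8, -2, -2, -1.5, -1, -0.5)), cfg)
  expect_equal(down$direction, "down")
  expect_equal(down$timing, "early_BTS")
})

test_that("raising the threshold never converts unchanged to a response", {
  set.seed(11)
  v <- matrix(2^cbind(0, matrix(rnorm(20 * 7, 0, 1.2), 20)), 20, 8,
              dimnames = list(sprintf("e%02d", 1:20), times8))
  fc <- fold_change(make_tc(v, times8))
  thresholds <- c(1.5, 2, 3, 5, 10)
  calls <- lapply(thresholds, function(th)
    classify_response(fc, lagnet_config(fc_threshold = th)))
  for (i in seq_along(thresholds)[-1]) {
    was_unchanged <- calls[[i - 1]]$direction == "unchanged"
    expect_true(all(calls[[i]]$direction[was_unchanged] == "unchanged"))
  }
})

test_that("differential selection partitions responders by class", {
  set.seed(3)
  n <- 10
  l2 <- matrix(runif(n * 7, -0.8, 0.8), n)  # none crossing 2-fold
  l2[1, 3] <- 2.1; l2[4, 6] <- -1.5; l2[7, 1] <- 1.2  # three responders
  v <- 2^cbind(0, l2)
  dimnames(v) <- list(sprintf("e%02d", 1:n), times8)
  tc <- make_tc(v, times8)
  ann <- make_ann(rownames(v),
                  rep(c("TF", "metabolic_gene", "metabolite"), length.out = n),
                  processes = rep(c("", "lipid", "nitrogen"), length.out = n))
  fc <- fold_change(tc)
  sel <- select_differential(fc, ann)
  expect_setequal(sel$all, c("e01", "e04", "e07"))
  expect_equal(sel$regulators, c("e01", "e04", "e07")[
    c("e01", "e04", "e07") %in% rownames(v)[ann$class == "TF"]])
  ## infinite threshold: nothing responds
  sel_inf <- select_differential(fc, ann, lagnet_config(fc_threshold = 1e9))
  expect_length(sel_inf$all, 0)
  expect_length(sel_inf$genes_by_process$lipid, 0)
})

test_that("planted responders are recovered exactly at zero noise", {
  d <- generate_dataset(small_synth(noise = 0), seed = 5)
  fc <- fold_change(d$timecourse)
  sel <- select_differential(fc, d$annotations)
  planted <- d$truth$responders$entity[d$truth$responders$direction != "unchanged"]
  expect_setequal(sel$all, planted)
  got <- sel$calls[match(planted, sel$calls$entity), ]
  want <- d$truth$responders[match(planted, d$truth$responders$entity), ]
  expect_equal(got$direction, want$direction)
  expect_equal(got$timing, want$timing)
  expect_equal(got$onset_time, want$onset_time)
})

test_that("skewness behaves symmetrically and vanishes for symmetric data", {
  r1 <- normality_report(matrix(c(-1, 0, 1), 3, 1))
  expect_equal(r1$skewness, 0)
  set.seed(21)
  x <- rnorm(200, 2, 3)^2
  rp <- normality_report(cbind(x, -x))
  expect_equal(rp$skewness[1], -rp$skewness[2])
  expect_equal(rp$se_skew[1], rp$se_skew[2])
})

test_that("z-values are calibrated on normal data and reject exponential", {
  set.seed(31)
  n <- 1000
  inside <- replicate(200, {
    r <- normality_report(matrix(rnorm(n), n, 1))
    abs(r$z_skew) < 1.96 & abs(r$z_kurt) < 1.96
  })
  rate <- mean(inside)
  ## both z's inside +/-1.96 should happen at roughly the joint nominal rate
  se <- sqrt(0.9 * 0.1 / 200)
  expect_gt(rate, 0.9025 - 4 * se)
  expect_lt(rate, 1)
  set.seed(32)
  re <- normality_report(matrix(rexp(n), n, 1))
  expect_lt(re$shapiro_p, 0.05)
  expect_gt(re$z_skew, 1.96)
})

test_that("diagnostics degrade gracefully for tiny samples", {
  r <- normality_report(matrix(c(1, 2), 2, 1))
  expect_true(is.na(r$shapiro_W))
  expect_true(is.na(r$skewness))
  expect_match(r$note, "Shapiro")
  r3 <- normality_report(matrix(c(1, 2, 4), 3, 1))
  expect_false(is.na(r3$skewness))
  expect_true(is.na(r3$kurtosis))
})
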