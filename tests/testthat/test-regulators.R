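simple_net <- function(targets, signs, regulator = "R1") {
  data.frame(regulator = regulator, target = targets, sign = signs,
             stringsAsFactors = FALSE)
}

test_that("activation z follows the consistency formula", {
  universe <- sprintf("g%02d", 1:20)
  de <- data.frame(gene = universe[1:4], direction = 1L)
  # 4 targets, all activating edges onto up genes: z = 4/sqrt(4) = 2
  net <- simple_net(universe[1:4], rep(1L, 4))
  res <- score_regulators(net, de, universe)
  expect_equal(res$activation_z, 2)
  expect_equal(res$n_overlap, 4L)
  # 2 consistent + 2 inconsistent -> 0
  net2 <- simple_net(universe[1:4], c(1L, 1L, -1L, -1L))
  expect_equal(score_regulators(net2, de, universe)$activation_z, 0)
  # flipping every DE direction flips z exactly (sign equivariance)
  de_flip <- transform(de, direction = -direction)
  expect_equal(score_regulators(net, de_flip, universe)$activation_z, -2)
})

test_that("overlap p and z match exhaustive enumeration on small networks", {
  set.seed(99)
  for (case in 1:120) {
    n_univ <- sample(20:40, 1)
    universe <- sprintf("g%03d", seq_len(n_univ))
    n_de <- sample(3:12, 1)
    de <- data.frame(gene = sample(universe, n_de),
                     direction = sample(c(-1L, 1L), n_de, replace = TRUE))
    n_t <- sample(1:15, 1)
    net <- simple_net(sample(universe, n_t),
                      sample(c(-1L, 1L), n_t, replace = TRUE))
    res <- suppressMessages(score_regulators(net, de, universe))
    expect_equal(res$activation_z, ur_z_oracle(net, de), tolerance = 1e-12)
    expect_equal(res$overlap_p,
                 hyper_tail_oracle(res$n_overlap, n_de, n_univ, n_t),
                 tolerance = 1e-12)
    expect_lte(abs(res$activation_z), sqrt(res$n_overlap) + 1e-12)
  }
})

test_that("state calls need both the z and the overlap-p threshold", {
  universe <- sprintf("g%02d", 1:100)
  de <- data.frame(gene = universe[1:10], direction = 1L)
  # 10 targets, 9 of them DE and consistent: strong overlap, z = 9/3 = 3
  net <- simple_net(c(universe[1:9], universe[50]), rep(1L, 10))
  res <- score_regulators(net, de, universe)
  expect_equal(res$state, "activated")
  # inhibition is the mirror image
  net_inh <- simple_net(c(universe[1:9], universe[50]), rep(-1L, 10))
  expect_equal(score_regulators(net_inh, de, universe)$state, "inhibited")
  # strong z but no overlap enrichment (universe-sized membership) stays ns
  de_all <- data.frame(gene = universe, direction = 1L)
  res_ns <- score_regulators(net, de_all, universe)
  expect_equal(res_ns$overlap_p, 1)
  expect_equal(res_ns$state, "ns")
  # DE genes outside the universe are rejected
  expect_error(score_regulators(net, data.frame(gene = "zz", direction = 1L),
                                universe),
               "absent from the universe")
})

test_that("cross-cell-line aggregation applies the supporting-line rule", {
  z_list <- c(2.5, 2.1, 3.0, 2.2, 2.6, 2.4, 1, 0, -1, 0.5)
  results <- lapply(z_list, function(z) {
    data.frame(regulator = "R1", n_targets_universe = 10L, n_overlap = 9L,
               n_consistent = 9L, overlap_p = 0.01, activation_z = z,
               state = ifelse(z > 2, "activated",
                              ifelse(z < -2, "inhibited", "ns")))
  })
  agg <- aggregate_ur_signature(results, min_lines = 6)
  expect_equal(agg$direction, "activated")
  expect_equal(agg$n_supporting, 6L)
  expect_equal(agg$n_evaluable, 10L)
  # all-null z -> empty signature
  null_res <- lapply(rep(0, 10), function(z) {
    data.frame(regulator = "R1", activation_z = z, state = "ns")
  })
  expect_equal(nrow(aggregate_ur_signature(null_res, 6)), 0)
  # mirrored negative calls aggregate as inhibited
  neg <- lapply(-z_list, function(z) {
    data.frame(regulator = "R1", activation_z = z,
               state = ifelse(z < -2, "inhibited", "ns"))
  })
  expect_equal(aggregate_ur_signature(neg, 6)$direction, "inhibited")
  expect_error(aggregate_ur_signature(results, min_lines = 11), "exceeds")
})

test_that("drug-vs-drug comparison assigns scatter quadrants", {
  mk <- function(z, p = 0.01) {
    data.frame(regulator = c("R1", "R2", "R3"), activation_z = z,
               overlap_p = p,
               state = ifelse(z > 2 & p < 0.05, "activated",
                              ifelse(z < -2 & p < 0.05, "inhibited", "ns")))
  }
  cmp <- compare_drugs(mk(c(3, 2.5, 1.9)), mk(c(-3, 2.5, 5)))
  expect_equal(cmp$quadrant, c("A_act_B_inh", "both_activated", "ns"))
  expect_warning(
    out <- compare_drugs(
      data.frame(regulator = "A1", activation_z = 1, overlap_p = 1,
                 state = "ns"),
      data.frame(regulator = "B1", activation_z = 1, overlap_p = 1,
                 state = "ns")),
    "no shared")
  expect_equal(nrow(out), 0)
})

test_that("responder discrimination recovers planted regulators on treatment", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_counts(cfg)
  net <- simulate_causal_network(cfg, sim$truth)
  coh <- simulate_trial_cohort(cfg)
  hk <- coh$annotation$gene[coh$annotation$is_housekeeping]
  norm <- normalize_counts(coh$counts, hk)
  planted <- net$active_regulators$guadecitabine$regulator
  rd <- suppressMessages(
    responder_discrimination(norm, coh$samples, net, planted))
  sig_at <- function(tp) rd$regulator[rd$timepoint == tp & rd$significant]
  expect_equal(length(sig_at("w0")), 0)
  expect_gt(length(sig_at("w4")), 0.8 * length(planted))
  expect_gt(length(sig_at("w12")), 0.8 * length(planted))
  # shuffled labels collapse the recovery to (near) null
  shuf <- coh$samples
  set.seed(1)
  shuf$response <- sample(shuf$response)
  rd0 <- suppressMessages(
    responder_discrimination(norm, shuf, net, planted))
  expect_lt(sum(rd0$significant), 0.2 * nrow(rd0))
  # a timepoint with an empty arm is skipped with a warning
  one_arm <- coh$samples
  one_arm$response[one_arm$timepoint == "w0"] <- "responder"
  expect_warning(
    rd1 <- suppressMessages(
      responder_discrimination(norm, one_arm, net, planted)),
    "skipped")
  expect_false("w0" %in% rd1$timepoint)
})

test_that("timepoint z correlation handles identity, mirror and degeneracy", {
  v <- c(2.1, 3.5, 2.8, 4.2, 1.1)
  expect_equal(timepoint_z_correlation(v, v)$r, 1)
  expect_equal(timepoint_z_correlation(v, -v)$r, -1)
  expect_error(timepoint_z_correlation(v[1:2], v[1:2]), ">= 3")
  res <- timepoint_z_correlation(rep(1, 5), v)
  expect_true(is.na(res$r))
  expect_match(res$note, "zero variance")
  # independent vectors: |r| small on average across seeds
  rs <- sapply(1:20, function(s) {
    set.seed(s)
    timepoint_z_correlation(rnorm(50), rnorm(50))$r
  })
  expect_lt(mean(abs(rs)), 0.2)
})
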