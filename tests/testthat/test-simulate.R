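test_that("panel generation assigns every gene one class with balanced sizes", {
  panel <- generate_panel(sim_config())
  expect_equal(sum(!panel$is_housekeeping), 731)
  expect_equal(length(unique(panel$class[!panel$is_housekeeping])), 21)
  sizes <- table(panel$class[!panel$is_housekeeping])
  expect_lte(diff(range(sizes)), 1)

  one_per <- generate_panel(sim_config(n_genes = 21, n_classes = 21,
                                       n_housekeeping = 0))
  expect_equal(as.vector(table(one_per$class)), rep(1L, 21))

  p100 <- generate_panel(sim_config(n_genes = 100, n_classes = 7,
                                    n_housekeeping = 0))
  sizes <- as.vector(table(p100$class))
  expect_true(all(sizes %in% c(14L, 15L)))
  expect_equal(sum(sizes), 100)

  expect_error(sim_config(n_genes = 5, n_classes = 7), "configuration error")
})

test_that("count simulation is reproducible and respects planted structure", {
  cfg <- tiny_config(seed = 11)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_counts(tiny_config(seed = 12))
  expect_false(identical(s1$counts, s3$counts))

  expect_true(all(s1$counts >= 0))
  expect_true(all(s1$counts == round(s1$counts)))
  # every treated sample has a matched control
  tr <- s1$samples[s1$samples$condition == "treated", ]
  for (i in seq_len(nrow(tr))) {
    expect_true(any(s1$samples$condition == "control" &
                      s1$samples$cell_line == tr$cell_line[i] &
                      s1$samples$drug == tr$drug[i]))
  }
  # planted genes belong to declared responsive classes; housekeeping never
  ann <- s1$annotation
  for (d in names(s1$truth$responsive_genes)) {
    g <- s1$truth$responsive_genes[[d]]
    expect_true(all(g$direction %in% c(-1L, 1L)))
    expect_true(all(g$gene %in% ann$gene[!ann$is_housekeeping]))
    declared <- sprintf("C%02d", cfg$planted_effects[[d]]$classes)
    expect_true(all(ann$class[match(g$gene, ann$gene)] %in% declared))
  }
  expect_error(sim_config(nb_dispersion = 0), "configuration error")
})

test_that("planted fold changes shift treated/control ratios as constructed", {
  # strong effect, tiny dispersion, no library-size noise: mean ratio -> 2
  cfg <- sim_config(
    n_genes = 200, n_classes = 4, n_housekeeping = 5,
    cell_lines = sprintf("CL%02d", 1:6), drugs = "guadecitabine",
    planted_effects = list(guadecitabine = list(
      classes = 1:2, log2fc_mean = 1, log2fc_sd = 1e-9,
      frac_genes = 1, frac_lines = 1, prob_up = 1)),
    nb_dispersion = 1e-3, library_size_lognormal_sigma = 1e-9, seed = 3)
  sim <- simulate_counts(cfg)
  planted <- sim$truth$responsive_genes$guadecitabine$gene
  trt <- sim$samples$sample[sim$samples$condition == "treated"]
  ctl <- sim$samples$sample[sim$samples$condition == "control"]
  ratios <- rowMeans(sim$counts[planted, trt]) /
    rowMeans(sim$counts[planted, ctl])
  expect_equal(mean(ratios), 2, tolerance = 0.02)
})

test_that("null simulation produces symmetric, rare modulation calls", {
  n_up <- n_down <- n_rows <- 0L
  for (s in 5:8) {
    cfg <- tiny_config(planted_effects = NULL, seed = s)
    mods <- modulate_sim(simulate_counts(cfg))
    n_up <- n_up + sum(mods$call == "up")
    n_down <- n_down + sum(mods$call == "down")
    n_rows <- n_rows + nrow(mods)
  }
  # calls within a treated/control pair share normalization factors, so the
  # spread exceeds the independent-binomial bound; assert relative symmetry
  # pooled over seeds
  expect_lt(abs(n_up - n_down) / (n_up + n_down), 0.25)
  expect_lt((n_up + n_down) / n_rows, 0.2)
})

test_that("causal network consistency and structure follow the config", {
  cfg <- tiny_config(seed = 7, regulator_consistency = 1)
  sim <- simulate_counts(cfg)
  net <- simulate_causal_network(cfg, sim$truth)
  expect_false(anyDuplicated(net$edges[c("regulator", "target")]) > 0)
  expect_true(all(net$edges$sign %in% c(-1L, 1L)))
  # consistency 1: every planted edge onto a responsive target matches its
  # planted direction exactly
  for (d in names(net$active_regulators)) {
    truth_g <- sim$truth$responsive_genes[[d]]
    dirs <- setNames(truth_g$direction, truth_g$gene)
    for (r in net$active_regulators[[d]]$regulator) {
      ed <- net$edges[net$edges$regulator == r, ]
      onto <- ed$target %in% names(dirs)
      expect_true(all(ed$sign[onto] == dirs[ed$target[onto]]))
    }
  }
  # binomial check on the default 0.9 consistency over several seeds
  hits <- 0L
  tot <- 0L
  for (s in 1:5) {
    cfg9 <- tiny_config(seed = s)
    sim9 <- simulate_counts(cfg9)
    net9 <- simulate_causal_network(cfg9, sim9$truth)
    for (d in names(net9$active_regulators)) {
      truth_g <- sim9$truth$responsive_genes[[d]]
      dirs <- setNames(truth_g$direction, truth_g$gene)
      for (r in net9$active_regulators[[d]]$regulator) {
        ed <- net9$edges[net9$edges$regulator == r, ]
        onto <- ed$target %in% names(dirs)
        hits <- hits + sum(ed$sign[onto] == dirs[ed$target[onto]])
        tot <- tot + sum(onto)
      }
    }
  }
  expect_lt(abs(hits / tot - 0.9), 3 * sqrt(0.9 * 0.1 / tot))
  expect_error(
    simulate_causal_network(
      tiny_config(targets_per_regulator = c(100L, 200L)), sim$truth),
    "exceeds panel size")
})

test_that("trial cohort plants monotone induction in responders only", {
  cfg <- tiny_config(seed = 9, n_patients = 16, n_induced_genes = 10)
  coh <- simulate_trial_cohort(cfg)
  expect_gt(nrow(coh$induced_genes), 0)
  means_by <- function(resp, tp) {
    idx <- coh$samples$response == resp & coh$samples$timepoint == tp
    mean(coh$counts[coh$induced_genes$gene, coh$samples$sample[idx]])
  }
  m_resp <- sapply(cfg$timepoints, means_by, resp = "responder")
  expect_true(m_resp[1] < m_resp[2] && m_resp[2] < m_resp[3])
  m_non <- sapply(cfg$timepoints, means_by, resp = "nonresponder")
  expect_lt(max(m_non) / min(m_non), 1.3)  # exchangeable, no trend planted
  expect_error(simulate_trial_cohort(tiny_config(responder_fraction = 1)),
               "strictly in")
  expect_error(simulate_trial_cohort(tiny_config(timepoints = "w0",
                                                 induction_log2fc = 0)),
               "at least 2 timepoints")
})

test_that("survival generator plants protective effects with target censoring", {
  cfg <- tiny_config(seed = 13, n_subjects = 400, n_protective_genes = 3,
                     n_null_survival_genes = 3)
  sv <- simulate_survival(cfg)
  expect_true(all(sv$survival$time > 0))
  expect_true(all(sv$survival$event %in% c(0L, 1L)))
  expect_lt(abs(mean(sv$survival$event == 0) - 0.3), 0.12)
  # higher protective-gene expression -> longer observed survival
  g <- sv$protective_genes[1]
  hi <- sv$survival$time[sv$survival[[g]] > 0 & sv$survival$event == 1]
  lo <- sv$survival$time[sv$survival[[g]] <= 0 & sv$survival$event == 1]
  expect_gt(median(hi), median(lo))
  # full censoring -> the screen rejects the design
  cfg_c <- tiny_config(seed = 13, censoring_fraction = 1)
  sv_c <- simulate_survival(cfg_c)
  expect_error(cox_screen(sv_c$survival), "censored")
})

test_that("config YAML round-trips through read/write", {
  cfg <- tiny_config(seed = 21)
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_identical(simulate_counts(cfg)$counts, simulate_counts(cfg2)$counts)
})
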