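# Independent brute-force oracles used to cross-check the analytical
# implementations, plus small simulation fixtures shared across tests.

# Upstream-regulator activation z by explicit edge-by-edge counting
# (unit weights).
ur_z_oracle <- function(edges, de) {
  dir <- setNames(de$direction, de$gene)
  n_c <- 0L
  n_i <- 0L
  for (i in seq_len(nrow(edges))) {
    g <- edges$target[i]
    if (!g %in% names(dir)) next
    if (edges$sign[i] * dir[[g]] > 0) n_c <- n_c + 1L else n_i <- n_i + 1L
  }
  if (n_c + n_i == 0L) 0 else (n_c - n_i) / sqrt(n_c + n_i)
}

# Upper-tail hypergeometric probability by direct summation of the
# combinatorial mass function: P(overlap >= k) drawing `draws` targets from
# a universe of size `n_univ` containing `n_de` DE genes.
hyper_tail_oracle <- function(k, n_de, n_univ, draws) {
  js <- seq(k, min(draws, n_de))
  if (length(js) == 0L || k <= 0) return(1)
  sum(choose(n_de, js) * choose(n_univ - n_de, draws - js)) /
    choose(n_univ, draws)
}

# Running enrichment score by explicit step-by-step accumulation.
es_oracle <- function(genes_ranked, scores, geneset, p = 1) {
  n <- length(genes_ranked)
  hit <- genes_ranked %in% geneset
  nh <- sum(hit)
  w <- abs(scores)^p
  tot <- sum(w[hit])
  if (tot == 0) {
    w <- rep(1, n)
    tot <- nh
  }
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) w[i] / tot else -1 / (n - nh)
    # keep the earliest extremum on a magnitude tie
    if (abs(run) > abs(best) + 1e-9) best <- run
  }
  best
}

# Small panel configuration used where full study scale is not needed.
tiny_config <- function(...) {
  defaults <- list(n_genes = 60, n_classes = 6, n_housekeeping = 5,
                   cell_lines = sprintf("CL%02d", 1:4),
                   drugs = c("guadecitabine", "JQ1"),
                   n_regulators = 10, regulators_per_drug = 3,
                   targets_per_regulator = c(5L, 8L),
                   n_patients = 8, n_subjects = 150)
  args <- utils::modifyList(defaults, list(...), keep.null = TRUE)
  do.call(sim_config, args)
}

# Run the cell-line half of the pipeline (normalize -> modulation calls) on
# a simulated experiment.
modulate_sim <- function(sim, tau = 1.5, min_control = 20) {
  hk <- sim$annotation$gene[sim$annotation$is_housekeeping]
  norm <- normalize_counts(sim$counts, hk)
  compute_modulation(norm, sim$samples, tau = tau, min_control = min_control)
}

# Signed DE list from modulation calls for one (drug, cell line).
de_from_mods <- function(mods, drug, cell_line) {
  sub <- mods[mods$drug == drug & mods$cell_line == cell_line &
                mods$call != "none", ]
  data.frame(gene = sub$gene,
             direction = ifelse(sub$call == "up", 1L, -1L),
             stringsAsFactors = FALSE)
}
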