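# Upstream-regulator (UR) analysis on a signed causal network: overlap
# enrichment + activation z-score, state calls, cross-cell-line aggregation,
# drug-vs-drug comparison and the responder-discrimination timecourse.

normalize_de <- function(de) {
  if (is.data.frame(de)) {
    stopifnot(all(c("gene", "direction") %in% names(de)))
    de <- de[, c("gene", "direction")]
  } else if (is.numeric(de) && !is.null(names(de))) {
    de <- data.frame(gene = names(de), direction = as.integer(sign(de)),
                     stringsAsFactors = FALSE)
  } else {
    stop("de must be a data.frame(gene, direction) or a named signed vector")
  }
  if (anyDuplicated(de$gene)) stop("duplicate genes in DE list")
  if (!all(de$direction %in% c(-1L, 1L))) {
    stop("DE directions must be +1 or -1")
  }
  de
}

#' Score upstream regulators against a signed DE gene list
#'
#' For each regulator, computes (i) the upper-tail hypergeometric probability
#' that its measured targets overlap the differentially expressed set at
#' least as much as observed, and (ii) the activation z-score
#' `z = sum(w_e * c_e) / sqrt(sum(w_e^2))` over overlapping edges, where
#' `c_e = +1` when edge sign x DE direction is consistent with regulator
#' activation and `-1` otherwise (with unit weights,
#' `z = (N_consistent - N_inconsistent) / sqrt(N)`). A regulator is called
#' `activated` when `z > z_threshold` and `overlap_p < p_threshold`,
#' `inhibited` for the mirrored condition, otherwise `ns`.
#'
#' @param network data.frame edge list with columns `regulator`, `target`,
#'   `sign` (+1/-1) and optionally `weight` (positive, default 1); or a
#'   [simulate_causal_network()] object.
#' @param de Signed DE gene list: data.frame(`gene`, `direction` in +1/-1)
#'   or a named signed numeric vector. Must be a subset of `universe`.
#' @param universe Character vector of measured genes; regulators are scored
#'   only against targets in this universe (regulators with none are omitted
#'   with a message).
#' @param z_threshold,p_threshold State-call thresholds (defaults 2 and
#'   0.05).
#' @param adjust Apply Benjamini-Hochberg correction to the overlap p-values
#'   before the state call (default FALSE: raw p-values gate the call).
#' @return data.frame of class `ur_result`: one row per scored regulator
#'   with `n_targets_universe`, `n_overlap`, `n_consistent`, `overlap_p`,
#'   `activation_z`, `state`.
#' @export
score_regulators <- function(network, de, universe, z_threshold = 2,
                             p_threshold = 0.05, adjust = FALSE) {
  if (inherits(network, "causal_network_sim")) network <- network$edges
  stopifnot(all(c("regulator", "target", "sign") %in% names(network)))
  if (!all(network$sign %in% c(-1, 1))) stop("edge signs must be +1 or -1")
  if (anyDuplicated(network[c("regulator", "target")])) {
    stop("duplicate (regulator, target) edges")
  }
  if (is.null(network$weight)) network$weight <- 1
  if (any(network$weight <= 0)) stop("edge weights must be positive")
  universe <- unique(as.character(universe))
  de <- normalize_de(de)
  if (!all(de$gene %in% universe)) {
    stop("DE genes absent from the universe: ",
         paste(utils::head(setdiff(de$gene, universe), 5), collapse = ", "))
  }
  net <- network[network$target %in% universe, , drop = FALSE]
  dropped <- setdiff(unique(network$regulator), unique(net$regulator))
  if (length(dropped)) {
    message(length(dropped),
            " regulator(s) with no measured targets omitted")
  }
  dir_map <- stats::setNames(de$direction, de$gene)
  n_univ <- length(universe)
  n_de <- nrow(de)
  regs <- sort(unique(net$regulator))
  rows <- lapply(regs, function(r) {
    ed <- net[net$regulator == r, , drop = FALSE]
    hit <- ed$target %in% de$gene
    k <- sum(hit)
    p <- stats::phyper(k - 1, n_de, n_univ - n_de, nrow(ed),
                       lower.tail = FALSE)
    z <- if (k == 0) {
      0
    } else {
      w <- ed$weight[hit]
      ce <- ed$sign[hit] * dir_map[ed$target[hit]]
      sum(w * ce) / sqrt(sum(w^2))
    }
    data.frame(regulator = r, n_targets_universe = nrow(ed),
               n_overlap = k,
               n_consistent = if (k == 0) 0L else
                 sum(ed$sign[hit] * dir_map[ed$target[hit]] > 0),
               overlap_p = p, activation_z = z, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  p_call <- if (adjust) stats::p.adjust(res$overlap_p, "BH") else res$overlap_p
  res$state <- ifelse(
    res$activation_z > z_threshold & p_call < p_threshold, "activated",
    ifelse(res$activation_z < -z_threshold & p_call < p_threshold,
           "inhibited", "ns"))
  attr(res, "z_threshold") <- z_threshold
  attr(res, "p_threshold") <- p_threshold
  class(res) <- c("ur_result", class(res))
  res
}

#' Aggregate regulator calls across cell lines into a UR signature
#'
#' A regulator enters the signature as `activated` when it is called
#' activated in at least `min_lines` cell lines (symmetrically for
#' `inhibited`). Regulators qualifying in both directions are excluded with
#' a message.
#'
#' @param results Named list of [score_regulators()] tables, one per cell
#'   line (>= 2).
#' @param min_lines Minimum number of supporting cell lines (default 6,
#'   i.e. more than half of a 10-line panel).
#' @return data.frame of class `ur_signature`: `regulator`, `direction`,
#'   `n_supporting`, `n_evaluable`.
#' @export
aggregate_ur_signature <- function(results, min_lines = 6) {
  if (length(results) < 2L) stop("need results from >= 2 cell lines")
  if (min_lines > length(results)) {
    stop("min_lines (", min_lines, ") exceeds the number of cell lines (",
         length(results), ")")
  }
  regs <- sort(unique(unlist(lapply(results, `[[`, "regulator"))))
  n_eval <- n_act <- n_inh <- stats::setNames(integer(length(regs)), regs)
  for (res in results) {
    idx <- match(res$regulator, regs)
    n_eval[idx] <- n_eval[idx] + 1L
    n_act[idx] <- n_act[idx] + (res$state == "activated")
    n_inh[idx] <- n_inh[idx] + (res$state == "inhibited")
  }
  act_in <- n_act >= min_lines
  inh_in <- n_inh >= min_lines
  conflict <- act_in & inh_in
  if (any(conflict)) {
    message("excluding regulator(s) with conflicting directions: ",
            paste(regs[conflict], collapse = ", "))
    act_in[conflict] <- inh_in[conflict] <- FALSE
  }
  keep <- act_in | inh_in
  out <- data.frame(
    regulator = regs[keep],
    direction = ifelse(act_in[keep], "activated", "inhibited"),
    n_supporting = ifelse(act_in[keep], n_act[keep], n_inh[keep]),
    n_evaluable = n_eval[keep], row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "min_lines") <- min_lines
  class(out) <- c("ur_signature", class(out))
  out
}

#' Compare regulator states between two drugs
#'
#' Pairs two [score_regulators()] tables on their shared regulators and
#' assigns each regulator to a scatter-plot quadrant: `both_activated`,
#' `both_inhibited`, `A_act_B_inh`, `A_inh_B_act`, or `ns` when either
#' state is non-significant.
#'
#' @param res_a,res_b [score_regulators()] tables for drugs A and B scored
#'   on a shared regulator universe.
#' @return data.frame with per-regulator z, p and state for both drugs and
#'   the `quadrant`; empty (with a warning) when the regulator sets are
#'   disjoint.
#' @export
compare_drugs <- function(res_a, res_b) {
  shared <- intersect(res_a$regulator, res_b$regulator)
  if (length(shared) == 0L) {
    warning("no shared regulators between the two result tables")
    return(data.frame(regulator = character(), z_a = numeric(),
                      z_b = numeric(), quadrant = character()))
  }
  a <- res_a[match(shared, res_a$regulator), ]
  b <- res_b[match(shared, res_b$regulator), ]
  quadrant <- rep("ns", length(shared))
  quadrant[a$state == "activated" & b$state == "activated"] <- "both_activated"
  quadrant[a$state == "inhibited" & b$state == "inhibited"] <- "both_inhibited"
  quadrant[a$state == "activated" & b$state == "inhibited"] <- "A_act_B_inh"
  quadrant[a$state == "inhibited" & b$state == "activated"] <- "A_inh_B_act"
  data.frame(regulator = shared,
             z_a = a$activation_z, p_a = a$overlap_p, state_a = a$state,
             z_b = b$activation_z, p_b = b$overlap_p, state_b = b$state,
             quadrant = quadrant, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-timepoint responder discrimination via regulator activation
#'
#' At each biopsy timepoint, ranks genes by responder vs non-responder
#' log2 fold change, thresholds the ranking into a signed DE list
#' (|log2FC| > `lfc_threshold`), scores the causal network against it and
#' restricts the result to the regulators of a UR signature. Only entries
#' with activation z above `z_threshold` are flagged significant.
#'
#' @param counts Normalized genes x samples matrix for the cohort.
#' @param samples data.frame with columns `sample`, `timepoint`, `response`
#'   ("responder"/"nonresponder").
#' @param network Causal network edge list (see [score_regulators()]).
#' @param signature An [aggregate_ur_signature()] object or character vector
#'   of regulator identifiers to track.
#' @param lfc_threshold DE threshold on |log2FC| (default log2(1.5), the
#'   modulation call threshold).
#' @param z_threshold Significance threshold on the activation z (default 2).
#' @param pseudocount Passed to [rank_genes()].
#' @return data.frame with one row per (timepoint, signature regulator):
#'   `activation_z`, `overlap_p`, `n_overlap`, `significant`. Timepoints
#'   with an empty arm are skipped with a warning.
#' @export
responder_discrimination <- function(counts, samples, network, signature,
                                     lfc_threshold = log2(1.5),
                                     z_threshold = 2, pseudocount = 1) {
  sig_regs <- if (inherits(signature, "ur_signature")) {
    signature$regulator
  } else {
    as.character(signature)
  }
  # tolerate samples excluded upstream (e.g. by normalization)
  samples <- samples[samples$sample %in% colnames(counts), , drop = FALSE]
  tps <- unique(samples$timepoint)
  out <- list()
  for (tp in tps) {
    ss <- samples[samples$timepoint == tp, , drop = FALSE]
    rs <- ss$sample[ss$response == "responder"]
    ns <- ss$sample[ss$response == "nonresponder"]
    if (length(rs) == 0L || length(ns) == 0L) {
      warning("timepoint ", tp, " skipped: one arm is empty")
      next
    }
    ranked <- rank_genes(counts, rs, ns, method = "log2fc",
                         pseudocount = pseudocount)
    de <- ranked[abs(ranked$score) > lfc_threshold, , drop = FALSE]
    de_list <- data.frame(gene = de$gene,
                          direction = as.integer(sign(de$score)),
                          stringsAsFactors = FALSE)
    res <- score_regulators(network, de_list, universe = rownames(counts),
                            z_threshold = z_threshold)
    res <- res[res$regulator %in% sig_regs, , drop = FALSE]
    if (nrow(res) == 0L) next
    out[[tp]] <- data.frame(
      timepoint = tp, regulator = res$regulator,
      activation_z = res$activation_z, overlap_p = res$overlap_p,
      n_overlap = res$n_overlap,
      significant = res$activation_z > z_threshold,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(timepoint = character(), regulator = character(),
                      activation_z = numeric(), overlap_p = numeric(),
                      n_overlap = integer(), significant = logical()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Correlation of regulator activation z-scores between two timepoints
#'
#' Pearson correlation (with two-sided p) of paired activation z vectors,
#' e.g. w4 vs w12. Vectors sharing names are matched on them.
#'
#' @param z_a,z_b Numeric vectors (optionally named by regulator) with at
#'   least 3 shared entries.
#' @return list with `r`, `p`, `n`; when either vector has zero variance the
#'   correlation is undefined and `r`/`p` are `NA` with a `note`.
#' @export
timepoint_z_correlation <- function(z_a, z_b) {
  if (!is.null(names(z_a)) && !is.null(names(z_b))) {
    shared <- intersect(names(z_a), names(z_b))
    z_a <- z_a[shared]
    z_b <- z_b[shared]
  }
  if (length(z_a) != length(z_b)) stop("paired vectors of equal length required")
  if (length(z_a) < 3L) stop("need >= 3 shared regulators")
  if (stats::sd(z_a) == 0 || stats::sd(z_b) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(z_a),
                note = "undefined: zero variance in one vector"))
  }
  ct <- stats::cor.test(z_a, z_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(z_a))
}
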