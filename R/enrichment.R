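# Pre-ranked GSEA: differential ranking statistic, weighted
# Kolmogorov-Smirnov running enrichment score, and a gene-permutation
# p-value / normalized enrichment score.

#' Rank genes by a between-condition differential statistic
#'
#' Produces a complete descending ranking of the measured universe by either
#' the log2 fold change of group means (with pseudocount) or a signed
#' (Welch) t-statistic on log2 counts. Ties are broken by gene identifier so
#' the ranking is deterministic.
#'
#' @param expr Genes x samples (normalized) matrix with rownames.
#' @param group_a,group_b Column names (or indices) of the two groups; the
#'   score is A vs B. `log2fc` needs >= 1 sample per group, `signed_t`
#'   needs >= 2.
#' @param method `"log2fc"` (default) or `"signed_t"`.
#' @param pseudocount Added to group means (log2fc) or counts (signed_t).
#' @return data.frame of class `ranked_list` with columns `gene`, `score`,
#'   ordered by decreasing score.
#' @export
rank_genes <- function(expr, group_a, group_b,
                       method = c("log2fc", "signed_t"), pseudocount = 1) {
  method <- match.arg(method)
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  if (ncol(a) == 0L || ncol(b) == 0L) stop("empty comparison group")
  if (method == "log2fc") {
    score <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
  } else {
    if (ncol(a) < 2L || ncol(b) < 2L) {
      stop("signed_t needs >= 2 samples per group")
    }
    la <- log2(a + pseudocount)
    lb <- log2(b + pseudocount)
    ma <- rowMeans(la)
    mb <- rowMeans(lb)
    va <- rowSums((la - ma)^2) / (ncol(a) - 1L)
    vb <- rowSums((lb - mb)^2) / (ncol(b) - 1L)
    se <- sqrt(va / ncol(a) + vb / ncol(b))
    score <- ifelse(se == 0, 0, (ma - mb) / se)
  }
  ord <- order(-score, rownames(expr))
  out <- data.frame(gene = rownames(expr)[ord], score = unname(score[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", class(out))
  out
}

# Core running-sum computation on a pre-sorted ranking. `hit` is a logical
# vector over positions, `w` the |score|^p weights.
es_core <- function(hit, w) {
  nh <- sum(hit)
  n <- length(hit)
  wh <- w * hit
  tot <- sum(wh)
  if (tot == 0) {           # all-zero scores: fall back to equal increments
    wh <- as.numeric(hit)
    tot <- nh
  }
  running <- cumsum(wh / tot - (!hit) / (n - nh))
  # extremum tie-break: earliest position within numerical tolerance of the
  # maximal |deviation| (positive and negative excursions can tie exactly)
  peak <- which(abs(running) >= max(abs(running)) - 1e-9)[1]
  list(es = running[peak], running = running, peak = peak)
}

#' Running enrichment score of a gene set in a ranked list
#'
#' Classic weighted Kolmogorov-Smirnov running sum: at each position a gene
#' set member increments the sum by `|score|^p` normalized by the total hit
#' mass, a non-member decrements it by `1/(N - N_hit)`. The enrichment score
#' (ES) is the signed extremum of the running sum.
#'
#' @param ranked A [rank_genes()] data.frame (or any data.frame with `gene`
#'   and `score`); re-sorted deterministically if needed.
#' @param geneset Character vector; at least one member must be in the
#'   ranked universe. A set spanning the whole universe yields ES 0 with a
#'   warning (the running sum is structurally degenerate).
#' @param p Weighting exponent on |score| (default 1; 0 gives the unweighted
#'   KS statistic).
#' @return list with `es`, `running` (length-N profile), `hit_positions`,
#'   `peak` (position of the extremum).
#' @export
running_es <- function(ranked, geneset, p = 1) {
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  ranked <- ranked[order(-ranked$score, ranked$gene), , drop = FALSE]
  hit <- ranked$gene %in% geneset
  nh <- sum(hit)
  n <- nrow(ranked)
  if (nh == 0L) stop("no gene set members in the ranked universe")
  if (nh == n) {
    warning("gene set spans the entire universe; ES set to 0")
    return(list(es = 0, running = rep(0, n), hit_positions = seq_len(n),
                peak = NA_integer_))
  }
  core <- es_core(hit, abs(ranked$score)^p)
  list(es = core$es, running = core$running, hit_positions = which(hit),
       peak = core$peak)
}

#' Pre-ranked GSEA with a gene-permutation null
#'
#' Computes the enrichment score of `geneset` in `ranked` and a permutation
#' p-value from random gene-label sets of equal size:
#' `p = (1 + #\{null ES at least as extreme, same sign\}) / (1 + n_perm)`.
#' The normalized enrichment score (NES) divides the observed ES by the mean
#' |null ES| of the same sign. Identical seed gives identical results.
#'
#' @inheritParams running_es
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `gsea_result`: list with `es`, `nes`, `p_perm`,
#'   `n_perm`, `leading_edge`, `seed`, `running`, `hit_positions`.
#' @export
gsea_pvalue <- function(ranked, geneset, n_perm = 1000, seed = 1, p = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  geneset <- unique(as.character(geneset))
  if (length(geneset) > nrow(ranked)) {
    stop("gene set larger than the ranked universe")
  }
  members <- intersect(geneset, ranked$gene)
  if (length(members) == nrow(ranked)) {
    warning("gene set spans the entire universe; ES set to 0")
    return(structure(list(es = 0, nes = NA_real_, p_perm = 1,
                          n_perm = n_perm, leading_edge = character(),
                          seed = seed, running = rep(0, nrow(ranked)),
                          hit_positions = seq_len(nrow(ranked))),
                     class = "gsea_result"))
  }
  obs <- running_es(ranked, members, p = p)
  ranked <- ranked[order(-ranked$score, ranked$gene), , drop = FALSE]
  n <- nrow(ranked)
  k <- length(members)
  w <- abs(ranked$score)^p
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    hit <- logical(n)
    hit[sample.int(n, k)] <- TRUE
    es_core(hit, w)$es
  }, numeric(1)))
  if (obs$es >= 0) {
    p_perm <- (1 + sum(null_es >= obs$es)) / (1 + n_perm)
    denom <- mean(null_es[null_es > 0])
  } else {
    p_perm <- (1 + sum(null_es <= obs$es)) / (1 + n_perm)
    denom <- mean(abs(null_es[null_es < 0]))
  }
  nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
  hits <- obs$hit_positions
  leading <- if (is.na(obs$peak)) {
    character()
  } else if (obs$es >= 0) {
    ranked$gene[hits[hits <= obs$peak]]
  } else {
    ranked$gene[hits[hits >= obs$peak]]
  }
  structure(list(es = obs$es, nes = nes, p_perm = p_perm, n_perm = n_perm,
                 leading_edge = leading, seed = seed, running = obs$running,
                 hit_positions = hits),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("Pre-ranked GSEA result\n")
  cat(sprintf("  ES = %.3f, NES = %.3f, p = %.4g (%d permutations)\n",
              x$es, x$nes, x$p_perm, x$n_perm))
  cat(sprintf("  leading edge: %d genes\n", length(x$leading_edge)))
  invisible(x)
}
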