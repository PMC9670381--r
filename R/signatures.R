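# Drug-specific gene signatures: cross-cell-line call frequency rule,
# multi-set Venn partitions, and overlap scoring against external gene lists.

#' Derive a drug-specific gene signature
#'
#' A gene enters the signature when the fraction of evaluable cell lines
#' sharing its majority call direction is at least `min_support`; the
#' signature direction is that majority sign. Genes with equally many up and
#' down calls (including none at all) are excluded as ties.
#'
#' @param mods A [compute_modulation()] table covering >= 2 cell lines for
#'   the drug.
#' @param drug Drug identifier present in `mods`.
#' @param min_support Minimum supporting fraction of evaluable cell lines
#'   (default 0.5, mirroring the "more than half of cell lines" aggregation
#'   rule used for regulators).
#' @param annotation Optional data.frame mapping `gene` to `class`; when
#'   supplied a `class` column is added.
#' @return data.frame of class `drug_signature`: one row per signature gene
#'   with `direction` ("up"/"down"), `support`, `n_up`, `n_down`,
#'   `n_evaluable`.
#' @export
derive_signature <- function(mods, drug, min_support = 0.5,
                             annotation = NULL) {
  if (!drug %in% mods$drug) stop("drug not present in modulation table: ", drug)
  sub <- mods[mods$drug == drug, , drop = FALSE]
  if (length(unique(sub$cell_line)) < 2L) {
    stop("need >= 2 evaluable cell lines for drug ", drug)
  }
  genes <- sort(unique(sub$gene))
  key <- factor(sub$gene, levels = genes)
  n_eval <- as.vector(tapply(sub$cell_line, key,
                             function(x) length(unique(x))))
  n_up <- as.vector(tapply(sub$call == "up", key, sum))
  n_down <- as.vector(tapply(sub$call == "down", key, sum))
  maj <- pmax(n_up, n_down)
  tie <- n_up == n_down            # covers the 0/0 case
  support <- maj / n_eval
  keep <- !tie & maj > 0 & support >= min_support
  sig <- data.frame(
    drug = rep(drug, sum(keep)), gene = genes[keep],
    direction = ifelse(n_up[keep] > n_down[keep], "up", "down"),
    support = support[keep], n_up = n_up[keep], n_down = n_down[keep],
    n_evaluable = n_eval[keep], row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    sig$class <- annotation$class[match(sig$gene, annotation$gene)]
  }
  attr(sig, "min_support") <- min_support
  class(sig) <- c("drug_signature", class(sig))
  sig
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("Drug signature: %s (%d genes, min_support = %g)\n",
              x$drug[1] %||% "?", nrow(x), attr(x, "min_support")))
  cat(sprintf("  up: %d  down: %d\n", sum(x$direction == "up"),
              sum(x$direction == "down")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Partition gene sets into Venn regions
#'
#' Counts the genes in every non-empty membership pattern of 2-6 sets.
#' Pattern labels are binary strings whose i-th character says whether the
#' gene belongs to the i-th set; counts sum to the union cardinality.
#'
#' @param sets Named (or unnamed) list of 2-6 character vectors.
#' @return Named integer vector over all `2^k - 1` non-empty patterns.
#' @export
#' @examples
#' venn_partition(list(A = c("a", "c"), B = c("b", "c")))
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 6L) stop("venn_partition supports 2 to 6 sets")
  sets <- lapply(sets, unique)
  un <- unique(unlist(sets))
  member <- vapply(sets, function(s) un %in% s, logical(length(un)))
  if (length(un) == 1L) member <- matrix(member, nrow = 1L)
  pat <- apply(member, 1, function(row) paste(as.integer(row), collapse = ""))
  grid <- expand.grid(rep(list(0:1), k))
  all_pat <- apply(grid, 1, paste, collapse = "")
  all_pat <- all_pat[all_pat != paste(rep("0", k), collapse = "")]
  # canonical region order: singles first (by set index), then pairs, ...
  popcount <- vapply(strsplit(all_pat, ""), function(b) sum(b == "1"), 0L)
  all_pat <- all_pat[order(popcount, -strtoi(all_pat, base = 2L))]
  counts <- table(factor(pat, levels = all_pat))
  stats::setNames(as.integer(counts), names(counts))
}

#' Overlap of a signature with an external up-regulated gene list
#'
#' Reports how many of the signature genes evaluable in an external study
#' appear in that study's up-regulated list, as a count and a percent
#' (1 decimal). The evaluable denominator is supplied by the caller because
#' measurability in the external study cannot be inferred from the
#' signature itself.
#'
#' @param signature A [derive_signature()] object or character vector of
#'   signature genes.
#' @param external_up Character vector of genes up-regulated in the external
#'   study.
#' @param evaluable Character vector: the signature genes measured in the
#'   external study (non-empty subset of the signature).
#' @return list with `n_overlap`, `n_evaluable`, `percent`.
#' @export
#' @examples
#' sig <- sprintf("g%03d", 1:170)
#' ev <- sig[1:166]
#' signature_overlap(sig, external_up = ev[1:35], evaluable = ev)
signature_overlap <- function(signature, external_up, evaluable) {
  genes <- if (inherits(signature, "drug_signature")) {
    signature$gene
  } else {
    as.character(signature)
  }
  evaluable <- intersect(as.character(evaluable), genes)
  if (length(evaluable) == 0L) {
    stop("empty evaluable set: no signature genes measured externally")
  }
  n_overlap <- length(intersect(evaluable, as.character(external_up)))
  list(n_overlap = n_overlap, n_evaluable = length(evaluable),
       percent = round(100 * n_overlap / length(evaluable), 1))
}
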