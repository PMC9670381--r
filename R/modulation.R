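# Modulation calls: housekeeping normalization, treated/control ratios, the
# |1.5| call rule, the two class-level summary metrics and the MTT
# working-dose rule.

#' Normalize panel counts to housekeeping genes
#'
#' Scales each sample so the geometric mean of its housekeeping genes equals
#' the cohort-wide geometric mean of those genes. Samples in which any
#' housekeeping gene has a zero count cannot be scaled and are excluded with
#' a warning.
#'
#' @param counts Non-negative genes x samples matrix with rownames.
#' @param housekeeping Character vector of housekeeping gene identifiers;
#'   at least one must be present in `counts`.
#' @return Normalized (real-valued) matrix with attributes `scale_factors`
#'   (named per retained sample) and `excluded_samples`.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, n_classes = 5,
#'                                   cell_lines = c("A", "B"),
#'                                   drugs = "guadecitabine"))
#' hk <- sim$annotation$gene[sim$annotation$is_housekeeping]
#' norm <- normalize_counts(sim$counts, hk)
#' attr(norm, "scale_factors")
normalize_counts <- function(counts, housekeeping) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  housekeeping <- intersect(as.character(housekeeping), rownames(counts))
  if (length(housekeeping) == 0L) {
    stop("no housekeeping genes present in the count matrix")
  }
  hk <- counts[housekeeping, , drop = FALSE]
  gm <- apply(hk, 2, function(x) if (any(x <= 0)) 0 else geo_mean(x))
  bad <- gm <= 0
  if (all(bad)) stop("every sample has a zero housekeeping count")
  if (any(bad)) {
    warning("excluding sample(s) with zero housekeeping counts: ",
            paste(colnames(counts)[bad], collapse = ", "))
  }
  target <- geo_mean(gm[!bad])
  sf <- target / gm[!bad]
  out <- sweep(counts[, !bad, drop = FALSE], 2, sf, "*")
  attr(out, "scale_factors") <- sf
  attr(out, "excluded_samples") <- colnames(counts)[bad]
  out
}

#' Treated/control ratios and modulation calls
#'
#' Computes, per gene and matched (cell line, drug) pair, the
#' treated/control expression ratio and a symmetric threshold call:
#' `up` if ratio > tau, `down` if ratio < 1/tau, `none` otherwise
#' (default tau = 1.5). When either member of a ratio is zero, the
#' pseudocount is added to both and the gene flagged. Genes whose smaller
#' pair member falls below `min_control` are set to `none` (a low-expression
#' floor, symmetric so that swapping treated and control mirrors every
#' call) rather than dropped.
#'
#' @param counts Normalized genes x samples matrix.
#' @param samples data.frame with columns `sample`, `cell_line`, `drug`,
#'   `condition` ("control"/"treated"). Every treated sample must have a
#'   matched control from the same cell line and drug.
#' @param tau Call threshold (> 1); default 1.5.
#' @param pseudocount Added to both members of a ratio when either is zero.
#' @param min_control Low-expression floor (default 20 normalized counts),
#'   applied to the smaller member of each treated/control pair; set to 0
#'   to disable.
#' @return data.frame of class `modulation_table` with one row per
#'   (gene, cell line, drug): `ratio`, `call`, `zero_adjusted`,
#'   `low_expression`. The threshold is stored in `attr(, "tau")`.
#' @export
compute_modulation <- function(counts, samples, tau = 1.5, pseudocount = 1,
                               min_control = 20) {
  stopifnot(is.matrix(counts), tau > 1)
  req <- c("sample", "cell_line", "drug", "condition")
  if (!all(req %in% names(samples))) {
    stop("samples must have columns: ", paste(req, collapse = ", "))
  }
  samples <- samples[samples$sample %in% colnames(counts), , drop = FALSE]
  treated <- samples[samples$condition == "treated", , drop = FALSE]
  if (nrow(treated) == 0L) stop("no treated samples present")
  out <- vector("list", nrow(treated))
  for (i in seq_len(nrow(treated))) {
    tr <- treated[i, ]
    ctrl <- samples$sample[samples$condition == "control" &
                             samples$cell_line == tr$cell_line &
                             samples$drug == tr$drug]
    if (length(ctrl) == 0L) {
      stop("no matched control for treated sample '", tr$sample, "'")
    }
    ct <- if (length(ctrl) > 1L) {
      rowMeans(counts[, ctrl, drop = FALSE])
    } else {
      counts[, ctrl]
    }
    tv <- counts[, tr$sample]
    zero <- tv == 0 | ct == 0
    ratio <- (tv + pseudocount * zero) / (ct + pseudocount * zero)
    call <- ifelse(ratio > tau, "up", ifelse(ratio < 1 / tau, "down", "none"))
    # floor on the smaller pair member keeps the call rule exactly
    # symmetric under a treated/control swap
    low <- pmin(ct, tv) < min_control
    call[low] <- "none"
    out[[i]] <- data.frame(
      gene = rownames(counts), cell_line = tr$cell_line, drug = tr$drug,
      ratio = ratio, call = call, zero_adjusted = zero, low_expression = low,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "tau") <- tau
  class(res) <- c("modulation_table", class(res))
  res
}

#' Class-level modulation metrics
#'
#' Summarises a modulation table per (functional class, drug, cell line)
#' with the two class metrics: the fraction of genes modulated,
#' `frac_modulated = (n_up + n_down) / n_genes`, and the direction index,
#' `d = (n_up - n_down) / (n_up + n_down)` (0 when no gene is modulated;
#' +1 when all modulated genes are up, -1 when all are down).
#'
#' @param mods A [compute_modulation()] table.
#' @param annotation data.frame mapping `gene` to `class` (one class per
#'   gene); every gene in `mods` must be annotated.
#' @return data.frame with one row per (class, drug, cell line):
#'   `n_genes`, `n_up`, `n_down`, `frac_modulated`, `direction_index`.
#' @export
class_metrics <- function(mods, annotation) {
  stopifnot(all(c("gene", "class") %in% names(annotation)))
  cls <- annotation$class[match(mods$gene, annotation$gene)]
  if (anyNA(cls)) {
    offenders <- unique(mods$gene[is.na(cls)])
    stop("unannotated gene(s): ",
         paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) " ..." else "")
  }
  key <- interaction(cls, mods$drug, mods$cell_line, drop = TRUE, sep = "\r")
  n_genes <- as.vector(table(key))
  n_up <- as.vector(tapply(mods$call == "up", key, sum))
  n_down <- as.vector(tapply(mods$call == "down", key, sum))
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  n_mod <- n_up + n_down
  data.frame(
    class = parts[, 1], drug = parts[, 2], cell_line = parts[, 3],
    n_genes = n_genes, n_up = n_up, n_down = n_down,
    frac_modulated = n_mod / n_genes,
    direction_index = ifelse(n_mod == 0, 0, (n_up - n_down) / n_mod),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the working drug dose from an MTT dose-response table
#'
#' Returns the maximum tested dose whose cell viability strictly exceeds
#' the threshold (default 60% of control), the rule used to keep drug doses
#' below overt anti-proliferative toxicity.
#'
#' @param dose_response data.frame with columns `dose` (nM) and `viability`
#'   (percent of control).
#' @param threshold Viability threshold in percent (default 60).
#' @return The selected dose (scalar).
#' @export
#' @examples
#' select_working_dose(data.frame(dose = c(7.8, 125, 1000),
#'                                viability = c(95, 80, 55)))
select_working_dose <- function(dose_response, threshold = 60) {
  stopifnot(all(c("dose", "viability") %in% names(dose_response)))
  ok <- dose_response$viability > threshold
  if (!any(ok)) {
    stop("no admissible dose: no viability exceeds ", threshold,
         "% of control")
  }
  max(dose_response$dose[ok])
}
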