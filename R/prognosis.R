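# Prognostic screen: per-gene univariate proportional-hazards models and the
# signature-level "significant, reduced risk" fraction statistic.

#' Per-gene univariate Cox proportional-hazards screen
#'
#' Fits one univariate proportional-hazards model per gene (expression
#' standardized internally, Efron tie handling) and reports the coefficient,
#' its z-score and p-value, the risk direction (`reduced` when z < 0,
#' `increased` otherwise) and a p < 0.05 significance flag, plus
#' Benjamini-Hochberg adjusted p-values. Degenerate or non-convergent fits
#' are reported as non-estimable, never silently dropped.
#'
#' @param survival_df data.frame with columns `time` (> 0), `event` (0/1)
#'   and one numeric expression column per gene. At least 2 observed events
#'   are required.
#' @param genes Genes to screen; defaults to every numeric column other than
#'   time/event/subject identifiers.
#' @param time_col,event_col Column names (defaults `"time"`, `"event"`).
#' @return data.frame of class `cox_screen`: `gene`, `coef`, `z`, `p`,
#'   `p_adj`, `risk_direction`, `significant`, `estimable`.
#' @export
cox_screen <- function(survival_df, genes = NULL, time_col = "time",
                       event_col = "event") {
  stopifnot(all(c(time_col, event_col) %in% names(survival_df)))
  time <- survival_df[[time_col]]
  event <- survival_df[[event_col]]
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) == 0) {
    stop("all observations are censored: hazard coefficients not estimable")
  }
  if (sum(event) < 2) stop("need >= 2 observed events")
  if (is.null(genes)) {
    cand <- setdiff(names(survival_df),
                    c(time_col, event_col, "subject", "id", "patient"))
    genes <- cand[vapply(survival_df[cand], is.numeric, logical(1))]
  }
  rows <- lapply(genes, function(g) {
    x <- survival_df[[g]]
    bad_row <- data.frame(gene = g, coef = NA_real_, z = NA_real_,
                          p = NA_real_, risk_direction = NA_character_,
                          significant = NA, estimable = FALSE,
                          stringsAsFactors = FALSE)
    if (is.null(x) || !is.numeric(x) || !all(is.finite(x)) ||
        stats::sd(x) == 0) {
      return(bad_row)
    }
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ z,
                      data = data.frame(time = time, event = event,
                                        z = as.numeric(scale(x))),
                      ties = "efron"),
      error = function(e) NULL)
    if (is.null(fit)) return(bad_row)
    sm <- summary(fit)$coefficients
    if (!all(is.finite(sm[1, c("coef", "z")]))) return(bad_row)
    data.frame(gene = g, coef = sm[1, "coef"], z = sm[1, "z"],
               p = sm[1, "Pr(>|z|)"],
               risk_direction = if (sm[1, "z"] < 0) "reduced" else "increased",
               significant = sm[1, "Pr(>|z|)"] < 0.05, estimable = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res <- res[, c("gene", "coef", "z", "p", "p_adj", "risk_direction",
                 "significant", "estimable")]
  class(res) <- c("cox_screen", class(res))
  res
}

#' Prognostic fraction of a drug signature
#'
#' Fraction of signature genes that are significant in the Cox screen
#' (p < 0.05, raw) and the fraction that are both significant and
#' risk-reducing (z < 0), reported as fractions and as percents rounded to
#' the nearest integer. Signature genes missing from the screen (or
#' non-estimable) are excluded from the denominator with a message.
#'
#' @param screen A [cox_screen()] table.
#' @param signature A [derive_signature()] object or character vector of
#'   signature genes.
#' @return list with `n_genes`, `frac_significant`,
#'   `frac_significant_reduced_risk`, `percent_significant`,
#'   `percent_significant_reduced_risk`.
#' @export
signature_prognostic_fraction <- function(screen, signature) {
  genes <- if (inherits(signature, "drug_signature")) {
    signature$gene
  } else {
    as.character(signature)
  }
  usable <- screen$gene[screen$estimable]
  present <- intersect(genes, usable)
  n_missing <- length(genes) - length(present)
  if (n_missing > 0) {
    message(n_missing, " signature gene(s) absent from the screen ",
            "(or non-estimable); excluded from the denominator")
  }
  if (length(present) == 0L) {
    stop("no signature genes present in the screen")
  }
  sub <- screen[match(present, screen$gene), ]
  frac_sig <- mean(sub$significant)
  frac_red <- mean(sub$significant & sub$z < 0)
  list(n_genes = length(present),
       frac_significant = frac_sig,
       frac_significant_reduced_risk = frac_red,
       percent_significant = round(100 * frac_sig),
       percent_significant_reduced_risk = round(100 * frac_red))
}
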