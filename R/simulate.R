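# Synthetic-data generator: every input the pipeline consumes, with planted
# ground truth (modulated classes, active regulators, responder induction,
# protective genes) so each downstream stage is testable by recovery.

#' Simulation configuration
#'
#' Builds the configuration object consumed by all `simulate_*()` generators.
#' Defaults emulate the study design the pipeline targets: a 731-gene immune
#' panel re-classified into 21 functional classes, measured on 10 tumor cell
#' lines treated with four epigenetic drugs (one matched control per
#' treated sample), a signed regulator-target causal network, a
#' three-timepoint (w0/w4/w12) responder-labelled biopsy cohort, and a
#' survival cohort with planted protective genes.
#'
#' @param n_genes Number of class-assigned panel genes (default 731).
#' @param n_classes Number of functional classes the panel genes are split
#'   into (default 21); class sizes differ by at most one.
#' @param n_housekeeping Number of additional housekeeping genes appended to
#'   the panel; never planted as responsive (default 20).
#' @param cell_lines Character vector of cell-line identifiers.
#' @param drugs Character vector of drug identifiers. The first drug is the
#'   "trial drug" whose up-regulated planted genes seed the clinical cohort
#'   and survival generators.
#' @param planted_effects Named list (one element per drug) describing the
#'   planted perturbation: `classes` (integer indices of responsive classes),
#'   `log2fc_mean`, `log2fc_sd` (magnitude distribution of planted log2 fold
#'   changes), `frac_genes` (fraction of genes per responsive class that are
#'   planted), `frac_lines` (fraction of cell lines that respond) and
#'   `prob_up` (probability a planted gene moves up rather than down). Use
#'   `NULL` for a null (zero-effect) simulation.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of gene
#'   baseline mean counts.
#' @param nb_dispersion Negative-binomial dispersion of panel counts
#'   (variance = mu + dispersion * mu^2); must be positive.
#' @param library_size_lognormal_sigma Log-normal sigma of per-sample size
#'   factors.
#' @param n_regulators Total number of regulators in the simulated causal
#'   network (planted + decoys).
#' @param regulators_per_drug Number of planted-active regulators per drug.
#' @param targets_per_regulator Integer range (length 2) of target counts.
#' @param regulator_consistency Fraction of a planted regulator's edges whose
#'   sign agrees with the planted direction of its target (default 0.9).
#' @param timepoints Ordered biopsy timepoint labels.
#' @param n_patients,responder_fraction Cohort size and fraction labelled
#'   responder (must lie strictly between 0 and 1).
#' @param n_induced_genes Cap on the number of responder-induced genes
#'   (drawn from the trial drug's up-planted genes).
#' @param induction_log2fc Non-decreasing numeric vector, one value per
#'   timepoint: planted log2 fold change of induced genes in responders.
#' @param cohort_dispersion NB dispersion for patient biopsy counts
#'   (larger than the cell-line value: biological variability).
#' @param n_subjects Survival cohort size.
#' @param baseline_hazard Exponential baseline hazard (> 0).
#' @param n_protective_genes,protective_log_hazard Number of planted
#'   protective genes and their per-SD log hazard (negative = protective).
#' @param n_null_survival_genes Null genes carried through the screen for
#'   calibration.
#' @param censoring_fraction Target fraction of censored subjects (0 to 1;
#'   1 censors everyone, a degenerate design the screen must reject).
#' @param seed Integer master seed; child seeds for each stage are derived
#'   as `seed * 101 + stage`.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_panel()], [simulate_counts()],
#'   [simulate_causal_network()], [simulate_trial_cohort()],
#'   [simulate_survival()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg
sim_config <- function(n_genes = 731,
                       n_classes = 21,
                       n_housekeeping = 20,
                       cell_lines = sprintf("CL%02d", 1:10),
                       drugs = c("guadecitabine", "givinostat", "JQ1", "GSK126"),
                       planted_effects = default_planted_effects(drugs, n_classes),
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1,
                       nb_dispersion = 0.01,
                       library_size_lognormal_sigma = 0.2,
                       n_regulators = 60,
                       regulators_per_drug = 8,
                       targets_per_regulator = c(15, 30),
                       regulator_consistency = 0.9,
                       timepoints = c("w0", "w4", "w12"),
                       n_patients = 24,
                       responder_fraction = 0.4,
                       n_induced_genes = 50,
                       induction_log2fc = c(0, 1.0, 1.8),
                       cohort_dispersion = 0.15,
                       n_subjects = 500,
                       baseline_hazard = 0.1,
                       n_protective_genes = 10,
                       protective_log_hazard = -0.8,
                       n_null_survival_genes = 10,
                       censoring_fraction = 0.3,
                       seed = 1) {
  if (!is_count(n_genes) || !is_count(n_classes) || !is_count(n_housekeeping)) {
    stop("n_genes, n_classes and n_housekeeping must be non-negative integers")
  }
  if (n_classes < 1) stop("n_classes must be >= 1")
  if (n_genes < n_classes) {
    stop("configuration error: n_genes (", n_genes,
         ") must be >= n_classes (", n_classes, ")")
  }
  if (nb_dispersion <= 0 || cohort_dispersion <= 0) {
    stop("configuration error: dispersions must be positive")
  }
  if (length(targets_per_regulator) != 2L ||
      targets_per_regulator[1] > targets_per_regulator[2] ||
      targets_per_regulator[1] < 1) {
    stop("targets_per_regulator must be an increasing range of length 2")
  }
  if (regulator_consistency < 0 || regulator_consistency > 1) {
    stop("regulator_consistency must lie in [0, 1]")
  }
  if (!is.null(planted_effects)) {
    if (is.null(names(planted_effects)) ||
        !all(names(planted_effects) %in% drugs)) {
      stop("planted_effects must be named by drugs")
    }
    for (d in names(planted_effects)) {
      pe <- planted_effects[[d]]
      if (any(pe$classes < 1 | pe$classes > n_classes)) {
        stop("planted classes for ", d, " outside 1..n_classes")
      }
    }
  }
  if (length(induction_log2fc) != length(timepoints)) {
    stop("induction_log2fc must have one value per timepoint")
  }
  if (is.unsorted(induction_log2fc)) {
    stop("induction_log2fc must be non-decreasing across timepoints")
  }
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  cfg <- list(
    n_genes = as.integer(n_genes), n_classes = as.integer(n_classes),
    n_housekeeping = as.integer(n_housekeeping),
    cell_lines = as.character(cell_lines), drugs = as.character(drugs),
    planted_effects = planted_effects,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    nb_dispersion = nb_dispersion,
    library_size_lognormal_sigma = library_size_lognormal_sigma,
    n_regulators = as.integer(n_regulators),
    regulators_per_drug = as.integer(regulators_per_drug),
    targets_per_regulator = as.integer(targets_per_regulator),
    regulator_consistency = regulator_consistency,
    timepoints = as.character(timepoints),
    n_patients = as.integer(n_patients),
    responder_fraction = responder_fraction,
    n_induced_genes = as.integer(n_induced_genes),
    induction_log2fc = induction_log2fc,
    cohort_dispersion = cohort_dispersion,
    n_subjects = as.integer(n_subjects),
    baseline_hazard = baseline_hazard,
    n_protective_genes = as.integer(n_protective_genes),
    protective_log_hazard = protective_log_hazard,
    n_null_survival_genes = as.integer(n_null_survival_genes),
    censoring_fraction = censoring_fraction,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted perturbation map
#'
#' Assigns each drug two distinct responsive functional classes (disjoint
#' between consecutive drugs when the class count allows) and a predominant
#' direction: up for all drugs except BET inhibitors (JQ1/OTX-style names),
#' which suppress immune gene expression.
#'
#' @param drugs Character vector of drug identifiers.
#' @param n_classes Number of functional classes.
#' @return Named list suitable for the `planted_effects` field of
#'   [sim_config()].
#' @export
default_planted_effects <- function(drugs, n_classes = 21) {
  eff <- vector("list", length(drugs))
  names(eff) <- drugs
  for (i in seq_along(drugs)) {
    cls <- ((c(2L * i - 2L, 2L * i - 1L)) %% n_classes) + 1L
    prob_up <- if (grepl("^(JQ1|OTX)", drugs[i])) 0 else 1
    eff[[i]] <- list(classes = unique(cls), log2fc_mean = 1.2, log2fc_sd = 0.25,
                     frac_genes = 0.8, frac_lines = 0.8, prob_up = prob_up)
  }
  eff
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (epidrugsig)\n")
  cat(sprintf("  panel: %d genes / %d classes (+%d housekeeping)\n",
              x$n_genes, x$n_classes, x$n_housekeeping))
  cat(sprintf("  cell lines: %d; drugs: %s\n", length(x$cell_lines),
              paste(x$drugs, collapse = ", ")))
  cat(sprintf("  planted drugs: %s\n",
              if (is.null(x$planted_effects)) "none (null simulation)"
              else paste(names(x$planted_effects), collapse = ", ")))
  cat(sprintf("  network: %d regulators (%d planted per drug)\n",
              x$n_regulators, x$regulators_per_drug))
  cat(sprintf("  cohort: %d patients x %s; survival: %d subjects\n",
              x$n_patients, paste(x$timepoints, collapse = "/"),
              x$n_subjects))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Generate the gene panel annotation
#'
#' Assigns `n_genes` genes to `n_classes` functional classes round-robin, so
#' class sizes differ by at most one, and appends `n_housekeeping`
#' housekeeping genes (class `"housekeeping"`), which are never planted as
#' responsive.
#'
#' @param config A [sim_config()] object.
#' @return data.frame with columns `gene`, `class`, `is_housekeeping`.
#' @export
#' @examples
#' head(generate_panel(sim_config()))
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  classes <- sprintf("C%02d", seq_len(config$n_classes))
  gene <- sprintf("G%04d", seq_len(config$n_genes))
  cls <- classes[((seq_len(config$n_genes) - 1L) %% config$n_classes) + 1L]
  hk <- if (config$n_housekeeping > 0) {
    sprintf("HK%02d", seq_len(config$n_housekeeping))
  } else {
    character()
  }
  data.frame(
    gene = c(gene, hk),
    class = c(cls, rep("housekeeping", length(hk))),
    is_housekeeping = c(rep(FALSE, length(gene)), rep(TRUE, length(hk))),
    stringsAsFactors = FALSE)
}

# Gene baseline mean counts from the stage-1 child seed. Housekeeping
# genes get a high, low-variance baseline of their own: reference genes
# are chosen for abundant, stable expression, and the normalization step
# must be able to rely on them being detected in every sample.
gene_baselines <- function(config, panel) {
  with_seed(child_seed(config$seed, 1L), {
    mu <- stats::rlnorm(nrow(panel), config$baseline_meanlog,
                        config$baseline_sdlog)
    n_hk <- sum(panel$is_housekeeping)
    if (n_hk > 0) {
      mu[panel$is_housekeeping] <- stats::rlnorm(n_hk, log(500), 0.25)
    }
    stats::setNames(mu, panel$gene)
  })
}

# Realise the planted perturbation (which genes, which direction, which
# magnitude, which cell lines) from its own child seed so that the counts,
# network, cohort and survival generators all agree on the ground truth.
plant_effects <- function(config, panel = generate_panel(config)) {
  if (is.null(config$planted_effects)) {
    return(structure(list(), names = character()))
  }
  with_seed(child_seed(config$seed, 2L), {
    out <- list()
    for (d in names(config$planted_effects)) {
      pe <- config$planted_effects[[d]]
      class_labels <- sprintf("C%02d", pe$classes)
      cand <- panel$gene[panel$class %in% class_labels]
      n_pick <- max(1L, round(pe$frac_genes * length(cand)))
      genes <- sort(sample(cand, n_pick))
      dir <- ifelse(stats::runif(n_pick) < pe$prob_up, 1L, -1L)
      mag <- pmax(abs(stats::rnorm(n_pick, pe$log2fc_mean, pe$log2fc_sd)), 0.1)
      n_lines <- max(1L, round(pe$frac_lines * length(config$cell_lines)))
      lines <- sort(sample(config$cell_lines, n_lines))
      cls <- panel$class[match(genes, panel$gene)]
      out[[d]] <- list(
        genes = data.frame(gene = genes, class = cls, direction = dir,
                           log2fc = dir * mag, stringsAsFactors = FALSE),
        lines = lines)
    }
    out
  })
}

#' Simulate paired control/treated panel counts
#'
#' For every (cell line, drug) pair draws one control and one treated sample
#' of negative-binomial counts with a log-normal per-sample size factor.
#' Treated means are multiplied by `2^log2FC` only for planted
#' (gene, drug, responsive cell line) triples. Identical configuration
#' (including seed) yields an identical matrix.
#'
#' @param config A [sim_config()] object.
#' @return list with components `counts` (genes x samples integer matrix),
#'   `samples` (data.frame: sample, cell_line, drug, condition), `annotation`
#'   (the panel, see [generate_panel()]) and `truth` (list with
#'   `responsive_genes` and `responsive_lines` per drug).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- generate_panel(config)
  baseline <- gene_baselines(config, panel)
  effects <- plant_effects(config, panel)
  samples <- expand.grid(
    condition = c("control", "treated"),
    cell_line = config$cell_lines,
    drug = config$drugs,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample <- paste(samples$cell_line, samples$drug,
                          ifelse(samples$condition == "control", "ctrl", "trt"),
                          sep = "_")
  samples <- samples[, c("sample", "cell_line", "drug", "condition")]
  counts <- with_seed(child_seed(config$seed, 3L), {
    sf <- stats::rlnorm(nrow(samples), 0, config$library_size_lognormal_sigma)
    m <- matrix(0L, nrow = nrow(panel), ncol = nrow(samples),
                dimnames = list(panel$gene, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- baseline * sf[j]
      if (samples$condition[j] == "treated") {
        eff <- effects[[samples$drug[j]]]
        if (!is.null(eff) && samples$cell_line[j] %in% eff$lines) {
          idx <- match(eff$genes$gene, panel$gene)
          mu[idx] <- mu[idx] * 2^eff$genes$log2fc
        }
      }
      m[, j] <- stats::rnbinom(nrow(panel), size = 1 / config$nb_dispersion,
                               mu = mu)
    }
    m
  })
  truth <- list(
    responsive_genes = lapply(effects, `[[`, "genes"),
    responsive_lines = lapply(effects, `[[`, "lines"))
  list(counts = counts, samples = samples, annotation = panel, truth = truth)
}

#' Simulate a signed regulator-target causal network
#'
#' Builds `n_regulators` regulators. Planted-active regulators (assigned per
#' drug) draw their targets from that drug's planted responsive genes, with
#' edge signs agreeing with the planted gene direction for a configurable
#' consistency fraction; decoy regulators draw targets uniformly with random
#' signs.
#'
#' @param config A [sim_config()] object.
#' @param truth The `truth` component returned by [simulate_counts()].
#' @return list with `edges` (data.frame: regulator, target, sign) and
#'   `active_regulators` (named list per drug: data.frame regulator,
#'   direction), of class `causal_network_sim`.
#' @export
simulate_causal_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  panel <- generate_panel(config)
  genes <- panel$gene[!panel$is_housekeeping]
  tr <- config$targets_per_regulator
  if (tr[2] > length(genes)) {
    stop("targets_per_regulator exceeds panel size")
  }
  planted_drugs <- names(truth$responsive_genes)
  n_planted <- length(planted_drugs) * config$regulators_per_drug
  if (n_planted > config$n_regulators) {
    stop("n_regulators too small for regulators_per_drug x planted drugs")
  }
  regs <- sprintf("UR%03d", seq_len(config$n_regulators))
  with_seed(child_seed(config$seed, 4L), {
    edge_list <- vector("list", config$n_regulators)
    active <- stats::setNames(vector("list", length(planted_drugs)),
                              planted_drugs)
    idx <- 0L
    for (d in planted_drugs) {
      resp <- truth$responsive_genes[[d]]
      planted_here <- character(config$regulators_per_drug)
      for (k in seq_len(config$regulators_per_drug)) {
        idx <- idx + 1L
        r <- regs[idx]
        planted_here[k] <- r
        m <- sample(seq(tr[1], tr[2]), 1L)
        n_resp <- min(m, nrow(resp))
        pick <- resp[sample(nrow(resp), n_resp), , drop = FALSE]
        sgn <- ifelse(stats::runif(n_resp) < config$regulator_consistency,
                      pick$direction, -pick$direction)
        tgt <- pick$gene
        if (m > n_resp) {
          extra <- sample(setdiff(genes, tgt), m - n_resp)
          tgt <- c(tgt, extra)
          sgn <- c(sgn, sample(c(-1L, 1L), m - n_resp, replace = TRUE))
        }
        edge_list[[idx]] <- data.frame(regulator = r, target = tgt,
                                       sign = as.integer(sgn),
                                       stringsAsFactors = FALSE)
      }
      active[[d]] <- data.frame(regulator = planted_here, direction = 1L,
                                stringsAsFactors = FALSE)
    }
    while (idx < config$n_regulators) {
      idx <- idx + 1L
      m <- sample(seq(tr[1], tr[2]), 1L)
      edge_list[[idx]] <- data.frame(
        regulator = regs[idx],
        target = sample(genes, m),
        sign = sample(c(-1L, 1L), m, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    structure(list(edges = do.call(rbind, edge_list),
                   active_regulators = active),
              class = "causal_network_sim")
  })
}

#' Simulate a responder-labelled biopsy timecourse cohort
#'
#' Each patient contributes one sample per timepoint. Responder-induced genes
#' (a subset of the trial drug's up-planted genes) receive a monotone
#' non-decreasing planted log2 fold change across timepoints in responders
#' only; all other genes are exchangeable across arms.
#'
#' @param config A [sim_config()] object. `config$drugs[1]` is the trial
#'   drug; set `planted_effects = NULL` for a null cohort.
#' @return list with `counts`, `samples` (sample, patient, timepoint,
#'   response), `induced_genes` (data.frame gene, direction) and `annotation`.
#' @export
simulate_trial_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$timepoints) < 2L) {
    stop("at least 2 timepoints are required")
  }
  rf <- config$responder_fraction
  if (!(rf > 0 && rf < 1)) {
    stop("responder_fraction must lie strictly in (0, 1): ",
         "a single-arm cohort leaves the between-arm contrast undefined")
  }
  panel <- generate_panel(config)
  baseline <- gene_baselines(config, panel)
  effects <- plant_effects(config, panel)
  trial_drug <- config$drugs[1]
  up <- if (length(effects) && trial_drug %in% names(effects)) {
    eff <- effects[[trial_drug]]$genes
    eff[eff$direction > 0, , drop = FALSE]
  } else {
    data.frame(gene = character(), direction = integer())
  }
  with_seed(child_seed(config$seed, 5L), {
    induced <- if (nrow(up) > config$n_induced_genes) {
      up[sort(sample(nrow(up), config$n_induced_genes)), , drop = FALSE]
    } else {
      up
    }
    patients <- sprintf("P%02d", seq_len(config$n_patients))
    n_resp <- min(max(1L, round(rf * config$n_patients)),
                  config$n_patients - 1L)
    responders <- sort(sample(patients, n_resp))
    samples <- expand.grid(timepoint = config$timepoints, patient = patients,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples$response <- ifelse(samples$patient %in% responders,
                               "responder", "nonresponder")
    samples$sample <- paste(samples$patient, samples$timepoint, sep = "_")
    samples <- samples[, c("sample", "patient", "timepoint", "response")]
    lfc_by_tp <- stats::setNames(config$induction_log2fc, config$timepoints)
    sf <- stats::rlnorm(nrow(samples), 0, config$library_size_lognormal_sigma)
    m <- matrix(0L, nrow = nrow(panel), ncol = nrow(samples),
                dimnames = list(panel$gene, samples$sample))
    ind_idx <- match(induced$gene, panel$gene)
    for (j in seq_len(nrow(samples))) {
      mu <- baseline * sf[j]
      if (samples$response[j] == "responder" && length(ind_idx)) {
        lfc <- induced$direction * lfc_by_tp[[samples$timepoint[j]]]
        mu[ind_idx] <- mu[ind_idx] * 2^lfc
      }
      m[, j] <- stats::rnbinom(nrow(panel), size = 1 / config$cohort_dispersion,
                               mu = mu)
    }
    list(counts = m, samples = samples,
         induced_genes = induced[, c("gene", "direction")],
         annotation = panel)
  })
}

#' Simulate a survival cohort with planted protective genes
#'
#' Event times are exponential with log hazard linear in the standardized
#' expression of planted protective genes (negative coefficients); censoring
#' is independent exponential tuned to the target censoring fraction.
#' Protective genes are drawn from the trial drug's up-planted panel genes
#' (falling back to the panel when no effects are planted).
#'
#' @param config A [sim_config()] object.
#' @return list with `survival` (data.frame: subject, time, event, one
#'   standardized expression column per screened gene), `protective_genes`
#'   and `null_genes` character vectors.
#' @export
simulate_survival <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- generate_panel(config)
  effects <- plant_effects(config, panel)
  trial_drug <- config$drugs[1]
  pool <- if (length(effects) && trial_drug %in% names(effects)) {
    g <- effects[[trial_drug]]$genes
    g$gene[g$direction > 0]
  } else {
    character()
  }
  if (length(pool) < config$n_protective_genes) {
    pool <- panel$gene[!panel$is_housekeeping]
  }
  with_seed(child_seed(config$seed, 6L), {
    protective <- sort(sample(pool, config$n_protective_genes))
    nulls <- sort(sample(setdiff(panel$gene[!panel$is_housekeeping], protective),
                         config$n_null_survival_genes))
    genes <- c(protective, nulls)
    n <- config$n_subjects
    x <- matrix(stats::rnorm(n * length(genes)), nrow = n,
                dimnames = list(NULL, genes))
    lp <- drop(x[, protective, drop = FALSE] %*%
                 rep(config$protective_log_hazard, length(protective)))
    haz <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = haz)
    q <- config$censoring_fraction
    if (q >= 1) {
      time <- stats::rexp(n, rate = config$baseline_hazard)
      event <- rep(0L, n)
    } else if (q <= 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      cens <- stats::rexp(n, rate = config$baseline_hazard * q / (1 - q))
      time <- pmin(t_event, cens)
      event <- as.integer(t_event <= cens)
    }
    surv <- data.frame(subject = sprintf("S%04d", seq_len(n)),
                       time = time, event = event, stringsAsFactors = FALSE)
    surv <- cbind(surv, as.data.frame(x))
    list(survival = surv, protective_genes = protective, null_genes = nulls)
  })
}
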