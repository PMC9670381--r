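# Plain-text readers/writers for the pipeline's standard formats: TSV count
# matrices, edge-list networks, GMT gene sets, .rnk rankings and the YAML
# simulation configuration.

#' Read / write a genes x samples count matrix as TSV
#'
#' The TSV carries gene identifiers in the first column (`gene`) and one
#' column per sample.
#'
#' @param file Path to the TSV file.
#' @return `read_counts_tsv()` returns a numeric matrix with gene rownames.
#' @export
read_counts_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_counts_tsv
#' @param counts Genes x samples matrix with dimnames.
#' @export
write_counts_tsv <- function(counts, file) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write a signed causal network as a 3-column edge list TSV
#'
#' Columns: `regulator`, `target`, `sign` (+1/-1).
#'
#' @param file Path to the TSV file.
#' @return `read_network_tsv()` returns the edge-list data.frame.
#' @export
read_network_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("regulator", "target", "sign") %in% names(df)))
  df$sign <- as.integer(df$sign)
  df
}

#' @rdname read_network_tsv
#' @param network Edge-list data.frame (or [simulate_causal_network()]
#'   output, whose `edges` are written).
#' @export
write_network_tsv <- function(network, file) {
  if (inherits(network, "causal_network_sim")) network <- network$edges
  utils::write.table(network, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param file Path to the GMT file.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, file, descriptions = names(sets)) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read / write a ranked gene list in .rnk format
#'
#' Two tab-separated columns (gene, score), no header, sorted by decreasing
#' score on write.
#'
#' @param file Path to the .rnk file.
#' @return `read_rnk()` returns a `ranked_list` data.frame (gene, score).
#' @export
read_rnk <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene", "score"))
  df <- df[order(-df$score, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ranked_list", class(df))
  df
}

#' @rdname read_rnk
#' @param ranked A [rank_genes()] data.frame.
#' @export
write_rnk <- function(ranked, file) {
  ranked <- ranked[order(-ranked$score, ranked$gene), c("gene", "score")]
  utils::write.table(ranked, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read / write a simulation configuration as YAML
#'
#' @param file Path to the YAML file.
#' @return `read_sim_config()` returns a validated [sim_config()] object.
#' @export
read_sim_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$targets_per_regulator)) {
    y$targets_per_regulator <- as.integer(y$targets_per_regulator)
  }
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @param config A [sim_config()] object.
#' @export
write_sim_config <- function(config, file) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}
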