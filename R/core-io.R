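# Domain types and plain-text readers/writers.
#
# All tabular formats are tab-separated text with "NA" as the missing-value
# token. Tissue labels are free strings compared exactly (case-sensitive).

## ---------------------------------------------------------------- expression

#' Construct a multi-tissue expression dataset
#'
#' Bundles a nonnegative gene-by-sample expression matrix (RPKM scale) with a
#' sample-to-tissue map and validates the invariants every downstream feature
#' computation relies on: unique gene and sample identifiers, finite
#' nonnegative values, and exactly one tissue label per sample.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param tissue_of Named character vector mapping sample id to tissue label.
#'   Must cover every column of `values`.
#' @param min_samples Minimum number of samples required per tissue
#'   (default 1).
#' @param residual Logical; residualized datasets (see [residualize()]) live on
#'   a centered log scale and are exempt from the nonnegativity check.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` and `tissue_of`.
#' @seealso [read_expression()], [per_tissue_moments()]
#' @export
expression_dataset <- function(values, tissue_of, min_samples = 1L,
                               residual = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("`values` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop_("duplicate gene ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_("duplicate sample ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  bad <- which(!is.finite(values) | (!residual & values < 0), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("invalid expression value (%s) for gene '%s' in sample '%s'",
          format(values[bad[1L, , drop = FALSE]]),
          rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]])
  }
  tissue_of <- tissue_of[colnames(values)]
  miss <- colnames(values)[is.na(tissue_of) | !nzchar(tissue_of)]
  if (length(miss))
    stop_("samples missing from tissue map: %s",
          paste(utils::head(miss, 5L), collapse = ", "))
  names(tissue_of) <- colnames(values)
  cnt <- table(tissue_of)
  if (any(cnt < min_samples))
    stop_("tissues with fewer than %d samples: %s", min_samples,
          paste(names(cnt)[cnt < min_samples], collapse = ", "))
  structure(list(values = values, tissue_of = tissue_of,
                 residual = residual),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples in %d tissues%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$tissue_of)),
              if (isTRUE(x$residual)) " (residualized)" else ""))
  invisible(x)
}

#' Tissues represented in an expression dataset
#' @param x An `expression_dataset`.
#' @return Character vector of tissue labels, sorted.
#' @export
tissues <- function(x) sort(unique(unname(x$tissue_of)))

#' Read an expression matrix and its sample-to-tissue map
#'
#' The expression file is a TSV with a header row of sample ids and one row
#' per gene (first column = gene id). GCT-like files (two extra header lines,
#' the second giving dimensions, plus a Description column) are detected from
#' a leading `#1.x` version line and handled. The tissue map is a two-column
#' TSV `sample <TAB> tissue`.
#'
#' @inheritParams expression_dataset
#' @param path Path to the expression TSV.
#' @param tissue_map_path Path to the sample-to-tissue TSV.
#' @param min_samples Minimum samples per tissue; the default 70 mirrors the
#'   usual requirement for stable within-tissue variance estimation in
#'   reference transcriptome panels. Lower it for small datasets.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, tissue_map_path, min_samples = 70L) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#1.")) 2L else 0L
  df <- utils::read.delim(path, skip = skip, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_("expression file '%s' has no sample columns", path)
  gene <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  if (skip > 0L && identical(tolower(names(df)[1L]), "description"))
    df <- df[, -1L, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1L))
  if (!all(num)) {
    col <- names(df)[!num][1L]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
    stop_("non-numeric expression value for gene '%s' in sample '%s'",
          gene[row %||% 1L], col)
  }
  values <- as.matrix(df)
  storage.mode(values) <- "double"
  rownames(values) <- gene
  tm <- utils::read.delim(tissue_map_path, header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(tm) < 2L) stop_("tissue map must have columns sample, tissue")
  tissue_of <- stats::setNames(as.character(tm[[2L]]), as.character(tm[[1L]]))
  expression_dataset(values, tissue_of, min_samples = min_samples)
}

#' Write an expression dataset (and its tissue map) to TSV
#'
#' @param x An `expression_dataset`.
#' @param path Output path for the expression TSV.
#' @param tissue_map_path Optional output path for the tissue map TSV.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path, tissue_map_path = NULL) {
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tissue_map_path)) {
    utils::write.table(
      data.frame(sample = names(x$tissue_of), tissue = unname(x$tissue_of)),
      tissue_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## --------------------------------------------------------------------- rates

#' Construct a per-gene substitution-rate table
#'
#' Holds nonsynonymous (dN) and synonymous (dS) substitution rates for a named
#' species comparison, and the evolutionary rate omega = dN/dS. omega is
#' missing (`NA`, not 0 or Inf) where dS = 0, since the ratio is undefined
#' without synonymous substitutions.
#'
#' @param gene_ids Character vector of unique gene ids.
#' @param dN,dS Nonnegative substitution rates per gene.
#' @param comparison Species comparison label, e.g. `"human-mouse"`.
#' @return A data frame of class `evol_rates` with columns `gene`, `dN`, `dS`,
#'   `omega` and attribute `comparison`.
#' @export
evol_rates <- function(gene_ids, dN, dS, comparison = "unspecified") {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop_("duplicate gene ids in rates: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  for (nm in c("dN", "dS")) {
    v <- get(nm)
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop_("invalid %s (%s) for gene '%s'", nm, format(v[bad[1L]]),
            gene_ids[bad[1L]])
  }
  omega <- ifelse(dS > 0, dN / dS, NA_real_)
  structure(data.frame(gene = gene_ids, dN = dN, dS = dS, omega = omega,
                       stringsAsFactors = FALSE),
            comparison = comparison, class = c("evol_rates", "data.frame"))
}

#' Read a substitution-rate table
#'
#' Expects a TSV with columns `gene`, `dN`, `dS`. A comment line of the form
#' `# comparison: human-mouse` before the header, or the `comparison`
#' argument, names the species comparison.
#'
#' @param path Path to the rates TSV.
#' @param comparison Optional comparison label overriding the file comment.
#' @return An [evol_rates()] table.
#' @export
read_rates <- function(path, comparison = NULL) {
  head_lines <- readLines(path, n = 5L)
  cmt <- grep("^#\\s*comparison\\s*:", head_lines, value = TRUE)
  if (is.null(comparison))
    comparison <- if (length(cmt))
      trimws(sub("^#\\s*comparison\\s*:", "", cmt[1L])) else "unspecified"
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene", "dN", "dS")
  if (!all(need %in% names(df)))
    stop_("rates file must have columns gene, dN, dS (got: %s)",
          paste(names(df), collapse = ", "))
  for (nm in c("dN", "dS")) if (!is.numeric(df[[nm]]))
    stop_("malformed non-numeric %s in '%s'", nm, path)
  evol_rates(df$gene, df$dN, df$dS, comparison = comparison)
}

#' Write a substitution-rate table to TSV
#' @param x An `evol_rates` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rates <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# comparison: %s", attr(x, "comparison")), con)
  utils::write.table(x[, c("gene", "dN", "dS")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ------------------------------------------------------------------- network

#' Construct an undirected gene network
#'
#' Deduplicates undirected edges and drops self-loops (with a message giving
#' the count), leaving a simple graph.
#'
#' @param edges Two-column data frame or matrix of gene-id pairs.
#' @param nodes Optional character vector of node ids (isolated nodes allowed);
#'   defaults to the ids appearing in `edges`.
#' @return An object of class `gene_network`: list with `nodes` (character)
#'   and `edges` (two-column character matrix with `from` < `to`).
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges)) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
  }
  colnames(edges) <- c("from", "to")
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Per-node degree of a gene network
#' @param net A `gene_network`.
#' @return Named integer vector of degrees over all nodes.
#' @export
network_degree <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(factor(as.vector(net$edges), levels = net$nodes))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(as.data.frame(net$edges),
                                directed = FALSE,
                                vertices = net$nodes)
}

#' Read an undirected gene network from a two-column edge list
#' @param path Path to the edge-list TSV (no header required; a `from`/`to`
#'   header line is tolerated).
#' @return A [gene_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_("empty network file: %s", path)
  if (grepl("^from\\b", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) stop_("network file has no edges: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop_("malformed edge line: '%s'", lines[which(lengths(parts) < 2L)[1L]])
  gene_network(cbind(vapply(parts, `[[`, "", 1L),
                     vapply(parts, `[[`, "", 2L)))
}

#' Write a gene network edge list to TSV
#' @param net A `gene_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## --------------------------------------------------------------- gene sets &c

#' Read a gene set (one id per line)
#' @param path Path to a text file with one gene id per line.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  ids <- trimws(readLines(path))
  unique(ids[nzchar(ids) & !startsWith(ids, "#")])
}

#' Read a YAML configuration file
#' @param path Path to a YAML key-value file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

## --------------------------------------------------------- permutation result

#' Construct a permutation-test result
#'
#' Shared return shape of all permutation operations. The empirical p-value is
#' reported exactly as the proportion of null draws that matched or exceeded
#' the observed statistic (`count / n_perm`), which can be 0; the attainable
#' resolution `1 / n_perm` is stored alongside.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics, one per permutation.
#' @param seed Integer seed used to generate the permutations.
#' @param alternative `"greater"` compares `null >= observed`; `"two.sided"`
#'   compares `|null| >= |observed|`.
#' @return Object of class `permutation_result` with fields `observed`,
#'   `null_values`, `empirical_p`, `n_perm`, `seed`, `resolution`,
#'   `alternative`.
#' @export
permutation_result <- function(observed, null_values, seed = NA_integer_,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(observed), length(observed) == 1L,
            is.numeric(null_values), length(null_values) >= 1L)
  p <- if (alternative == "greater") mean(null_values >= observed)
       else mean(abs(null_values) >= abs(observed))
  structure(list(observed = observed, null_values = null_values,
                 empirical_p = p, n_perm = length(null_values),
                 resolution = 1 / length(null_values),
                 seed = seed, alternative = alternative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> observed = %.4g, empirical p = %.4g",
                     " (%d permutations, resolution %.2g, %s)\n"),
              x$observed, x$empirical_p, x$n_perm, x$resolution,
              x$alternative))
  invisible(x)
}

## ------------------------------------------------------------- feature table

#' Write a gene feature table to TSV
#'
#' Columns are written in their stored (stable) order; missing values are
#' encoded as `NA`.
#'
#' @param x A `gene_feature_table` (see [build_feature_table()]), or any data
#'   frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a gene feature table written by [write_feature_table()]
#' @param path Path to the TSV.
#' @return A data frame of class `gene_feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  class(df) <- c("gene_feature_table", "data.frame")
  df
}
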