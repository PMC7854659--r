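#' Read a genes x samples count matrix from TSV
#'
#' Expects a header of sample ids and gene ids in the first column.
#'
#' @param path TSV file.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (any(is.na(m)) || any(m < 0))
    stop("counts must be non-negative and complete")
  rownames(m) <- genes
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix to TSV
#'
#' @param counts genes x samples matrix.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample`, `tissue`, `condition` (optionally `sex`).
#'
#' @param path TSV file.
#' @param samples optional sample ids that must all be present.
#' @return validated data.frame.
#' @export
read_metadata <- function(path, samples = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (!is.null(samples)) {
    absent <- setdiff(samples, df$sample)
    if (length(absent))
      stop("samples absent from metadata: ", paste(absent, collapse = ", "))
  }
  df
}

#' Read a one-gene-per-line list
#'
#' @param path text file with one gene id per line.
#' @param universe optional valid gene ids; unknown genes are dropped with a
#'   warning.
#' @return character vector.
#' @export
read_gene_list <- function(path, universe = NULL) {
  g <- readLines(path)
  g <- trimws(g)
  g <- unique(g[nzchar(g)])
  if (!is.null(universe)) {
    unknown <- setdiff(g, universe)
    if (length(unknown)) {
      warning("dropping gene(s) absent from counts: ",
              paste(utils::head(unknown, 5), collapse = ", "))
      g <- intersect(g, universe)
    }
  }
  g
}

#' Export a network as TSV tables and a Cytoscape SIF file
#'
#' Writes `<prefix>_edges.tsv` (geneA, geneB, r, further edge columns),
#' `<prefix>_nodes.tsv` (node attribute table) and `<prefix>.sif`
#' (`geneA co geneB` lines). Rows are ordered by sorted endpoints so the
#' export is deterministic.
#'
#' @param net `"coexnet"` object.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the files written.
#' @export
export_network <- function(net, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- net$edges[order(net$edges$from, net$edges$to), , drop = FALSE]
  ef <- file.path(dir, paste0(prefix, "_edges.tsv"))
  nf <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  sf <- file.path(dir, paste0(prefix, ".sif"))
  utils::write.table(edges, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, nf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(if (nrow(edges)) paste(edges$from, "co", edges$to, sep = "\t")
             else character(0), sf)
  invisible(c(ef, nf, sf))
}

#' Re-import the edge set of an exported SIF file
#'
#' @param path SIF file written by [export_network()].
#' @return data.frame with `from` and `to` columns.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(from = character(0), to = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1),
             to = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}
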