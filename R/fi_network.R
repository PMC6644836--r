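FI_ANNOTATIONS <- c("activation", "catalysis", "inhibition",
                    "complex_or_input", "predicted", "other")

#' Read a functional-interaction edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `annotation` (one of activation,
#' catalysis, inhibition, complex_or_input, predicted, other) and `curated`
#' (TRUE/FALSE; predicted edges are the dashed ones in the usual rendering).
#' Self-loops are rejected; non-directional annotations are stored with the
#' endpoints in canonical (alphabetical) order.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the four columns above, symbols uppercased.
#' @export
read_fi_edges <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "annotation", "curated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    validation_error(paste0("FI edge list missing columns: ",
                            paste(miss, collapse = ", ")))
  df$gene_a <- toupper(df$gene_a); df$gene_b <- toupper(df$gene_b)
  if (any(df$gene_a == df$gene_b))
    validation_error("FI edge list contains self-loops")
  bad <- setdiff(unique(df$annotation), FI_ANNOTATIONS)
  if (length(bad))
    validation_error(paste0("unknown FI annotations: ", paste(bad, collapse = ", ")))
  df$curated <- as.logical(df$curated)
  undirected <- !(df$annotation %in% c("activation", "catalysis", "inhibition"))
  swap <- undirected & df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]; df$gene_b[swap] <- tmp
  unique(df[, need])
}

#' Read a gene-to-mutated-sample-count table
#'
#' TSV with columns `gene` and `samples` (non-negative integer count of
#' samples in which the gene is mutated).
#'
#' @param path Path to the TSV file.
#' @return Named integer vector (gene -> sample count).
#' @export
read_mutation_counts <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "samples") %in% names(df)))
    validation_error("mutation count table needs columns 'gene' and 'samples'")
  cnt <- suppressWarnings(as.integer(df$samples))
  if (any(is.na(cnt)) || any(cnt < 0))
    validation_error("sample counts must be non-negative integers")
  stats::setNames(cnt, toupper(df$gene))
}

#' Build a mutation-filtered functional-interaction subnetwork
#'
#' Keeps the genes mutated in at least `min_samples` samples as nodes and
#' the FI edges whose two endpoints both survive the threshold. Each node
#' carries its mutated-sample count (`sample_count`) and a `node_type` of
#' `"gene"`.
#'
#' @param edges FI edge data frame ([read_fi_edges()]).
#' @param counts Named vector of mutated-sample counts
#'   ([read_mutation_counts()]).
#' @param min_samples Minimum number of mutated samples. Default 5.
#' @return An [igraph::igraph] object.
#' @export
build_subnetwork <- function(edges, counts, min_samples = 5L) {
  stopifnot(is.data.frame(edges))
  if (min_samples < 1L) usage_error("min_samples must be >= 1")
  genes <- if (length(counts)) names(counts)[counts >= min_samples]
           else character(0)
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes
  sub <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = if (nrow(sub)) data.frame(from = sub$gene_a, to = sub$gene_b,
                                  annotation = sub$annotation,
                                  curated = sub$curated)
        else data.frame(from = character(0), to = character(0),
                        annotation = character(0), curated = logical(0)),
    directed = FALSE,
    vertices = data.frame(name = genes,
                          sample_count = unname(counts[genes]),
                          node_type = rep("gene", length(genes))))
  g
}

#' Overlay drug-target edges on a subnetwork
#'
#' Adds each drug whose minimum supporting assay value against some gene in
#' the network is at or below `max_nM` as a node of `node_type = "drug"`,
#' with one drug-gene edge per qualifying target annotated with the minimum
#' assay value (`min_assay_nM`).
#'
#' @param g Subnetwork from [build_subnetwork()].
#' @param interactions Interaction data frame ([read_interactions()]).
#' @param max_nM Inclusive assay threshold in nM. Default 100.
#' @return The augmented igraph object.
#' @export
overlay_drugs <- function(g, interactions, max_nM = 100) {
  stopifnot(igraph::is_igraph(g), is.data.frame(interactions))
  genes <- igraph::V(g)$name[igraph::V(g)$node_type == "gene"]
  hit <- interactions[interactions$target %in% genes, , drop = FALSE]
  if (nrow(hit)) {
    key <- paste(hit$drug, hit$target, sep = "\r")
    mins <- tapply(hit$assay_value_nM, key, min)
    pairs <- do.call(rbind, strsplit(names(mins), "\r", fixed = TRUE))
    sel <- mins <= max_nM
    pairs <- pairs[sel, , drop = FALSE]
    mins <- mins[sel]
  } else {
    pairs <- matrix(character(0), ncol = 2)
    mins <- numeric(0)
  }
  if (nrow(pairs) == 0L) return(g)
  drugs <- sort(unique(pairs[, 1L]))
  g <- igraph::add_vertices(g, length(drugs), name = drugs,
                            sample_count = NA_integer_, node_type = "drug")
  ord <- order(pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]; mins <- mins[ord]
  g <- igraph::add_edges(g, as.vector(t(pairs)),
                         annotation = "drug_target", curated = NA,
                         min_assay_nM = unname(mins))
  g
}

#' Export a network as SIF plus a node-attribute table
#'
#' Writes `<path>` as SIF (source, annotation, target) and, when
#' `attr_path` is given, a node-attribute TSV with columns `node`,
#' `sample_count` and `node_type` so downstream renderers can size gene
#' nodes and style drug nodes.
#'
#' @param g igraph object from [build_subnetwork()]/[overlay_drugs()].
#' @param path SIF output path.
#' @param attr_path Optional node-attribute TSV path.
#' @return Number of SIF rows written.
#' @export
write_network_sif <- function(g, path, attr_path = NULL) {
  stopifnot(igraph::is_igraph(g))
  el <- igraph::as_edgelist(g)
  ann <- if (igraph::ecount(g)) igraph::E(g)$annotation else character(0)
  rows <- if (nrow(el)) sprintf("%s\t%s\t%s", el[, 1L], ann, el[, 2L]) else character(0)
  writeLines(rows, path)
  if (!is.null(attr_path)) {
    at <- data.frame(node = igraph::V(g)$name,
                     sample_count = igraph::V(g)$sample_count,
                     node_type = igraph::V(g)$node_type)
    utils::write.table(at, attr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  length(rows)
}
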