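#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated, `name <tab> description
#' <tab> gene1 <tab> gene2 ...`. Gene symbols are uppercase-normalized.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name -> genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      validation_error("GMT line with fewer than 3 fields")
    sets[[parts[1L]]] <- unique(toupper(parts[-c(1L, 2L)]))
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail binomial p-value for pathway enrichment
#'
#' P(X >= k) for X ~ Binomial(n, s/N): the chance that at least `hits` of the
#' `query_size` query genes fall in a pathway of `pathway_size` genes drawn
#' from a background of `background_size`.
#'
#' @param hits Number of query genes in the pathway (k).
#' @param query_size Number of query genes tested (n).
#' @param pathway_size Pathway gene count (s).
#' @param background_size Background gene count (N).
#' @return The upper-tail p-value.
#' @export
binomial_pvalue <- function(hits, query_size, pathway_size, background_size) {
  if (hits < 0 || query_size < 0 || hits > query_size)
    usage_error("need 0 <= hits <= query_size")
  if (pathway_size <= 0 || background_size <= 0 ||
      pathway_size > background_size)
    usage_error("need 0 < pathway_size <= background_size")
  if (hits == 0) return(1)
  # upper tail computed on the log scale by pbinom for stability
  stats::pbinom(hits - 1, query_size, pathway_size / background_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard BH step-up with monotonicity enforcement; the output preserves
#' the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Vector of q-values (FDR-adjusted p-values), same order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    usage_error("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pathway enrichment of a gene list
#'
#' Tests every gene set for over-representation of the query genes with the
#' upper-tail binomial test and corrects across sets with Benjamini-Hochberg
#' FDR. Results are sorted by p-value (ties broken by pathway name) and
#' filtered at `fdr_cutoff`.
#'
#' @param query Character vector of query gene symbols (uppercase-normalized
#'   internally, de-duplicated).
#' @param gene_sets Named list of character vectors ([read_gmt()]).
#' @param background_size Background gene count N. The default 20000 is an
#'   arbitrary genome-scale placeholder; supply the real background of the
#'   analysis.
#' @param fdr_cutoff Keep results with FDR at or below this value.
#'   Default 1 (keep all).
#' @param background_genes Optional character vector; query genes outside it
#'   are dropped with a warning before testing.
#' @return Data frame with columns `pathway`, `pathway_size`, `hits`,
#'   `p_value`, `fdr`, `hit_genes` (comma-joined, in query order).
#' @export
enrich <- function(query, gene_sets, background_size = 20000,
                   fdr_cutoff = 1, background_genes = NULL) {
  stopifnot(is.list(gene_sets))
  query <- unique(toupper(as_chr(query)))
  if (!is.null(background_genes)) {
    background_genes <- toupper(background_genes)
    out <- setdiff(query, background_genes)
    if (length(out)) {
      warning(sprintf("%d query gene(s) absent from the background dropped: %s",
                      length(out), paste(out, collapse = ", ")))
      query <- intersect(query, background_genes)
    }
  }
  empty <- data.frame(pathway = character(0), pathway_size = integer(0),
                      hits = integer(0), p_value = numeric(0),
                      fdr = numeric(0), hit_genes = character(0))
  if (length(query) == 0L) {
    warning("empty query; no enrichment computed")
    return(empty)
  }
  if (length(gene_sets) == 0L) return(empty)
  sizes <- vapply(gene_sets, length, integer(1))
  if (background_size < length(unique(toupper(unlist(gene_sets)))))
    usage_error("background_size smaller than the union of the gene sets")

  res <- data.frame(
    pathway = names(gene_sets),
    pathway_size = unname(sizes),
    hits = vapply(gene_sets, function(g) sum(query %in% toupper(g)), integer(1)),
    row.names = NULL)
  res$p_value <- mapply(binomial_pvalue, res$hits,
                        MoreArgs = list(query_size = length(query),
                                        background_size = background_size),
                        pathway_size = res$pathway_size)
  res$fdr <- bh_fdr(res$p_value)
  res$hit_genes <- vapply(gene_sets, function(g)
    paste(query[query %in% toupper(g)], collapse = ","), character(1))
  res <- res[order(res$p_value, res$pathway), , drop = FALSE]
  res <- res[res$fdr <= fdr_cutoff, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export enrichment results as TSV
#'
#' Columns mirror the usual pathway-enrichment report: Pathway, Pathway
#' Size, Number of Targets in Pathway, P-value, FDR, Targets in Pathway.
#'
#' @param results Data frame from [enrich()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- data.frame(
    `Pathway` = results$pathway,
    `Pathway Size` = results$pathway_size,
    `Number of Targets in Pathway` = results$hits,
    `P-value` = results$p_value,
    `FDR` = results$fdr,
    `Targets in Pathway` = results$hit_genes,
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
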