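# Deterministic generators for every input format the package consumes, so
# the full pipeline is exercisable without any external download.

#' Canonical single-reaction pathway
#'
#' A pathway with one reaction of the canonical shape: two inputs, one
#' catalyst, two activators, two inhibitors and two outputs. Compiling it
#' yields the five-relation pattern (one AND, the activator and inhibitor OR
#' accessories, and two output ASSIGNs).
#'
#' @return An `fp_pathway`.
#' @export
make_typical_reaction <- function() {
  ids <- c("input1", "input2", "catalyst", "activator1", "activator2",
           "inhibitor1", "inhibitor2", "output1", "output2")
  pathway(
    id = "typical_reaction", name = "Typical reaction",
    entities = lapply(ids, function(i) entity(i, entity_class = "protein")),
    reactions = list(reaction(
      "rxn1",
      inputs = c("input1", "input2"), catalysts = "catalyst",
      activators = c("activator1", "activator2"),
      inhibitors = c("inhibitor1", "inhibitor2"),
      outputs = c("output1", "output2"))))
}

#' Feedback-loop pathway
#'
#' A pathway whose compiled network contains a directed cycle and, under
#' default initial values, a periodic attractor: an entry reaction (ligand
#' input, kinase catalyst) feeds a rotation loop of `loop_reactions`
#' reactions whose final reaction regenerates the loop entry and emits an
#' output complex; a feedback entity, produced from the output under a
#' modulator catalyst, inhibits the first loop reaction. Inhibiting the
#' kinase gates the loop entry; lowering the modulator's initial value
#' raises the floor of the output's oscillation, so the drug's effect on the
#' attractor minimum can be probed directionally.
#'
#' @param loop_reactions Number of reactions forming the cycle (>= 2).
#'   Default 4.
#' @param seed Unused (the construction is fully deterministic); kept so all
#'   fixture generators share one signature.
#' @return An `fp_pathway` with entities `ligand`, `kinase`, `modulator`,
#'   `loop_1` ... `loop_n`, `feedback` and `output_complex`.
#' @export
make_feedback_loop_pathway <- function(loop_reactions = 4L, seed = NULL) {
  n <- as.integer(loop_reactions)
  if (n < 2L) usage_error("loop_reactions must be >= 2")
  loop_ids <- sprintf("loop_%d", seq_len(n))
  # display names are uppercase gene-symbol style so drug tables (whose
  # target symbols are uppercase-normalized) resolve against them
  ents <- c(
    lapply(c("ligand", "kinase", "modulator", "feedback", "output_complex"),
           function(i) entity(i, name = toupper(i), entity_class = "protein")),
    lapply(loop_ids, function(i)
      entity(i, name = toupper(i), entity_class = "protein")))
  rxns <- list(
    reaction("r0_entry", inputs = "ligand", catalysts = "kinase",
             outputs = loop_ids[1L]),
    reaction("r1_loop", inputs = loop_ids[1L], inhibitors = "feedback",
             outputs = loop_ids[2L]))
  if (n > 2L)
    for (i in 2L:(n - 1L))
      rxns[[length(rxns) + 1L]] <- reaction(
        sprintf("r%d_loop", i), inputs = loop_ids[i], outputs = loop_ids[i + 1L])
  rxns[[length(rxns) + 1L]] <- reaction(
    sprintf("r%d_loop", n), inputs = loop_ids[n],
    outputs = c(loop_ids[1L], "output_complex"))
  rxns[[length(rxns) + 1L]] <- reaction(
    "r_feedback", inputs = "output_complex", catalysts = "modulator",
    outputs = "feedback")
  pathway(id = sprintf("feedback_loop_%d", n),
          name = sprintf("Feedback loop (%d reactions)", n),
          entities = ents, reactions = rxns)
}

#' Seeded random drug-target interaction table
#'
#' Generates a reproducible table in the `targetome` dialect: drugs
#' `DRUG_01` ..., targets `TGT_01` ...; every selected drug-target pair has
#' two or more assay rows with types drawn from KD/Ki/IC50/EC50 and values
#' log-uniform over [0.1, 1e6] nM. The first pair additionally carries one
#' value in each branch of the affinity-to-strength function (0.5, 5, 500,
#' 5e5 nM) so the full piecewise range is always represented.
#'
#' @param n_drugs,n_targets Numbers of drugs and targets (>= 1).
#' @param seed Integer seed.
#' @return Data frame in the `targetome` column layout.
#' @export
make_drug_table <- function(n_drugs = 5L, n_targets = 8L, seed = 1L) {
  if (n_drugs < 1L || n_targets < 1L) usage_error("sizes must be >= 1")
  set.seed(seed)
  drugs <- sprintf("DRUG_%02d", seq_len(n_drugs))
  targets <- sprintf("TGT_%02d", seq_len(n_targets))
  rows <- list(data.frame(
    drug = drugs[1L], target = targets[1L],
    assay_type = c("KD", "Ki", "IC50", "EC50"),
    assay_value_nM = c(0.5, 5, 500, 5e5),
    source = "fixture", pubmed_id = "PMID:0"))
  for (d in drugs) for (t in targets) {
    if (d == drugs[1L] && t == targets[1L]) next
    if (stats::runif(1) > 0.6) next
    k <- sample(2:4, 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      drug = d, target = t,
      assay_type = sample(ASSAY_TYPES, k, replace = TRUE),
      assay_value_nM = round(10^stats::runif(k, -1, 6), 4),
      source = "fixture", pubmed_id = sprintf("PMID:%d", sample.int(1e6, 1L)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an interaction table as TSV
#'
#' @param records Interaction data frame in the internal column layout.
#' @param path Output file path.
#' @param dialect Output dialect (`"targetome"` or `"drugcentral"`).
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path, dialect = c("targetome", "drugcentral")) {
  dialect <- match.arg(dialect)
  map <- DIALECTS[[dialect]]
  out <- data.frame(records$drug, records$target, records$assay_type,
                    records$assay_value_nM, records$source, records$pubmed_id)
  names(out) <- unname(map[c("drug", "target", "assay_type", "assay_value",
                             "source", "pubmed_id")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# printed layout of the canonical kinase-inhibitor enrichment example:
# set name, set size, and the query genes belonging to each set
TABLE_SETS <- list(
  list("Signaling by Receptor Tyrosine Kinases", 406L,
       c("FLT1", "FLT3", "FLT4", "KDR", "PDGFRB", "PDGFRA", "BRAF",
         "MAPK14", "KIT", "FGFR3")),
  list("RAF/MAP kinase cascade", 202L,
       c("RET", "FLT3", "PDGFRB", "PDGFRA", "BRAF", "KIT", "RAF1", "FGFR3")),
  list("MAPK1/MAPK3 signaling", 207L,
       c("RET", "FLT3", "PDGFRB", "PDGFRA", "BRAF", "KIT", "RAF1", "FGFR3")),
  list("MAPK family signaling cascades", 246L,
       c("RET", "FLT3", "PDGFRB", "PDGFRA", "BRAF", "KIT", "RAF1", "FGFR3")),
  list("VEGF ligand-receptor interactions", 8L, c("FLT1", "FLT4", "KDR")),
  list("VEGF binds to VEGFR leading to receptor dimerization", 8L,
       c("FLT1", "FLT4", "KDR")),
  list("Neurophilin interactions with VEGF and VEGFR", 4L, c("FLT1", "KDR")),
  list("PI5P, PP2A and IER3 Regulate PI3K/AKT Signaling", 90L,
       c("PDGFRB", "PDGFRA", "KIT", "FGFR3")),
  list("Signaling by VEGF", 94L, c("FLT1", "FLT4", "KDR", "MAPK14")),
  list("Negative regulation of the PI3K/AKT network", 95L,
       c("PDGFRB", "PDGFRA", "KIT", "FGFR3")),
  list("Negative feedback regulation of MAPK pathway", 6L, c("BRAF", "RAF1")),
  list("RAF activation", 12L, c("BRAF", "RAF1")))

#' Gene sets shaped like the kinase-inhibitor enrichment example
#'
#' Twelve gene sets with fixed sizes (406, 202, 207, 246, 8, 8, 4, 90, 94,
#' 95, 6, 12) whose membership of the twelve query kinase genes mirrors the
#' published receptor-tyrosine-kinase inhibitor target pattern; each set is
#' padded to size with deterministic filler symbols. The query is the union
#' of the member kinases.
#'
#' @return A list with `gene_sets` (named list of character vectors) and
#'   `query` (character vector of 12 gene symbols).
#' @export
make_table1_gene_sets <- function() {
  sets <- list()
  for (i in seq_along(TABLE_SETS)) {
    nm <- TABLE_SETS[[i]][[1L]]
    size <- TABLE_SETS[[i]][[2L]]
    members <- TABLE_SETS[[i]][[3L]]
    fill <- sprintf("SET%02d_G%04d", i, seq_len(size - length(members)))
    sets[[nm]] <- c(members, fill)
  }
  query <- unique(unlist(lapply(TABLE_SETS, `[[`, 3L)))
  list(gene_sets = sets, query = query)
}

#' Mutation-network fixture with drug overlay
#'
#' Builds the inputs of the network-overlay workflow: mutated-sample counts
#' for a small gene panel (a hub receptor gene `EGFR` plus kinases and
#' frequently mutated genes, two of them below the 5-sample threshold), a
#' mixed curated/predicted FI edge list among them, and an 18-drug
#' interaction table in which 14 drugs bind the hub at <= 100 nM and the
#' drug `SUNITINIB_MALATE` binds the two disjoint-pathway kinases `TNIK`
#' and `PAK3`.
#'
#' @param seed Integer seed for assay-value jitter.
#' @return A list with `edges`, `counts` and `interactions`.
#' @export
make_fi_fixture <- function(seed = 1L) {
  set.seed(seed)
  counts <- c(TP53 = 280L, TTN = 60L, EGFR = 11L, BRCA1 = 12L, CSMD3 = 19L,
              NF1 = 13L, CDK12 = 9L, FAT3 = 17L, GABRA6 = 6L, RB1 = 10L,
              TNIK = 7L, PAK3 = 5L, USH2A = 4L, HMCN1 = 3L)
  edges <- data.frame(
    gene_a = c("EGFR", "EGFR", "EGFR", "TP53", "TP53", "BRCA1", "NF1",
               "TNIK", "PAK3", "FAT3", "EGFR", "RB1", "USH2A"),
    gene_b = c("TP53", "NF1", "CDK12", "BRCA1", "RB1", "CDK12", "TTN",
               "TP53", "RB1", "CSMD3", "GABRA6", "CDK12", "HMCN1"),
    annotation = c("activation", "inhibition", "complex_or_input",
                   "complex_or_input", "inhibition", "predicted",
                   "predicted", "activation", "predicted",
                   "complex_or_input", "predicted", "other", "predicted"),
    curated = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
                TRUE, FALSE, TRUE, FALSE))
  hub_drugs <- sprintf("EGFR_DRUG_%02d", seq_len(14L))
  other <- data.frame(
    drug = c("SUNITINIB_MALATE", "SUNITINIB_MALATE", "TP53_DRUG",
             "RB1_DRUG", "NF1_DRUG"),
    target = c("TNIK", "PAK3", "TP53", "RB1", "NF1"))
  inter <- rbind(
    data.frame(drug = hub_drugs, target = "EGFR"),
    other)
  inter$assay_type <- sample(ASSAY_TYPES, nrow(inter), replace = TRUE)
  inter$assay_value_nM <- round(stats::runif(nrow(inter), 1, 100), 2)
  inter$source <- "fixture"
  inter$pubmed_id <- sprintf("PMID:%d", seq_len(nrow(inter)))
  list(edges = edges, counts = counts, interactions = inter)
}

#' Write a mutation-count table as TSV
#'
#' @param counts Named vector (gene -> mutated sample count).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mutation_counts <- function(counts, path) {
  utils::write.table(data.frame(gene = names(counts), samples = unname(counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an FI edge list as TSV
#'
#' @param edges FI edge data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fi_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
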