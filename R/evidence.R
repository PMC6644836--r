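ASSAY_TYPES <- c("KD", "Ki", "IC50", "EC50")

# column maps for the two supported table dialects
DIALECTS <- list(
  targetome = c(drug = "drug", target = "target", assay_type = "assay_type",
                assay_value = "assay_value_nM", source = "source",
                pubmed_id = "pubmed_id"),
  drugcentral = c(drug = "DRUG_NAME", target = "GENE", assay_type = "ACT_TYPE",
                  assay_value = "ACT_VALUE", source = "ACT_SOURCE",
                  pubmed_id = "PUBMED_ID")
)

#' Read a drug-target interaction table
#'
#' Supports two TSV dialects: `targetome` (columns `drug`, `target`,
#' `assay_type`, `assay_value_nM`, `source`, `pubmed_id`) and `drugcentral`
#' (columns `DRUG_NAME`, `GENE`, `ACT_TYPE`, `ACT_VALUE`, `ACT_SOURCE` and
#' optionally `PUBMED_ID`). Assay types are restricted to KD, Ki, IC50 and
#' EC50; values are kept in nM internally. Activity values recorded on a
#' p-scale (-log10 molar) are converted to nM via `10^(9 - p)` only when
#' `pscale = TRUE`; the scale is never auto-detected. Malformed rows
#' (non-numeric or non-positive values, unknown assay types, missing fields)
#' are collected into a rejects report attached as the `"rejects"`
#' attribute, not silently dropped.
#'
#' @param path Path to the TSV file.
#' @param dialect `"targetome"` or `"drugcentral"`.
#' @param pscale Logical; interpret the value column as p-scale and convert
#'   to nM. Default `FALSE`.
#' @return Data frame with columns `drug`, `target`, `assay_type`,
#'   `assay_value_nM`, `source`, `pubmed_id`; attribute `rejects` holds the
#'   rejected rows with a `reason` column.
#' @export
read_interactions <- function(path, dialect = c("targetome", "drugcentral"),
                              pscale = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) usage_error(sprintf("no such file: %s", path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- DIALECTS[[dialect]]
  need <- map[c("drug", "target", "assay_type", "assay_value")]
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    validation_error(paste0("dialect '", dialect, "': missing columns: ",
                            paste(missing_cols, collapse = ", ")))

  get <- function(key) {
    col <- map[[key]]
    if (col %in% names(raw)) as.character(raw[[col]]) else rep(NA_character_, nrow(raw))
  }
  df <- data.frame(drug = get("drug"), target = toupper(get("target")),
                   assay_type = get("assay_type"),
                   value_raw = get("assay_value"),
                   source = get("source"), pubmed_id = get("pubmed_id"),
                   stringsAsFactors = FALSE)

  val <- suppressWarnings(as.numeric(df$value_raw))
  if (pscale) val <- 10^(9 - val)
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$drug) | !nzchar(df$drug)] <- "missing drug"
  reason[is.na(df$target) | !nzchar(df$target)] <- "missing target"
  reason[!(df$assay_type %in% ASSAY_TYPES)] <- "unknown assay type"
  reason[is.na(val)] <- "non-numeric assay value"
  reason[!is.na(val) & val <= 0] <- "non-positive assay value"

  keep <- is.na(reason)
  out <- data.frame(drug = df$drug[keep], target = df$target[keep],
                    assay_type = df$assay_type[keep],
                    assay_value_nM = val[keep],
                    source = df$source[keep], pubmed_id = df$pubmed_id[keep],
                    stringsAsFactors = FALSE)
  rejects <- cbind(raw[!keep, , drop = FALSE],
                   reason = reason[!keep])
  if (nrow(out) == 0L)
    validation_error(sprintf("no parseable rows in %s (%d rejected)",
                             path, nrow(rejects)))
  if (nrow(rejects) > 0L)
    message(sprintf("read_interactions: %d row(s) rejected (see attr 'rejects')",
                    nrow(rejects)))
  attr(out, "rejects") <- rejects
  out
}

#' Filter interactions by assay value and type
#'
#' Keeps records whose assay value is at or below `max_nM` (the threshold is
#' inclusive) and whose assay type is in `assay_types`. Row order is
#' preserved; filtering is idempotent and monotone in the threshold.
#'
#' @param records Interaction data frame (see [read_interactions()]).
#' @param max_nM Positive threshold in nM.
#' @param assay_types Nonempty subset of KD, Ki, IC50, EC50.
#' @return The retained rows.
#' @export
filter_by_assay <- function(records, max_nM, assay_types = ASSAY_TYPES) {
  stopifnot(is.data.frame(records))
  if (!is.numeric(max_nM) || length(max_nM) != 1L || max_nM <= 0)
    usage_error("max_nM must be a single positive value")
  if (length(assay_types) == 0L)
    usage_error("assay_types must be a nonempty subset of KD, Ki, IC50, EC50")
  bad <- setdiff(assay_types, ASSAY_TYPES)
  if (length(bad))
    usage_error(paste0("unknown assay types: ", paste(bad, collapse = ", ")))
  keep <- records$assay_value_nM <= max_nM & records$assay_type %in% assay_types
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize evidence for one drug
#'
#' Computes per-target minimum assay values, flags targets supported by two
#' or more assay records at or below `multi_nM` (the "multiple assay values
#' under threshold" notion), and bins all of the drug's assay values into a
#' histogram. Bins are half-open `[lo, hi)` with the final bin closed.
#'
#' @param records Interaction data frame.
#' @param drug Drug name.
#' @param bin_edges Strictly increasing numeric vector of histogram edges
#'   (nM).
#' @param multi_nM Threshold for the multi-assay-support flag. Default 100.
#' @return A list of class `fp_evidence_summary`: `drug`, `targets` (data
#'   frame `target`, `min_assay_nM`, `n_records`, `multi_assay`), and
#'   `histogram` (data frame `lower`, `upper`, `count`).
#' @export
summarize_evidence <- function(records, drug,
                               bin_edges = c(0, 1, 10, 100, 1000, 1e6),
                               multi_nM = 100) {
  stopifnot(is.data.frame(records))
  if (any(diff(bin_edges) <= 0))
    usage_error("bin_edges must be strictly increasing")
  rows <- records[records$drug == drug, , drop = FALSE]
  if (nrow(rows) == 0L)
    warning(sprintf("drug '%s' has no interaction records", drug))

  if (nrow(rows)) {
    split_vals <- split(rows$assay_value_nM, rows$target)
    targets <- data.frame(
      target = names(split_vals),
      min_assay_nM = vapply(split_vals, min, numeric(1)),
      n_records = vapply(split_vals, length, integer(1)),
      multi_assay = vapply(split_vals, function(v) sum(v <= multi_nM) >= 2L,
                           logical(1)),
      row.names = NULL)
    targets <- targets[order(targets$min_assay_nM, targets$target), ]
    rownames(targets) <- NULL
  } else {
    targets <- data.frame(target = character(0), min_assay_nM = numeric(0),
                          n_records = integer(0), multi_assay = logical(0))
  }

  nb <- length(bin_edges) - 1L
  counts <- integer(nb)
  for (i in seq_len(nb)) {
    lo <- bin_edges[i]; hi <- bin_edges[i + 1L]
    counts[i] <- if (i < nb) sum(rows$assay_value_nM >= lo & rows$assay_value_nM < hi)
                 else sum(rows$assay_value_nM >= lo & rows$assay_value_nM <= hi)
  }
  structure(list(drug = drug, targets = targets,
                 histogram = data.frame(lower = bin_edges[-length(bin_edges)],
                                        upper = bin_edges[-1L],
                                        count = counts)),
            class = "fp_evidence_summary")
}

#' @export
print.fp_evidence_summary <- function(x, ...) {
  cat(sprintf("<evidence summary for '%s': %d target(s), %d binned record(s)>\n",
              x$drug, nrow(x$targets), sum(x$histogram$count)))
  print(utils::head(x$targets, 10), row.names = FALSE)
  invisible(x)
}

#' Export an evidence summary as TSV
#'
#' @param summary An `fp_evidence_summary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evidence_summary <- function(summary, path) {
  stopifnot(inherits(summary, "fp_evidence_summary"))
  utils::write.table(summary$targets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
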