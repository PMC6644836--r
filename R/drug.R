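#' Map a binding assay value to a perturbation strength
#'
#' Piecewise affinity-to-strength mapping over the minimum supporting assay
#' value (in nM) of a drug-target interaction:
#' 0.999 below 1 nM; 0.99 below 10 nM; `0.99 - 0.196 * (log10(v) - 1)`
#' below 1e6 nM; 0 at or above 1e6 nM. The logarithm is base 10, which makes
#' the third branch continuous with the second at 10 nM. The result is
#' clipped to [0, 0.999].
#'
#' @param min_assay_nM Positive assay value in nanomolar (vectorized).
#' @return Strength value(s) in [0, 0.999].
#' @export
strength_from_assay <- function(min_assay_nM) {
  if (!is.numeric(min_assay_nM) || any(!is.finite(min_assay_nM)) ||
      any(min_assay_nM <= 0))
    usage_error("assay values must be positive and finite (nM)")
  s <- ifelse(min_assay_nM < 1, 0.999,
       ifelse(min_assay_nM < 10, 0.99,
       ifelse(min_assay_nM < 1e6, 0.99 - 0.196 * (log10(min_assay_nM) - 1),
              0)))
  pmin(pmax(s, 0), 0.999)
}

#' Minimum supporting assay value for a drug-target pair
#'
#' @param interactions Data frame of interactions (see
#'   [read_interactions()]): columns `drug`, `target`, `assay_value_nM`.
#' @param drug,target Drug name and target gene symbol.
#' @return The minimum assay value in nM across all assay types, or `NULL`
#'   when the pair has no records.
#' @export
min_assay <- function(interactions, drug, target) {
  stopifnot(is.data.frame(interactions))
  hit <- interactions$drug == drug & interactions$target == target
  if (!any(hit)) return(NULL)
  min(interactions$assay_value_nM[hit])
}

#' Construct a drug action
#'
#' A drug action carries the perturbation applied during simulation: the
#' mechanism (inhibition or activation) and a strength in [0, 0.999],
#' usually derived from assay evidence via [strength_from_assay()].
#'
#' @param drug Drug name.
#' @param targets Character vector of target variable ids.
#' @param mechanism `"inhibition"` or `"activation"`.
#' @param strength Value in [0, 0.999].
#' @return A list of class `fp_drug_action`.
#' @export
drug_action <- function(drug, targets, mechanism = c("inhibition", "activation"),
                        strength) {
  mechanism <- match.arg(mechanism)
  targets <- as_chr(targets)
  if (length(targets) == 0L) usage_error("drug action needs >= 1 target")
  if (!is.numeric(strength) || length(strength) != 1L ||
      strength < 0 || strength > 0.999)
    usage_error("strength must be a single value in [0, 0.999]")
  structure(list(drug = drug, targets = targets, mechanism = mechanism,
                 strength = strength),
            class = "fp_drug_action")
}

#' Apply a drug action to a network's transfer functions
#'
#' Returns a per-variable transfer list in which each target's transfer is
#' composed with the drug gate: for inhibition of strength s the
#' post-transfer value is multiplied by (1 - s); for activation the value v
#' becomes v + s(1 - v). Untargeted variables are unchanged. This is the
#' static ("modify the transfer functions") view of the perturbation;
#' [simulate_network()] applies the same gating dynamically via its
#' `actions` argument, which also covers targets that have no relation.
#'
#' @param net An `fp_boolnet`.
#' @param transfers Named list of [transfer_spec()], or `NULL`.
#' @param action A [drug_action()].
#' @return A named list of transfer closures (functions of one value).
#' @export
apply_drug <- function(net, transfers = NULL, action) {
  stopifnot(inherits(net, "fp_boolnet"), inherits(action, "fp_drug_action"))
  unknown <- setdiff(action$targets, net$variables$id)
  if (length(unknown))
    runtime_error(paste0("drug targets not in network: ",
                         paste(unknown, collapse = ", ")))
  out <- lapply(stats::setNames(net$variables$id, net$variables$id),
                function(id) {
    tf <- transfers[[id]]
    if (id %in% action$targets)
      function(v) gate_value(apply_transfer(v, tf), action$mechanism,
                             action$strength)
    else
      function(v) apply_transfer(v, tf)
  })
  out
}

#' Per-variable relative impact scores between two traces
#'
#' For each variable the area under its fuzzy-value-vs-time-step curve (AUC;
#' rectangle rule with unit step width, i.e. the sum over steps) is computed
#' for the reference and the perturbed trace, and the score is
#' `(perturbation_AUC - reference_AUC) / (perturbation_AUC + reference_AUC)`,
#' with 0/0 defined as 0. Scores lie in [-1, 1] and are antisymmetric under
#' swapping the two traces.
#'
#' @param reference,perturbed `fp_trace` objects (or matrices) over the same
#'   variables with equal step counts.
#' @return Data frame with columns `variable`, `reference_auc`,
#'   `perturbation_auc`, `score`.
#' @export
relative_impact <- function(reference, perturbed) {
  mr <- unclass(reference); mp <- unclass(perturbed)
  if (!identical(colnames(mr), colnames(mp)))
    usage_error("traces cover different variables")
  if (nrow(mr) != nrow(mp))
    usage_error("traces have different step counts; expand in lockstep first")
  ref_auc <- colSums(mr)
  per_auc <- colSums(mp)
  denom <- per_auc + ref_auc
  score <- ifelse(denom > 0, (per_auc - ref_auc) / denom, 0)
  data.frame(variable = colnames(mr), reference_auc = unname(ref_auc),
             perturbation_auc = unname(per_auc), score = unname(score),
             row.names = NULL)
}

# map drug-table target symbols onto pathway entity variables (ids first,
# then display names; ids are the primary join key)
resolve_targets <- function(pw, targets) {
  ids <- names(pw$entities)
  nms <- vapply(pw$entities, function(e) e$name, character(1))
  hit <- targets %in% ids | targets %in% nms
  out <- character(0)
  for (t in targets[hit]) {
    if (t %in% ids) out <- c(out, t)
    else out <- c(out, ids[nms == t])
  }
  unique(out)
}

#' Run a drug-perturbation study on a pathway
#'
#' Compiles the pathway, resolves the drug's targets against the pathway's
#' entities (by id, then display name), derives one inhibition/activation
#' strength per target from the minimum supporting assay value, and runs a
#' reference simulation (no drug) and a perturbation simulation (drug
#' applied) from identical initial values. Both traces are then expanded in
#' lockstep along their attractors until the per-entity relative impact
#' scores stabilize, and the scores are returned.
#'
#' @param pw An `fp_pathway`.
#' @param interactions Drug-target interaction data frame
#'   ([read_interactions()]).
#' @param drug Drug name, present in `interactions`.
#' @param mechanism `"inhibition"` (default) or `"activation"`.
#' @param config A [sim_config()].
#' @param transfers Named list of [transfer_spec()], or `NULL`.
#' @return A list of class `fp_perturbation_study`: `reference` and
#'   `perturbed` expanded traces of equal length, `scores`
#'   (see [relative_impact()]), and `actions` applied.
#' @export
run_perturbation_study <- function(pw, interactions, drug,
                                   mechanism = c("inhibition", "activation"),
                                   config = sim_config(), transfers = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(pw, "fp_pathway"), is.data.frame(interactions))
  rows <- interactions[interactions$drug == drug, , drop = FALSE]
  if (nrow(rows) == 0L)
    usage_error(sprintf("drug '%s' not present in the interaction table", drug))
  targets <- resolve_targets(pw, unique(rows$target))
  if (length(targets) == 0L)
    runtime_error(sprintf(
      "drug '%s' has no target among the pathway's entities", drug))

  net <- build_network(pw)
  actions <- lapply(targets, function(tgt) {
    sym <- unique(rows$target[rows$target == tgt |
                              rows$target == pw$entities[[tgt]]$name])
    mav <- min(rows$assay_value_nM[rows$target %in% sym])
    drug_action(drug, tgt, mechanism, strength_from_assay(mav))
  })

  reference <- simulate_network(net, config, transfers = transfers)
  perturbed <- simulate_network(net, config, transfers = transfers,
                                actions = actions)
  ex <- expand_trace(perturbed, config, reference = reference)
  structure(list(reference = ex$reference, perturbed = ex$trace,
                 scores = ex$scores, actions = actions),
            class = "fp_perturbation_study")
}

#' Export impact scores as TSV
#'
#' @param scores Data frame from [relative_impact()] (or a study's
#'   `$scores`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(is.data.frame(scores))
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.fp_perturbation_study <- function(x, ...) {
  cat(sprintf("<perturbation study: %d variables, %d steps, drug '%s' (%s)>\n",
              ncol(x$reference), nrow(x$reference),
              x$actions[[1]]$drug, x$actions[[1]]$mechanism))
  top <- x$scores[order(-abs(x$scores$score)), ][seq_len(min(5, nrow(x$scores))), ]
  print(top, row.names = FALSE)
  invisible(x)
}
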