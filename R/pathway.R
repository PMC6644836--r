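#' Construct a pathway entity
#'
#' An entity is any node of the reaction model: a protein, a small molecule,
#' a complex (all components required), an entity set (interchangeable
#' members), or an untyped placeholder. Identifiers are opaque strings and are
#' the only join keys; display names are never used for matching.
#'
#' @param id Opaque string identifier, unique within a pathway.
#' @param name Display name (defaults to the id).
#' @param entity_class One of `"protein"`, `"small_molecule"`, `"complex"`,
#'   `"entity_set"`, `"other"`.
#' @param components Character vector of entity ids. Must be nonempty exactly
#'   when `entity_class` is `"complex"` or `"entity_set"` (subunits or set
#'   members respectively), and empty otherwise.
#' @return A list of class `fp_entity`.
#' @export
entity <- function(id, name = id,
                   entity_class = c("protein", "small_molecule", "complex",
                                    "entity_set", "other"),
                   components = character(0)) {
  entity_class <- match.arg(entity_class)
  if (!is_string(id) || !nzchar(id))
    validation_error("entity 'id' must be a nonempty string")
  if (!is_string(name)) validation_error(sprintf("entity '%s': bad 'name'", id))
  components <- as_chr(components)
  container <- entity_class %in% c("complex", "entity_set")
  if (container && length(components) == 0L)
    validation_error(sprintf(
      "entity '%s': class '%s' requires nonempty 'components'", id, entity_class))
  if (!container && length(components) > 0L)
    validation_error(sprintf(
      "entity '%s': class '%s' must not have 'components'", id, entity_class))
  structure(list(id = id, name = name, entity_class = entity_class,
                 components = components),
            class = "fp_entity")
}

#' Construct a biochemical reaction
#'
#' A reaction has one or more inputs, zero or more catalysts, activators and
#' inhibitors, and one or more outputs, all referring to entity ids. Multiple
#' catalysts are allowed and all enter the AND like inputs (the single-catalyst
#' case is the degenerate form).
#'
#' @param id Opaque string identifier.
#' @param inputs,outputs Character vectors of entity ids; both must be
#'   nonempty.
#' @param catalysts,activators,inhibitors Character vectors of entity ids,
#'   possibly empty.
#' @return A list of class `fp_reaction`.
#' @export
reaction <- function(id, inputs, outputs, catalysts = character(0),
                     activators = character(0), inhibitors = character(0)) {
  if (!is_string(id) || !nzchar(id))
    validation_error("reaction 'id' must be a nonempty string")
  inputs <- as_chr(inputs); outputs <- as_chr(outputs)
  catalysts <- as_chr(catalysts); activators <- as_chr(activators)
  inhibitors <- as_chr(inhibitors)
  if (length(inputs) == 0L)
    validation_error(sprintf("reaction '%s': 'inputs' must be nonempty", id))
  if (length(outputs) == 0L)
    validation_error(sprintf("reaction '%s': 'outputs' must be nonempty", id))
  structure(list(id = id, inputs = inputs, catalysts = catalysts,
                 activators = activators, inhibitors = inhibitors,
                 outputs = outputs),
            class = "fp_reaction")
}

#' Construct a pathway
#'
#' Bundles entities and reactions and checks referential integrity: unique
#' ids, resolvable references, and no cyclic containment of complexes or
#' entity sets.
#'
#' @param id,name Pathway identifier and display name.
#' @param entities List of [entity()] objects.
#' @param reactions List of [reaction()] objects.
#' @return A list of class `fp_pathway` with `entities` and `reactions` as
#'   named lists keyed by id.
#' @export
pathway <- function(id, name = id, entities = list(), reactions = list()) {
  if (!is_string(id) || !nzchar(id))
    validation_error("pathway 'id' must be a nonempty string")
  stopifnot(is.list(entities), is.list(reactions))
  ent_ids <- vapply(entities, function(e) e$id, character(1))
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ent_ids))
    integrity_error(paste0("duplicate entity ids: ",
                           paste(unique(ent_ids[duplicated(ent_ids)]), collapse = ", ")))
  if (anyDuplicated(rxn_ids))
    integrity_error(paste0("duplicate reaction ids: ",
                           paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  names(entities) <- ent_ids
  names(reactions) <- rxn_ids
  pw <- structure(list(id = id, name = name, entities = entities,
                       reactions = reactions),
                  class = "fp_pathway")
  validate_pathway(pw)
  pw
}

#' Validate a pathway's invariants
#'
#' Checks that every component and reaction-role reference resolves to a
#' declared entity and that containment (complex/entity-set membership) is
#' acyclic. Called by [pathway()] and [read_pathway()]; exported for callers
#' that assemble pathways programmatically.
#'
#' @param pw An `fp_pathway`.
#' @return `pw`, invisibly, if valid; otherwise an integrity error listing the
#'   unresolved ids or the containment cycle.
#' @export
validate_pathway <- function(pw) {
  stopifnot(inherits(pw, "fp_pathway"))
  ent_ids <- names(pw$entities)

  dangling <- character(0)
  for (e in pw$entities) {
    miss <- setdiff(e$components, ent_ids)
    if (length(miss))
      dangling <- c(dangling, sprintf("entity '%s' component '%s'", e$id, miss))
  }
  for (r in pw$reactions) {
    refs <- c(r$inputs, r$catalysts, r$activators, r$inhibitors, r$outputs)
    miss <- setdiff(refs, ent_ids)
    if (length(miss))
      dangling <- c(dangling, sprintf("reaction '%s' reference '%s'", r$id, miss))
  }
  if (length(dangling))
    integrity_error(paste0("unresolved references: ",
                           paste(dangling, collapse = "; ")))

  # containment must be a DAG: DFS with a grey set
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack)
      integrity_error(paste0("cyclic containment: ",
                             paste(c(stack, id), collapse = " -> ")))
    if (isTRUE(state[[id]])) return(invisible(NULL))
    for (cid in pw$entities[[id]]$components) visit(cid, c(stack, id))
    state[[id]] <- TRUE
    invisible(NULL)
  }
  for (id in ent_ids) visit(id, character(0))
  invisible(pw)
}

# ---------------------------------------------------------------------------
# JSON dialect (this package's own schema, versioned)

FP_PATHWAY_FORMAT <- "fuzzypath-pathway"
FP_PATHWAY_VERSION <- "1.0"

#' Read a pathway from its JSON file
#'
#' The file format is this package's own documented dialect (see the methods
#' vignette): a top-level object with `format`, `version`, `id`, `name`, an
#' `entities` array (`id`, `name`, `class`, optional `components`) and a
#' `reactions` array (`id`, `inputs`, `catalysts`, `activators`, `inhibitors`,
#' `outputs`). All invariants are checked on read.
#'
#' @param path Path to a pathway JSON file.
#' @return An `fp_pathway`.
#' @seealso [write_pathway()], [write_sif()]
#' @export
read_pathway <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("no such file: %s", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    validation_error(sprintf("not valid JSON (%s): %s",
                                             path, conditionMessage(e))))
  if (!identical(doc$format, FP_PATHWAY_FORMAT))
    validation_error("field 'format': expected 'fuzzypath-pathway'")
  if (is.null(doc$id)) validation_error("field 'id': missing")
  ents <- lapply(doc$entities %||% list(), function(e) {
    if (is.null(e$id)) validation_error("field 'entities[].id': missing")
    entity(id = e$id, name = e$name %||% e$id,
           entity_class = e$class %||% "other",
           components = as_chr(e$components))
  })
  rxns <- lapply(doc$reactions %||% list(), function(r) {
    if (is.null(r$id)) validation_error("field 'reactions[].id': missing")
    reaction(id = r$id, inputs = as_chr(r$inputs), outputs = as_chr(r$outputs),
             catalysts = as_chr(r$catalysts),
             activators = as_chr(r$activators),
             inhibitors = as_chr(r$inhibitors))
  })
  pathway(id = doc$id, name = doc$name %||% doc$id,
          entities = ents, reactions = rxns)
}

#' Write a pathway to JSON
#'
#' Inverse of [read_pathway()]: `read_pathway(write_pathway(pw, f))`
#' round-trips to an identical pathway.
#'
#' @param pw An `fp_pathway`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(pw, path) {
  stopifnot(inherits(pw, "fp_pathway"))
  doc <- list(
    format = FP_PATHWAY_FORMAT,
    version = FP_PATHWAY_VERSION,
    id = pw$id,
    name = pw$name,
    entities = unname(lapply(pw$entities, function(e) {
      out <- list(id = e$id, name = e$name, class = e$entity_class)
      if (length(e$components)) out$components <- as.list(e$components)
      out
    })),
    reactions = unname(lapply(pw$reactions, function(r)
      list(id = r$id, inputs = as.list(r$inputs),
           catalysts = as.list(r$catalysts),
           activators = as.list(r$activators),
           inhibitors = as.list(r$inhibitors),
           outputs = as.list(r$outputs))))
  )
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) runtime_error(sprintf("cannot write %s", path)))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE), con)
  invisible(path)
}

#' Export pathway wiring as SIF
#'
#' Writes one tab-separated row per (source, relation, target) triple derived
#' from reaction roles and containment. The fixed relation vocabulary is:
#' `input`, `catalyst`, `activator`, `inhibitor` (entity -> reaction),
#' `output` (reaction -> entity) and `component` (component -> container).
#' Rows are emitted in reaction id order (roles in the order above), then
#' container entities in id order.
#'
#' @param pw An `fp_pathway`.
#' @param path Output file path.
#' @return The number of rows written.
#' @export
write_sif <- function(pw, path) {
  stopifnot(inherits(pw, "fp_pathway"))
  rows <- character(0)
  for (rid in sort(names(pw$reactions))) {
    r <- pw$reactions[[rid]]
    rows <- c(rows,
              sprintf("%s\tinput\t%s", r$inputs, rid),
              sprintf("%s\tcatalyst\t%s", r$catalysts, rid),
              sprintf("%s\tactivator\t%s", r$activators, rid),
              sprintf("%s\tinhibitor\t%s", r$inhibitors, rid),
              sprintf("%s\toutput\t%s", rid, r$outputs))
  }
  for (eid in sort(names(pw$entities))) {
    e <- pw$entities[[eid]]
    if (length(e$components))
      rows <- c(rows, sprintf("%s\tcomponent\t%s", e$components, eid))
  }
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) runtime_error(sprintf("cannot write %s", path))
  length(rows)
}

#' @export
print.fp_pathway <- function(x, ...) {
  cat(sprintf("<pathway '%s' (%s): %d entities, %d reactions>\n",
              x$id, x$name, length(x$entities), length(x$reactions)))
  invisible(x)
}
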