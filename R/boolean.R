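#' Construct a Boolean relation
#'
#' A relation computes one output variable from a set of literals:
#' `AND` combines by conjunction (fuzzy min), `OR` by disjunction (fuzzy max),
#' and `ASSIGN` copies a single literal. Negation (`!x`, fuzzy `1 - x`) is
#' only legal on literals inside `AND` relations, where compiled inhibitors
#' live.
#'
#' @param output Output variable id.
#' @param op `"AND"`, `"OR"` or `"ASSIGN"`.
#' @param literals Data frame with columns `id` (character) and `negated`
#'   (logical), or a character vector (all non-negated).
#' @return A list of class `fp_relation`.
#' @export
bool_relation <- function(output, op = c("AND", "OR", "ASSIGN"), literals) {
  op <- match.arg(op)
  if (!is_string(output)) validation_error("relation 'output' must be a string")
  if (is.character(literals))
    literals <- data.frame(id = literals, negated = FALSE)
  stopifnot(is.data.frame(literals), all(c("id", "negated") %in% names(literals)))
  literals <- unique(literals[, c("id", "negated")])
  rownames(literals) <- NULL
  if (nrow(literals) == 0L) validation_error("relation literals must be nonempty")
  if (op == "ASSIGN" && nrow(literals) != 1L)
    validation_error("ASSIGN relation must have exactly one literal")
  if (op != "AND" && any(literals$negated))
    validation_error("negation only allowed inside AND relations")
  structure(list(output = output, op = op, literals = literals),
            class = "fp_relation")
}

# deterministic accessory-variable ids, derived from reaction id + role
accessory_id <- function(rid, role) paste0(rid, "__", role, "_acc")

#' Compile one reaction into Boolean relations
#'
#' Implements the reaction-conversion scheme: inputs, catalysts, the
#' activator term and the negated inhibitor term are ANDed into the output
#' term. Accessory variables are introduced only when a role has two or more
#' members: multiple activators (or inhibitors) are ORed into an accessory
#' that enters the AND as one literal, and multiple outputs are fed by an
#' output accessory through one ASSIGN per output. A role with a single
#' member is wired directly; a reaction reduced to one input and one output
#' compiles to a single ASSIGN.
#'
#' @param r An [reaction()].
#' @return A list with `relations` (list of [bool_relation()]) and
#'   `accessories` (data frame `id`, `kind` of the variables introduced).
#' @export
convert_reaction <- function(r) {
  stopifnot(inherits(r, "fp_reaction"))
  rels <- list()
  acc <- data.frame(id = character(0), kind = character(0))

  activators <- unique(r$activators)
  inhibitors <- unique(r$inhibitors)
  outputs <- unique(r$outputs)

  lits <- data.frame(id = unique(c(r$inputs, r$catalysts)), negated = FALSE)

  if (length(activators) >= 2L) {
    aid <- accessory_id(r$id, "activator")
    rels[[length(rels) + 1L]] <- bool_relation(aid, "OR", activators)
    acc <- rbind(acc, data.frame(id = aid, kind = "accessory_activator"))
    lits <- rbind(lits, data.frame(id = aid, negated = FALSE))
  } else if (length(activators) == 1L) {
    lits <- rbind(lits, data.frame(id = activators, negated = FALSE))
  }

  if (length(inhibitors) >= 2L) {
    iid <- accessory_id(r$id, "inhibitor")
    rels[[length(rels) + 1L]] <- bool_relation(iid, "OR", inhibitors)
    acc <- rbind(acc, data.frame(id = iid, kind = "accessory_inhibitor"))
    lits <- rbind(lits, data.frame(id = iid, negated = TRUE))
  } else if (length(inhibitors) == 1L) {
    lits <- rbind(lits, data.frame(id = inhibitors, negated = TRUE))
  }

  if (length(outputs) >= 2L) {
    oid <- accessory_id(r$id, "output")
    acc <- rbind(acc, data.frame(id = oid, kind = "accessory_output"))
  } else {
    oid <- outputs
  }

  lits <- unique(lits)
  op <- if (nrow(lits) == 1L && !lits$negated[1L]) "ASSIGN" else "AND"
  rels[[length(rels) + 1L]] <- bool_relation(oid, op, lits)

  if (length(outputs) >= 2L)
    for (out in outputs)
      rels[[length(rels) + 1L]] <- bool_relation(out, "ASSIGN", oid)

  list(relations = rels, accessories = acc)
}

#' Expand a complex into an AND relation
#'
#' A complex is present only when all of its subunits are, so its defining
#' relation is the conjunction of its components (an ASSIGN for a
#' single-subunit complex). Nested complexes expand recursively through their
#' own relations: the outer AND references the inner complex's variable.
#'
#' @param e An [entity()] with `entity_class = "complex"`.
#' @return A [bool_relation()].
#' @export
expand_complex <- function(e) {
  stopifnot(inherits(e, "fp_entity"))
  if (!identical(e$entity_class, "complex"))
    usage_error(sprintf("entity '%s' is not a complex", e$id))
  comps <- unique(e$components)
  if (length(comps) == 0L)
    integrity_error(sprintf("complex '%s' has no components", e$id))
  bool_relation(e$id, if (length(comps) == 1L) "ASSIGN" else "AND", comps)
}

#' Expand an entity set into an OR relation
#'
#' Any member of an entity set can stand in for the set, so its defining
#' relation is the disjunction of its members (an ASSIGN for a single-member
#' set).
#'
#' @param e An [entity()] with `entity_class = "entity_set"`.
#' @return A [bool_relation()].
#' @export
expand_entity_set <- function(e) {
  stopifnot(inherits(e, "fp_entity"))
  if (!identical(e$entity_class, "entity_set"))
    usage_error(sprintf("entity '%s' is not an entity set", e$id))
  mem <- unique(e$components)
  if (length(mem) == 0L)
    integrity_error(sprintf("entity set '%s' has no members", e$id))
  bool_relation(e$id, if (length(mem) == 1L) "ASSIGN" else "OR", mem)
}

# entities on a directed cycle of the entity -> reaction -> entity graph
cycle_entities <- function(pw) {
  if (length(pw$reactions) == 0L) return(character(0))
  from <- character(0); to <- character(0)
  for (r in pw$reactions) {
    used <- unique(c(r$inputs, r$catalysts, r$activators, r$inhibitors))
    rnode <- paste0("rxn::", r$id)
    from <- c(from, used, rep(rnode, length(unique(r$outputs))))
    to <- c(to, rep(rnode, length(used)), unique(r$outputs))
  }
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = TRUE)
  scc <- igraph::components(g, mode = "strong")
  big <- which(tabulate(scc$membership) > 1L)
  on_cycle <- names(scc$membership)[scc$membership %in% big]
  setdiff(on_cycle, grep("^rxn::", on_cycle, value = TRUE))
}

#' Compile a pathway into a Boolean network
#'
#' Converts every reaction, complex and entity set of the pathway into
#' Boolean relations over one variable per entity plus the accessory
#' variables that multi-member roles require. `root_inputs` collects the
#' entities used by reactions (as input, catalyst, activator or inhibitor)
#' that are either never produced as an output or lie on a directed cycle of
#' the entity/reaction graph; these receive the default initial value 1.0 in
#' simulation. All ordering is lexicographic by id so compilation is
#' deterministic.
#'
#' @param pw An `fp_pathway`.
#' @return A list of class `fp_boolnet` with `variables` (data frame `id`,
#'   `kind`), `relations` (list of [bool_relation()], sorted), and
#'   `root_inputs` (character vector of variable ids).
#' @export
build_network <- function(pw) {
  stopifnot(inherits(pw, "fp_pathway"))
  validate_pathway(pw)

  rels <- list()
  acc <- data.frame(id = character(0), kind = character(0))
  for (rid in sort(names(pw$reactions))) {
    conv <- convert_reaction(pw$reactions[[rid]])
    rels <- c(rels, conv$relations)
    acc <- rbind(acc, conv$accessories)
  }
  for (eid in sort(names(pw$entities))) {
    e <- pw$entities[[eid]]
    if (e$entity_class == "complex")
      rels[[length(rels) + 1L]] <- expand_complex(e)
    else if (e$entity_class == "entity_set")
      rels[[length(rels) + 1L]] <- expand_entity_set(e)
  }

  variables <- rbind(
    data.frame(id = sort(names(pw$entities)),
               kind = rep("entity", length(pw$entities))),
    acc)
  variables <- variables[order(variables$id), , drop = FALSE]
  rownames(variables) <- NULL
  if (anyDuplicated(variables$id))
    integrity_error("variable id collision between entities and accessories")

  # stable relation order: output id, then op, then literal signature
  sig <- vapply(rels, function(rl)
    paste(rl$output, rl$op,
          paste(ifelse(rl$literals$negated, "!", ""), rl$literals$id,
                sep = "", collapse = ","), sep = "|"), character(1))
  rels <- rels[order(sig)]

  for (rl in rels) {
    bad <- setdiff(c(rl$output, rl$literals$id), variables$id)
    if (length(bad))
      integrity_error(paste0("relation references undeclared variables: ",
                             paste(bad, collapse = ", ")))
  }

  used <- unique(unlist(lapply(pw$reactions, function(r)
    c(r$inputs, r$catalysts, r$activators, r$inhibitors))))
  produced <- unique(unlist(lapply(pw$reactions, function(r) r$outputs)))
  roots <- sort(unique(c(setdiff(used, produced),
                         intersect(used, cycle_entities(pw)))))

  structure(list(variables = variables, relations = rels,
                 root_inputs = roots),
            class = "fp_boolnet")
}

#' @export
print.fp_boolnet <- function(x, ...) {
  cat(sprintf("<boolean network: %d variables, %d relations, %d root inputs>\n",
              nrow(x$variables), length(x$relations), length(x$root_inputs)))
  invisible(x)
}

# one relation as a human-readable rule line, using the conventional
# operators: "a · b · !c = out", "a + b = out", "a = out"
format_relation <- function(rl) {
  toks <- paste0(ifelse(rl$literals$negated, "!", ""), rl$literals$id)
  lhs <- switch(rl$op,
                AND = paste(toks, collapse = " · "),
                OR = paste(toks, collapse = " + "),
                ASSIGN = toks)
  paste(lhs, "=", rl$output)
}

#' Write a network as a human-readable rule file
#'
#' One relation per line, conjunction as `·`, disjunction as `+`,
#' negation as `!`.
#'
#' @param net An `fp_boolnet`.
#' @param path Output file path.
#' @return The number of lines written, invisibly.
#' @export
write_rules <- function(net, path) {
  stopifnot(inherits(net, "fp_boolnet"))
  lines <- vapply(net$relations, format_relation, character(1))
  writeLines(lines, path)
  invisible(length(lines))
}

#' Serialize a network to JSON
#'
#' @param net An `fp_boolnet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "fp_boolnet"))
  doc <- list(
    format = "fuzzypath-network", version = "1.0",
    variables = lapply(seq_len(nrow(net$variables)), function(i)
      list(id = net$variables$id[i], kind = net$variables$kind[i])),
    relations = lapply(net$relations, function(rl)
      list(output = rl$output, op = rl$op,
           literals = lapply(seq_len(nrow(rl$literals)), function(i)
             list(id = rl$literals$id[i],
                  negated = rl$literals$negated[i])))),
    root_inputs = as.list(net$root_inputs))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
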