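# Independent oracles and generators used across the suite. These never call
# the code paths they check: the Boolean simulator works on logicals with
# all()/any(), the combinational evaluator is a fixpoint sweep, and the
# statistics oracles are direct enumerations / closed forms.

# assemble a Boolean network directly (for simulator tests that do not go
# through a pathway)
as_boolnet <- function(relations, extra_vars = character(0),
                       roots = character(0)) {
  ids <- sort(unique(c(unlist(lapply(relations, function(r)
    c(r$output, r$literals$id))), extra_vars)))
  structure(list(variables = data.frame(id = ids,
                                        kind = rep("entity", length(ids))),
                 relations = relations, root_inputs = roots),
            class = "fp_boolnet")
}

# pure two-state synchronous Boolean simulator (logical state)
boolean_oracle_step <- function(net, state) {
  new <- state
  outs <- vapply(net$relations, function(r) r$output, character(1))
  for (v in unique(outs)) {
    vals <- vapply(net$relations[outs == v], function(r) {
      lit <- state[r$literals$id]
      lit[r$literals$negated] <- !lit[r$literals$negated]
      switch(r$op, AND = all(lit), OR = any(lit), ASSIGN = lit[[1L]])
    }, logical(1))
    new[[v]] <- any(vals)
  }
  new
}

boolean_oracle_trace <- function(net, state, n_steps) {
  rows <- matrix(NA, nrow = n_steps + 1L, ncol = length(state),
                 dimnames = list(NULL, names(state)))
  rows[1L, ] <- state
  for (i in seq_len(n_steps)) {
    state <- boolean_oracle_step(net, state)
    rows[i + 1L, ] <- state
  }
  rows
}

# evaluate a relation list as a combinational circuit over a Boolean
# assignment of the base variables: sweep to fixpoint
eval_combinational <- function(relations, assignment) {
  vals <- as.list(assignment)
  for (pass in 1:10) {
    changed <- FALSE
    for (r in relations) {
      lit <- unlist(vals[r$literals$id])
      if (anyNA(lit) || is.null(lit) || length(lit) < nrow(r$literals)) next
      lit[r$literals$negated] <- !lit[r$literals$negated]
      v <- switch(r$op, AND = all(lit), OR = any(lit), ASSIGN = lit[[1L]])
      if (is.null(vals[[r$output]]) || !identical(vals[[r$output]], v)) {
        vals[[r$output]] <- v
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  vals
}

# direct truth value of a reaction: inputs AND catalysts AND (any activator,
# if any annotated) AND NOT (any inhibitor, if any annotated)
direct_reaction_value <- function(r, assignment) {
  v <- all(unlist(assignment[c(r$inputs, r$catalysts)]))
  if (length(r$activators)) v <- v && any(unlist(assignment[r$activators]))
  if (length(r$inhibitors)) v <- v && !any(unlist(assignment[r$inhibitors]))
  v
}

# random reaction with at most `max_vars` distinct base variables
random_reaction <- function(seed, max_vars = 12L) {
  set.seed(seed)
  repeat {
    sizes <- c(inputs = sample(1:3, 1), catalysts = sample(0:2, 1),
               activators = sample(0:3, 1), inhibitors = sample(0:3, 1),
               outputs = sample(1:3, 1))
    if (sum(sizes) <= max_vars) break
  }
  pool <- sprintf("v%02d", seq_len(sum(sizes)))
  idx <- 0L
  take <- function(n) {
    out <- pool[idx + seq_len(n)]
    idx <<- idx + n
    out
  }
  reaction(sprintf("rr%d", seed),
           inputs = take(sizes[["inputs"]]),
           catalysts = take(sizes[["catalysts"]]),
           activators = take(sizes[["activators"]]),
           inhibitors = take(sizes[["inhibitors"]]),
           outputs = take(sizes[["outputs"]]))
}

# enumerate all Boolean assignments of the reaction's base variables and
# check the compiled relations against the direct formula
check_reaction_truth_table <- function(r) {
  base <- unique(c(r$inputs, r$catalysts, r$activators, r$inhibitors))
  rels <- convert_reaction(r)$relations
  for (bits in 0:(2^length(base) - 1L)) {
    assignment <- as.list(stats::setNames(
      as.logical(bitwAnd(bits, 2^(seq_along(base) - 1L)) > 0), base))
    vals <- eval_combinational(rels, assignment)
    want <- direct_reaction_value(r, assignment)
    for (out in unique(r$outputs))
      if (!identical(vals[[out]], want)) return(FALSE)
  }
  TRUE
}

# random Boolean network over <= max_vars variables
random_boolnet <- function(seed, max_vars = 12L) {
  set.seed(seed)
  n <- sample(3:max_vars, 1)
  ids <- sprintf("x%02d", seq_len(n))
  rels <- list()
  for (v in ids) {
    if (stats::runif(1) < 0.3) next  # leave some variables relation-free
    for (k in seq_len(sample(1:2, 1))) {
      op <- sample(c("AND", "OR", "ASSIGN"), 1)
      nl <- if (op == "ASSIGN") 1L else sample(1:3, 1)
      lits <- data.frame(id = sample(ids, nl),
                         negated = if (op == "AND") stats::runif(nl) < 0.3
                                   else rep(FALSE, nl))
      rels[[length(rels) + 1L]] <- bool_relation(v, op, lits)
    }
  }
  if (length(rels) == 0L)
    rels <- list(bool_relation(ids[1L], "ASSIGN", ids[2L]))
  as_boolnet(rels, extra_vars = ids)
}

# closed-form BH step-up: p * m / rank, cumulative-minimum from the largest p
bh_closed_form <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# upper-tail binomial by direct enumeration
binom_tail_enum <- function(k, n, pr) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * pr^j * (1 - pr)^(n - j),
             numeric(1)))
}

# strip a trace down to its bare value matrix
trace_values <- function(tr) array(unclass(tr), dim = dim(tr))

# wrap a plain matrix as a trace (for attractor/expansion tests)
as_trace <- function(m, terminated_by = "iteration_cap", attractor = NULL) {
  dimnames(m) <- list(step = as.character(seq_len(nrow(m)) - 1L),
                      variable = colnames(m) %||% sprintf("v%d", seq_len(ncol(m))))
  structure(m, class = c("fp_trace", "matrix", "array"),
            terminated_by = terminated_by, attractor = attractor,
            config = sim_config())
}

`%||%` <- function(x, y) if (is.null(x)) y else x
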