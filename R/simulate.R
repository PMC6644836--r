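#' Transfer function specification
#'
#' Each variable's combined relation value is passed through a transfer
#' function before it becomes the next-step value. Two forms are supported:
#' `identity` (the default; used for all shipped examples) and a normalized
#' Hill function \eqn{f(x) = x^n (1 + k^n) / (x^n + k^n)}, which satisfies
#' f(0) = 0, f(1) = 1 and is monotone increasing on [0, 1].
#'
#' @param form `"identity"` or `"hill"`.
#' @param hill_n Hill exponent (> 0); ignored by `identity`. Default 3.
#' @param hill_k Half-maximal point in (0, 1]; ignored by `identity`.
#'   Default 0.5.
#' @return A list of class `fp_transfer`.
#' @export
transfer_spec <- function(form = c("identity", "hill"), hill_n = 3, hill_k = 0.5) {
  form <- match.arg(form)
  if (form == "hill") {
    if (!is.numeric(hill_n) || hill_n <= 0)
      usage_error("hill_n must be > 0")
    if (!is.numeric(hill_k) || hill_k <= 0 || hill_k > 1)
      usage_error("hill_k must be in (0, 1]")
  }
  structure(list(form = form, hill_n = hill_n, hill_k = hill_k),
            class = "fp_transfer")
}

apply_transfer <- function(v, tf) {
  if (is.null(tf) || tf$form == "identity") return(v)
  kn <- tf$hill_k^tf$hill_n
  xn <- v^tf$hill_n
  out <- xn * (1 + kn) / (xn + kn)
  min(max(out, 0), 1)
}

#' Simulation configuration
#'
#' Collects the stopping rules and numerical tolerances of the fuzzy
#' simulation. The iteration cap defaults to the larger of 100 and 1.2 times
#' the number of network variables (rounded up), applied when
#' `max_iterations` is left `NULL`.
#'
#' @param convergence_tol Maximum difference between two consecutive
#'   iterations below which the simulation stops as converged. Default 1e-6.
#' @param max_iterations Explicit iteration cap, or `NULL` for the
#'   max(100, ceiling(1.2 * |variables|)) rule.
#' @param expansion_step Number of time steps added per attractor-replay
#'   expansion block. Default 20.
#' @param expansion_tol Expansion stops once the monitored per-variable
#'   quantity changes by less than this between consecutive expansions.
#'   Default 0.01.
#' @param expansion_cap Maximum total trace length (time steps) reached by
#'   expansion. Default 1000.
#' @param initial_values Named numeric vector of initial values in [0, 1],
#'   overriding the defaults (1.0 for root inputs, 0.0 otherwise) for the
#'   named variables.
#' @return A list of class `fp_config`.
#' @export
sim_config <- function(convergence_tol = 1e-6, max_iterations = NULL,
                       expansion_step = 20L, expansion_tol = 0.01,
                       expansion_cap = 1000L, initial_values = NULL) {
  if (convergence_tol <= 0 || expansion_tol <= 0)
    usage_error("tolerances must be > 0")
  if (expansion_step < 1L || expansion_cap < 1L)
    usage_error("expansion_step and expansion_cap must be >= 1")
  if (!is.null(initial_values)) {
    if (is.null(names(initial_values)) || any(!nzchar(names(initial_values))))
      usage_error("initial_values must be a named vector")
    if (any(initial_values < 0 | initial_values > 1))
      usage_error("initial values must lie in [0, 1]")
  }
  structure(list(convergence_tol = convergence_tol,
                 max_iterations = max_iterations,
                 expansion_step = as.integer(expansion_step),
                 expansion_tol = expansion_tol,
                 expansion_cap = as.integer(expansion_cap),
                 initial_values = initial_values),
            class = "fp_config")
}

#' Default initial values for a network
#'
#' Root inputs (entities used by reactions that are never produced, or that
#' sit on a directed cycle of the reaction graph) start at 1.0; every other
#' variable, including accessories, starts at 0.0.
#'
#' @param net An `fp_boolnet`.
#' @return Named numeric vector over all network variables.
#' @export
default_initial_values <- function(net) {
  stopifnot(inherits(net, "fp_boolnet"))
  init <- stats::setNames(rep(0, nrow(net$variables)), net$variables$id)
  init[net$root_inputs] <- 1
  init
}

#' Evaluate one relation on a fuzzy state
#'
#' Gödel fuzzy semantics: AND is the minimum of the literal values, OR the
#' maximum, a negated literal contributes `1 - value`, and ASSIGN copies its
#' single literal. The combined value is then passed through the output
#' variable's transfer function.
#'
#' @param rl A [bool_relation()].
#' @param state Named numeric vector covering all literal ids.
#' @param transfer A [transfer_spec()] for the output variable, or `NULL`
#'   for identity.
#' @return A value in [0, 1].
#' @export
eval_relation <- function(rl, state, transfer = NULL) {
  vals <- state[rl$literals$id]
  if (anyNA(vals))
    runtime_error(paste0("state is missing variables: ",
                         paste(rl$literals$id[is.na(vals)], collapse = ", ")))
  vals <- ifelse(rl$literals$negated, 1 - vals, vals)
  combined <- switch(rl$op, AND = min(vals), OR = max(vals), ASSIGN = vals[[1L]])
  apply_transfer(combined, transfer)
}

# index: list output id -> list of relations
relation_index <- function(net) {
  idx <- split(net$relations,
               vapply(net$relations, function(rl) rl$output, character(1)))
  idx
}

# drug gating of a single value
gate_value <- function(v, mechanism, strength) {
  if (mechanism == "inhibition") v * (1 - strength) else v + strength * (1 - v)
}

#' Advance a fuzzy state by one synchronous step
#'
#' Every variable with at least one relation is updated to the OR (max) over
#' its relations' post-transfer values, computed from the previous state;
#' variables with no relation hold their value. Drug actions, if given, gate
#' their targets after the transfer: inhibition of strength s multiplies the
#' value by (1 - s), activation moves it to v + s(1 - v). A targeted variable
#' with no relation is clamped to the gated initial value instead (see the
#' methods vignette).
#'
#' @param net An `fp_boolnet`.
#' @param state Named numeric vector covering all variables.
#' @param transfers Named list of [transfer_spec()] per variable id
#'   (missing entries mean identity), or `NULL`.
#' @param actions List of [drug_action()] objects, or `NULL`.
#' @param init Initial values (used to clamp relation-less drug targets);
#'   defaults to `state`.
#' @param rel_idx Precomputed [relation_index] (internal speed-up).
#' @return The next state, a named numeric vector in [0, 1].
#' @export
sim_step <- function(net, state, transfers = NULL, actions = NULL,
                     init = state, rel_idx = relation_index(net)) {
  new <- state
  for (out in names(rel_idx)) {
    tf <- transfers[[out]]
    vals <- vapply(rel_idx[[out]], eval_relation, numeric(1),
                   state = state, transfer = tf)
    new[[out]] <- max(vals)
  }
  if (!is.null(actions)) {
    for (act in actions) {
      for (tgt in act$targets) {
        if (is.na(match(tgt, names(state))))
          runtime_error(sprintf("drug target '%s' is not a network variable", tgt))
        if (is.null(rel_idx[[tgt]]))
          new[[tgt]] <- gate_value(init[[tgt]], act$mechanism, act$strength)
        else
          new[[tgt]] <- gate_value(new[[tgt]], act$mechanism, act$strength)
      }
    }
  }
  new
}

#' Run a constrained fuzzy-logic simulation
#'
#' Synchronously iterates the network from its initial state until either
#' the maximum change between two consecutive iterations falls below
#' `convergence_tol`, or the iteration count reaches the larger of 100 and
#' 1.2 times the number of variables (unless overridden). The returned trace
#' stores one row per time step, starting with the initial state at step 0,
#' and is annotated with the detected attractor when one exists.
#'
#' @param net An `fp_boolnet`.
#' @param config A [sim_config()].
#' @param transfers Named list of [transfer_spec()] per variable, or `NULL`
#'   (identity everywhere).
#' @param actions List of [drug_action()] perturbations, or `NULL` for a
#'   reference run.
#' @return An `fp_trace`: a numeric matrix (rows = time steps, columns =
#'   variables) with attributes `terminated_by` (`"converged"` or
#'   `"iteration_cap"`) and `attractor` (list with 0-based `start` and
#'   `period`, or `NULL`).
#' @export
simulate_network <- function(net, config = sim_config(), transfers = NULL,
                             actions = NULL) {
  stopifnot(inherits(net, "fp_boolnet"), inherits(config, "fp_config"))
  vars <- net$variables$id
  init <- default_initial_values(net)
  if (!is.null(config$initial_values)) {
    unknown <- setdiff(names(config$initial_values), vars)
    if (length(unknown))
      usage_error(paste0("initial_values name unknown variables: ",
                         paste(unknown, collapse = ", ")))
    init[names(config$initial_values)] <- config$initial_values
  }
  maxit <- config$max_iterations %||% max(100L, as.integer(ceiling(1.2 * length(vars))))
  rel_idx <- relation_index(net)

  rows <- vector("list", maxit + 1L)
  rows[[1L]] <- init
  state <- init
  terminated <- "iteration_cap"
  n_rows <- 1L
  for (it in seq_len(maxit)) {
    nxt <- sim_step(net, state, transfers = transfers, actions = actions,
                    init = init, rel_idx = rel_idx)
    n_rows <- n_rows + 1L
    rows[[n_rows]] <- nxt
    if (max(abs(nxt - state)) < config$convergence_tol) {
      terminated <- "converged"
      break
    }
    state <- nxt
  }
  m <- do.call(rbind, rows[seq_len(n_rows)])
  dimnames(m) <- list(step = as.character(seq_len(n_rows) - 1L), variable = vars)
  tr <- structure(m, class = c("fp_trace", "matrix", "array"),
                  terminated_by = terminated, attractor = NULL,
                  config = config)
  att <- detect_attractor(tr)
  if (is.null(att) && terminated == "converged")
    att <- list(start = n_rows - 1L, period = 1L)  # numerically converged tail
  attr(tr, "attractor") <- att
  tr
}

#' Detect the attractor of a trace
#'
#' Finds the smallest period p and the earliest start s such that the trace's
#' rows repeat with period p (within `tol` in the max norm) from s to the end,
#' requiring at least two full periods of evidence in the tail. A converged
#' trace yields period 1 (a fixed point); returns `NULL` when no repetition
#' is found.
#'
#' @param trace An `fp_trace` (or plain matrix) with at least 2 rows.
#' @param tol Row-matching tolerance. Default 1e-9 (below the convergence
#'   tolerance, above float noise).
#' @return `list(start =, period =)` with a 0-based start step, or `NULL`.
#' @export
detect_attractor <- function(trace, tol = 1e-9) {
  m <- unclass(trace)
  n <- nrow(m)
  if (is.null(n) || n < 2L) usage_error("trace must have at least 2 rows")
  for (p in seq_len(n %/% 2L)) {
    tail_ok <- max(abs(m[(n - p + 1L):n, , drop = FALSE] -
                       m[(n - 2L * p + 1L):(n - p), , drop = FALSE])) <= tol
    if (!tail_ok) next
    s <- n - 2L * p + 1L
    while (s > 1L &&
           max(abs(m[s - 1L, ] - m[s - 1L + p, ])) <= tol) s <- s - 1L
    return(list(start = s - 1L, period = p))
  }
  NULL
}

# extend a trace to `target` total rows by replaying its attractor cycle
replay_to <- function(trace, target) {
  att <- attr(trace, "attractor")
  if (is.null(att))
    runtime_error("no attractor detected; raise the iteration cap and re-simulate")
  m <- unclass(trace)
  n <- nrow(m)
  if (target <= n) return(trace)
  s <- att$start + 1L  # 1-based
  p <- att$period
  idx <- s + ((n + seq_len(target - n) - 1L) - (s - 1L) ) %% p
  ext <- m[idx, , drop = FALSE]
  out <- rbind(m, ext)
  dimnames(out) <- list(step = as.character(seq_len(target) - 1L),
                        variable = colnames(m))
  structure(out, class = class(trace),
            terminated_by = attr(trace, "terminated_by"),
            attractor = att, config = attr(trace, "config"))
}

#' Expand a trace along its attractor
#'
#' Replays the detected attractor cycle in blocks of `expansion_step` time
#' steps. After each block the per-variable monitored quantity is compared
#' with its value after the previous block; expansion stops when the maximum
#' absolute change drops below `expansion_tol`, or when the total trace
#' length reaches `expansion_cap`. With a `reference` trace (the
#' drug-perturbation case) the monitored quantity is the per-variable
#' relative impact score of `trace` against `reference`, and the reference is
#' expanded in lockstep; without one it is the per-variable mean fuzzy value.
#'
#' @param trace An `fp_trace` with a detected attractor.
#' @param config A [sim_config()].
#' @param reference Optional reference `fp_trace` (same variables), expanded
#'   in lockstep.
#' @return The expanded `fp_trace`; when `reference` is given, a list with
#'   elements `trace`, `reference` and `scores` (see [relative_impact()]).
#' @export
expand_trace <- function(trace, config = sim_config(), reference = NULL) {
  stopifnot(inherits(trace, "fp_trace"))
  if (is.null(attr(trace, "attractor")))
    runtime_error("no attractor detected; raise the iteration cap and re-simulate")
  cap <- config$expansion_cap
  step <- config$expansion_step

  if (is.null(reference)) {
    quantity <- function(tr) colMeans(unclass(tr))
    cur <- trace
    prev_q <- quantity(cur)
    repeat {
      n <- nrow(cur)
      if (n >= cap) break
      cur <- replay_to(cur, min(n + step, cap))
      q <- quantity(cur)
      if (max(abs(q - prev_q)) < config$expansion_tol) break
      prev_q <- q
    }
    return(cur)
  }

  stopifnot(inherits(reference, "fp_trace"))
  if (is.null(attr(reference, "attractor")))
    runtime_error("no attractor detected in reference; raise the iteration cap")
  if (!identical(colnames(trace), colnames(reference)))
    usage_error("trace and reference cover different variables")

  len <- min(max(nrow(trace), nrow(reference)), cap)
  cur <- replay_to(trace, len)
  ref <- replay_to(reference, len)
  prev_s <- relative_impact(ref, cur)$score
  repeat {
    if (len >= cap) break
    len <- min(len + step, cap)
    cur <- replay_to(cur, len)
    ref <- replay_to(ref, len)
    s <- relative_impact(ref, cur)$score
    if (max(abs(s - prev_s)) < config$expansion_tol) break
    prev_s <- s
  }
  list(trace = cur, reference = ref, scores = relative_impact(ref, cur))
}

#' Export a trace as TSV
#'
#' Writes a `step` column followed by one column per variable, one row per
#' time step, suitable for external plotting.
#'
#' @param trace An `fp_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fp_trace"))
  df <- data.frame(step = seq_len(nrow(trace)) - 1L, unclass(trace),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Values of one variable over a single attractor period
#'
#' @param trace An `fp_trace` with a detected attractor.
#' @param variable Variable id.
#' @return Numeric vector of length `period`, starting at the attractor's
#'   start step.
#' @export
attractor_cycle <- function(trace, variable) {
  att <- attr(trace, "attractor")
  if (is.null(att)) runtime_error("trace has no detected attractor")
  if (!variable %in% colnames(trace))
    usage_error(sprintf("unknown variable '%s'", variable))
  m <- unclass(trace)
  m[att$start + seq_len(att$period), variable]
}

#' @export
print.fp_trace <- function(x, ...) {
  att <- attr(x, "attractor")
  cat(sprintf("<fuzzy trace: %d steps x %d variables, %s%s>\n",
              nrow(x), ncol(x), attr(x, "terminated_by"),
              if (is.null(att)) ", no attractor"
              else sprintf(", attractor period %d from step %d",
                           att$period, att$start)))
  invisible(x)
}
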