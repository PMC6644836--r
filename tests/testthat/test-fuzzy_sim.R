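test_that("relation evaluation follows min/max/complement semantics", {
  st <- c(a = 0.7, b = 0.4, c = 1.0)
  expect_equal(eval_relation(bool_relation("o", "AND", c("c", "c")), st), 1.0)
  expect_equal(eval_relation(
    bool_relation("o", "AND",
                  data.frame(id = c("a", "c"), negated = c(FALSE, TRUE))), st),
    0.0)
  expect_equal(eval_relation(bool_relation("o", "AND", c("a", "b")), st), 0.4)
  expect_equal(eval_relation(bool_relation("o", "OR", c("a", "b")), st), 0.7)
  expect_equal(eval_relation(bool_relation("o", "ASSIGN", "b"), st), 0.4)
  expect_error(eval_relation(bool_relation("o", "ASSIGN", "zz"), st),
               "zz", class = "fuzzypath_runtime_error")

  # {0,1} corners agree with Boolean logic
  for (bits in 0:3) {
    st2 <- c(a = bitwAnd(bits, 1) > 0, b = bitwAnd(bits, 2) > 0) + 0
    expect_equal(eval_relation(bool_relation("o", "AND", c("a", "b")), st2),
                 as.numeric(st2[["a"]] && st2[["b"]]))
    expect_equal(eval_relation(bool_relation("o", "OR", c("a", "b")), st2),
                 as.numeric(st2[["a"]] || st2[["b"]]))
  }
})

test_that("the normalized Hill transfer is anchored and monotone", {
  tf <- transfer_spec("hill", hill_n = 3, hill_k = 0.5)
  f <- function(x) vapply(x, fuzzypath:::apply_transfer, numeric(1), tf = tf)
  expect_equal(f(0), 0)
  expect_equal(f(1), 1)
  xs <- seq(0, 1, length.out = 200)
  expect_true(all(diff(f(xs)) >= 0))
  expect_true(all(f(xs) >= 0 & f(xs) <= 1))
  expect_error(transfer_spec("hill", hill_n = -1),
               class = "fuzzypath_usage_error")
})

test_that("a synchronous step updates driven variables and holds the rest", {
  net <- as_boolnet(list(), extra_vars = c("a", "b"))
  st <- c(a = 0.3, b = 0.9)
  expect_identical(sim_step(net, st), st)

  net <- as_boolnet(list(bool_relation("b", "ASSIGN", "a")))
  expect_equal(sim_step(net, c(a = 1, b = 0))[["b"]], 1)
})

test_that("restriction to {0,1} states reproduces pure Boolean dynamics", {
  for (seed in 1:30) {
    net <- random_boolnet(seed)
    set.seed(seed + 1000)
    init <- stats::setNames(sample(0:1, nrow(net$variables), replace = TRUE),
                            net$variables$id)
    cfg <- sim_config(initial_values = init, max_iterations = 25L)
    tr <- simulate_network(net, cfg)
    oracle <- boolean_oracle_trace(net, init > 0, nrow(tr) - 1L)
    expect_equal(trace_values(tr), unname(oracle + 0))
  }
})

test_that("fuzzy values stay within [0,1] from arbitrary initial states", {
  for (seed in 31:45) {
    net <- random_boolnet(seed)
    set.seed(seed)
    init <- stats::setNames(stats::runif(nrow(net$variables)),
                            net$variables$id)
    tr <- simulate_network(net, sim_config(initial_values = init,
                                           max_iterations = 30L))
    expect_true(all(tr >= 0 & tr <= 1))
  }
})

test_that("simulation is deterministic", {
  net <- build_network(make_feedback_loop_pathway(3))
  t1 <- simulate_network(net)
  t2 <- simulate_network(net)
  expect_identical(t1, t2)
})

test_that("stopping rules are honored", {
  # constant network: converges after one comparison -> 2 rows
  net <- as_boolnet(list(), extra_vars = c("a", "b"))
  tr <- simulate_network(net)
  expect_identical(nrow(tr), 2L)
  expect_identical(attr(tr, "terminated_by"), "converged")
  expect_lt(max(abs(tr[2, ] - tr[1, ])), 1e-6)

  # 3-variable rotation never converges: cap = max(100, ceil(1.2*3)) = 100
  rot <- as_boolnet(list(bool_relation("b", "ASSIGN", "a"),
                         bool_relation("c", "ASSIGN", "b"),
                         bool_relation("a", "ASSIGN", "c")))
  tr <- simulate_network(rot, sim_config(initial_values = c(a = 1, b = 0, c = 0)))
  expect_identical(attr(tr, "terminated_by"), "iteration_cap")
  expect_identical(nrow(tr), 101L)
  # period-3 rotation from the start
  expect_identical(attr(tr, "attractor"), list(start = 0L, period = 3L))

  # above 84 variables the 1.2*|V| arm takes over: 90 vars -> 108 iterations
  ids <- sprintf("n%03d", 1:90)
  rels <- lapply(1:90, function(i)
    bool_relation(ids[i %% 90 + 1L], "ASSIGN", ids[i]))
  big <- as_boolnet(rels)
  init <- stats::setNames(c(1, rep(0, 89)), sort(ids))
  tr <- simulate_network(big, sim_config(initial_values = init))
  expect_identical(nrow(tr), as.integer(ceiling(1.2 * 90)) + 1L)
})

test_that("attractor detection finds the smallest period and earliest start", {
  set.seed(42)
  # fixed point
  m <- rbind(c(0.2, 0.8), c(0.5, 0.8), c(0.5, 0.8), c(0.5, 0.8))
  expect_identical(detect_attractor(as_trace(m)), list(start = 1L, period = 1L))

  # 6-row cycle after a transient, repeated twice in the tail
  cyc <- matrix(stats::runif(12), nrow = 6)
  m <- rbind(matrix(stats::runif(6), nrow = 3), cyc, cyc)
  expect_identical(detect_attractor(as_trace(m)), list(start = 3L, period = 6L))

  # strictly monotone trace has no attractor
  m <- cbind(seq(0, 1, length.out = 8), seq(1, 0, length.out = 8))
  expect_null(detect_attractor(as_trace(m)))

  expect_error(detect_attractor(as_trace(m[1, , drop = FALSE])),
               class = "fuzzypath_usage_error")
})

test_that("the loop pathway reaches a periodic attractor", {
  net <- build_network(make_feedback_loop_pathway(4))
  tr <- simulate_network(net)
  att <- attr(tr, "attractor")
  expect_false(is.null(att))
  expect_gt(att$period, 1L)
  cyc <- attractor_cycle(tr, "output_complex")
  expect_true(min(cyc) == 0 && max(cyc) == 1)  # full-range oscillation
})

test_that("expansion replays the attractor in blocks and stops on stability", {
  # fixed point: first comparison already stable, one block appended
  m <- rbind(c(0.3, 0.6), c(0.3, 0.6))
  tr <- as_trace(m, "converged", attractor = list(start = 1L, period = 1L))
  ex <- expand_trace(tr, sim_config())
  expect_identical(nrow(ex), 22L)  # 2 rows + one 20-step block
  expect_true(all(ex[, 1] == 0.3 & ex[, 2] == 0.6))

  # a cycling trace driven to the cap with an unreachable tolerance
  cyc <- matrix(rep(c(0, 1, 1, 0.5, 0.2, 0.9), 4), ncol = 2)
  tr <- as_trace(rbind(cyc, cyc), attractor = list(start = 0L, period = 6L))
  cfg <- sim_config(expansion_tol = 1e-15, expansion_cap = 100L)
  ex <- expand_trace(tr, cfg)
  expect_identical(nrow(ex), 100L)
  # replay really is the cycle, continued
  expect_equal(unname(ex[25:30, ]), unname(cyc[1:6, ] ))

  # no attractor -> instructive error
  mono <- as_trace(cbind(seq(0, 1, length.out = 5)))
  expect_error(expand_trace(mono), "iteration cap",
               class = "fuzzypath_runtime_error")
})

test_that("lockstep expansion yields equal-length traces and stable scores", {
  net <- build_network(make_feedback_loop_pathway(4))
  cfg <- sim_config(initial_values = c(modulator = 0.5))
  ref <- simulate_network(net, cfg)
  per <- simulate_network(net, cfg,
                          actions = list(drug_action("d", "kinase",
                                                     "inhibition", 0.95)))
  ex <- expand_trace(per, cfg, reference = ref)
  expect_identical(nrow(ex$trace), nrow(ex$reference))
  expect_true(all(abs(ex$scores$score) <= 1))
})

test_that("trace TSV export has a step column and one column per variable", {
  net <- build_network(make_feedback_loop_pathway(2))
  tr <- simulate_network(net)
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  df <- utils::read.delim(f, check.names = FALSE)
  expect_identical(nrow(df), nrow(tr))
  expect_identical(names(df), c("step", colnames(tr)))
  expect_identical(df$step, seq_len(nrow(tr)) - 1L)
})
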