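test_that("the affinity-to-strength map hits its branch values", {
  expect_equal(strength_from_assay(0.5), 0.999)
  expect_equal(strength_from_assay(5), 0.99)
  expect_equal(strength_from_assay(16), 0.99 - 0.196 * (log10(16) - 1))
  expect_equal(strength_from_assay(1e6), 0)
  expect_equal(strength_from_assay(1e7), 0)
  expect_error(strength_from_assay(0), class = "fuzzypath_usage_error")
  expect_error(strength_from_assay(-3), class = "fuzzypath_usage_error")
})

test_that("the strength map is continuous at 10 nM and non-increasing", {
  eps <- 1e-9
  expect_lt(abs(strength_from_assay(10 - eps) - strength_from_assay(10 + eps)),
            1e-6)
  expect_equal(strength_from_assay(10), 0.99)  # log10(10) = 1 anchors branch 3
  grid <- 10^seq(log10(0.1), log10(1e7), length.out = 10000)
  s <- strength_from_assay(grid)
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 0.999))
})

test_that("min_assay takes the minimum across assay types", {
  tbl <- data.frame(drug = c("d1", "d1", "d1", "d2"),
                    target = c("KIT", "KIT", "RET", "KIT"),
                    assay_type = c("KD", "IC50", "KD", "Ki"),
                    assay_value_nM = c(16, 40, 3, 7))
  expect_equal(min_assay(tbl, "d1", "KIT"), 16)
  expect_equal(min_assay(tbl, "d2", "KIT"), 7)
  expect_null(min_assay(tbl, "d3", "KIT"))
})

test_that("drug gating composes with the dynamics as multiplicative/saturating", {
  # b is driven to 1 through "a = b"; inhibition leaves (1-s) of the drive
  net <- as_boolnet(list(bool_relation("b", "ASSIGN", "a")), roots = "a")
  ref <- simulate_network(net)
  expect_equal(unname(ref[nrow(ref), "b"]), 1)

  inh <- simulate_network(net, actions = list(
    drug_action("d", "b", "inhibition", 0.999)))
  expect_equal(unname(inh[nrow(inh), "b"]), 0.001)

  # zero-strength drug leaves the dynamics untouched
  z <- simulate_network(net, actions = list(
    drug_action("d", "b", "inhibition", 0)))
  expect_identical(unclass(z), unclass(ref))

  # activation lifts a variable receiving zero drive to s
  net0 <- as_boolnet(list(bool_relation("b", "ASSIGN", "a")))  # a holds 0
  act <- simulate_network(net0, actions = list(
    drug_action("d", "b", "activation", 0.99)))
  expect_equal(unname(act[nrow(act), "b"]), 0.99)

  # a relation-less target is clamped to its gated initial value
  hold <- simulate_network(net, actions = list(
    drug_action("d", "a", "inhibition", 0.95)))
  expect_equal(unname(hold[nrow(hold), "a"]), 0.05)
  expect_equal(unname(hold[1, "a"]), 1)  # step 0 is the unperturbed state

  expect_error(
    simulate_network(net, actions = list(
      drug_action("d", "ghost", "inhibition", 0.5))),
    "ghost", class = "fuzzypath_runtime_error")
})

test_that("apply_drug returns gated transfer closures for the targets", {
  net <- as_boolnet(list(bool_relation("b", "ASSIGN", "a")))
  tfs <- apply_drug(net, NULL, drug_action("d", "b", "inhibition", 0.9))
  expect_equal(tfs[["b"]](1), 0.1)
  expect_equal(tfs[["a"]](0.7), 0.7)
  expect_error(apply_drug(net, NULL, drug_action("d", "zz", "inhibition", 0.5)),
               class = "fuzzypath_runtime_error")
})

test_that("relative impact scores follow the AUC formula", {
  m1 <- as_trace(cbind(a = c(0, 0, 0), b = c(0.5, 0.5, 0.5)))
  m2 <- as_trace(cbind(a = c(0.2, 0.4, 0.4), b = c(0.5, 0.5, 0.5)))
  sc <- relative_impact(m1, m2)
  expect_equal(sc$score[sc$variable == "a"], 1)   # reference AUC is zero
  expect_equal(sc$score[sc$variable == "b"], 0)   # identical columns
  expect_equal(sc$reference_auc[sc$variable == "b"], 1.5)
  expect_equal(sc$perturbation_auc[sc$variable == "a"], 1.0)

  expect_equal(relative_impact(m1, m1)$score, c(0, 0))

  expect_error(relative_impact(m1, as_trace(cbind(a = 1:2 / 2, b = 1:2 / 2))),
               class = "fuzzypath_usage_error")
  expect_error(relative_impact(m1, as_trace(cbind(x = c(0, 0, 0), b = c(1, 1, 1)))),
               class = "fuzzypath_usage_error")
})

test_that("impact scores are bounded and antisymmetric on random trace pairs", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:12, 1); k <- sample(1:4, 1)
    a <- as_trace(matrix(stats::runif(n * k), nrow = n,
                         dimnames = list(NULL, sprintf("v%d", 1:k))))
    b <- as_trace(matrix(stats::runif(n * k), nrow = n,
                         dimnames = list(NULL, sprintf("v%d", 1:k))))
    s1 <- relative_impact(a, b)$score
    s2 <- relative_impact(b, a)$score
    expect_true(all(abs(s1) <= 1))
    expect_equal(s1, -s2)
  }
})

test_that("a perturbation study reproduces the loop-collapse direction", {
  pw <- make_feedback_loop_pathway(4)
  tbl <- data.frame(drug = "kinase_inhibitor", target = "kinase",
                    assay_type = "KD", assay_value_nM = 16,
                    source = "fixture", pubmed_id = "PMID:1")
  cfg <- sim_config(initial_values = c(modulator = 0.5))
  study <- run_perturbation_study(pw, tbl, "kinase_inhibitor", config = cfg)

  ref_min <- min(attractor_cycle(study$reference, "output_complex"))
  per_min <- min(attractor_cycle(study$perturbed, "output_complex"))
  expect_lt(per_min, ref_min)  # the drug collapses the oscillation floor
  expect_lt(study$scores$score[study$scores$variable == "output_complex"], 0)
  expect_identical(nrow(study$reference), nrow(study$perturbed))
})

test_that("a strength-zero drug scores zero everywhere", {
  pw <- make_feedback_loop_pathway(3)
  tbl <- data.frame(drug = "inert", target = "kinase",
                    assay_type = "KD", assay_value_nM = 1e6,
                    source = "fixture", pubmed_id = "PMID:2")
  study <- run_perturbation_study(pw, tbl, "inert")
  expect_equal(study$scores$score, rep(0, nrow(study$scores)))
})

test_that("reducing a root input's initial value changes the attractor", {
  net <- build_network(make_feedback_loop_pathway(4))
  t1 <- simulate_network(net)
  t2 <- simulate_network(net, sim_config(initial_values = c(modulator = 0.5)))
  c1 <- attractor_cycle(t1, "output_complex")
  c2 <- attractor_cycle(t2, "output_complex")
  expect_gt(min(c2), min(c1))  # weaker feedback raises the oscillation floor
})

test_that("missing drugs and unresolvable targets are reported", {
  pw <- make_feedback_loop_pathway(2)
  tbl <- data.frame(drug = "d", target = "NOT_IN_PATHWAY",
                    assay_type = "KD", assay_value_nM = 10,
                    source = "s", pubmed_id = "p")
  expect_error(run_perturbation_study(pw, tbl, "absent"),
               class = "fuzzypath_usage_error")
  expect_error(run_perturbation_study(pw, tbl, "d"),
               class = "fuzzypath_runtime_error")
})

test_that("score export writes the four documented columns", {
  m1 <- as_trace(cbind(a = c(0, 1), b = c(1, 1)))
  m2 <- as_trace(cbind(a = c(1, 1), b = c(1, 1)))
  f <- tempfile(fileext = ".tsv")
  write_scores(relative_impact(m1, m2), f)
  df <- utils::read.delim(f)
  expect_identical(names(df),
                   c("variable", "reference_auc", "perturbation_auc", "score"))
  expect_equal(df$score[df$variable == "a"], 1 / 3)
})
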