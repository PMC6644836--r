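test_that("the canonical reaction compiles to exactly the five expected relations", {
  net <- build_network(make_typical_reaction())
  lines <- sort(vapply(net$relations, fuzzypath:::format_relation, character(1)))
  expect_identical(lines, sort(c(
    "input1 · input2 · catalyst · rxn1__activator_acc · !rxn1__inhibitor_acc = rxn1__output_acc",
    "activator1 + activator2 = rxn1__activator_acc",
    "inhibitor1 + inhibitor2 = rxn1__inhibitor_acc",
    "rxn1__output_acc = output1",
    "rxn1__output_acc = output2")))
})

test_that("degenerate roles compile without accessory variables", {
  conv <- convert_reaction(reaction("r", inputs = "a", outputs = "b"))
  expect_length(conv$relations, 1L)
  rl <- conv$relations[[1L]]
  expect_identical(rl$op, "ASSIGN")
  expect_identical(rl$output, "b")
  expect_identical(rl$literals$id, "a")
  expect_identical(nrow(conv$accessories), 0L)

  # single activator / inhibitor are wired directly into the AND
  conv <- convert_reaction(reaction("r", inputs = "a", outputs = "b",
                                    activators = "act", inhibitors = "inh"))
  expect_length(conv$relations, 1L)
  rl <- conv$relations[[1L]]
  expect_identical(rl$op, "AND")
  expect_setequal(rl$literals$id, c("a", "act", "inh"))
  expect_identical(rl$literals$negated[rl$literals$id == "inh"], TRUE)
  expect_identical(rl$literals$negated[rl$literals$id == "act"], FALSE)
})

test_that("single-inhibitor compilation matches the direct formula on all assignments", {
  r <- reaction("r", inputs = c("i1", "i2"), outputs = "o", inhibitors = "inh")
  expect_true(check_reaction_truth_table(r))
})

test_that("complexes expand to AND, entity sets to OR, singletons to ASSIGN", {
  cx <- entity("cx", entity_class = "complex", components = c("s1", "s2", "s3"))
  rl <- expand_complex(cx)
  expect_identical(rl$op, "AND")
  expect_identical(rl$literals$id, c("s1", "s2", "s3"))
  expect_false(any(rl$literals$negated))

  one <- entity("c1", entity_class = "complex", components = "s1")
  expect_identical(expand_complex(one)$op, "ASSIGN")

  es <- entity("es", entity_class = "entity_set",
               components = c("m1", "m2", "m3"))
  rl <- expand_entity_set(es)
  expect_identical(rl$op, "OR")
  expect_identical(rl$literals$id, c("m1", "m2", "m3"))

  es1 <- entity("e1", entity_class = "entity_set", components = "m1")
  expect_identical(expand_entity_set(es1)$op, "ASSIGN")

  expect_error(expand_complex(es), class = "fuzzypath_usage_error")
})

test_that("nested containers evaluate like their flat enumeration", {
  # outer complex contains an inner complex and an entity set
  pw <- pathway("nest", entities = list(
    entity("a"), entity("b"), entity("c"), entity("d"),
    entity("inner", entity_class = "complex", components = c("a", "b")),
    entity("set1", entity_class = "entity_set", components = c("c", "d")),
    entity("outer", entity_class = "complex",
           components = c("inner", "set1"))))
  net <- build_network(pw)
  base <- c("a", "b", "c", "d")
  for (bits in 0:15) {
    assignment <- as.list(stats::setNames(
      as.logical(bitwAnd(bits, 2^(0:3)) > 0), base))
    vals <- eval_combinational(net$relations, assignment)
    want_inner <- assignment$a && assignment$b
    want_set <- assignment$c || assignment$d
    expect_identical(vals$inner, want_inner)
    expect_identical(vals$set1, want_set)
    expect_identical(vals$outer, want_inner && want_set)
  }
})

test_that("build_network computes root inputs from usage and cycles", {
  net <- build_network(make_typical_reaction())
  expect_setequal(net$root_inputs,
                  c("input1", "input2", "catalyst", "activator1", "activator2",
                    "inhibitor1", "inhibitor2"))

  empty <- build_network(pathway("e", entities = list(entity("a"))))
  expect_length(empty$relations, 0L)

  # loop fixture: upstream entities are roots, loop members are cycle inputs
  net <- build_network(make_feedback_loop_pathway(4))
  expect_true(all(c("ligand", "kinase", "modulator") %in% net$root_inputs))
  expect_true(all(sprintf("loop_%d", 1:4) %in% net$root_inputs))
  # the regenerated entry is an output yet still a root via the cycle rule
  expect_true("loop_1" %in% net$root_inputs)
})

test_that("compilation is deterministic", {
  f1 <- tempfile(); f2 <- tempfile()
  write_network_json(build_network(make_feedback_loop_pathway(4)), f1)
  write_network_json(build_network(make_feedback_loop_pathway(4)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("variable count equals entities plus multi-member-role accessories", {
  for (seed in 1:25) {
    r <- random_reaction(seed)
    ids <- unique(c(r$inputs, r$catalysts, r$activators, r$inhibitors,
                    r$outputs))
    pw <- pathway(sprintf("p%d", seed),
                  entities = lapply(ids, entity), reactions = list(r))
    net <- build_network(pw)
    want <- length(ids) +
      (length(unique(r$outputs)) >= 2) +
      (length(unique(r$activators)) >= 2) +
      (length(unique(r$inhibitors)) >= 2)
    expect_identical(nrow(net$variables), as.integer(want))
  }
})

test_that("compiled relations reproduce the direct reaction formula", {
  for (seed in 1:30)
    expect_true(check_reaction_truth_table(random_reaction(seed)))
})
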