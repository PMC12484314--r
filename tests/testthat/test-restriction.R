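test_that("restriction to the full leaf set is the identity up to equivalence", {
  for (net in c(enumerate_networks(3, 1)[seq(1, 21, by = 4)],
                list(fx_bare_gall(), fx_two_cycles()))) {
    expect_true(is_equivalent(restrict_network(net, unname(net$labels)), net))
  }
})

test_that("hand-traced restrictions collapse as expected", {
  # bare gall to {1}: the two in-edges of the reticulation merge and the
  # whole scaffold cascades down to root -> leaf
  sub <- restrict_network(fx_bare_gall(), 1)
  st <- network_stats(sub)
  expect_equal(st$n_vertices, 2L)
  expect_equal(st$n_reticulations, 0L)
  expect_equal(unname(sub$labels), 1L)

  # normal gall restricted to reticulation child + one side leaf develops a
  # shortcut, so it leaves the normal class
  sub <- restrict_network(fx_normal_gall(), c(1, 2))
  cls <- classify_network(sub)
  expect_false(cls[["normal"]])
  expect_false(is.null(has_shortcut(sub)))
  expect_true(cls[["tree_child"]])

  expect_error(restrict_network(fx_bare_gall(), integer(0)), "empty")
  expect_error(restrict_network(fx_bare_gall(), 9), "unknown")
})

test_that("restriction composes and never increases r or height", {
  pool <- c(enumerate_networks(3, 1), enumerate_networks(3, 2)[seq(1, 270, 15)])
  for (net in pool) {
    st <- network_stats(net)
    labs <- sort(unname(net$labels))
    for (Y in list(labs, labs[-1], labs[1])) {
      sub <- restrict_network(net, Y)
      stY <- network_stats(sub)
      expect_lte(stY$n_reticulations, st$n_reticulations)
      expect_lte(stY$height, st$height)
      for (Z in list(Y, Y[1])) {
        expect_true(is_equivalent(restrict_network(sub, Z),
                                  restrict_network(net, Z)))
      }
    }
  }
})

test_that("closure counterexamples exist exactly where the lemmas say", {
  # tree-child network with a reticulation inside another's cycle: a
  # single-leaf witness exists
  tc <- class_spec("tree-child")
  w <- closure_counterexample(tc, fx_two_cycles())
  expect_false(is.null(w))
  expect_length(w$leaf_subset, 1L)
  expect_false(classify_network(w$restricted)[["tree_child"]])

  # any galled tree is stable for the tree-child class
  gt <- class_spec("galled-tree")
  expect_null(closure_counterexample(tc, fx_bare_gall()))
  expect_null(closure_counterexample(gt, fx_bare_gall()))

  # trees never yield witnesses for any class
  tre <- read_enewick("((1,2),(3,4));")
  for (cl in network_classes()) {
    expect_null(closure_counterexample(class_spec(cl), tre))
  }

  # normal networks with a reticulation always yield a witness
  nm <- class_spec("normal")
  w <- closure_counterexample(nm, fx_normal_gall())
  expect_false(is.null(w))
  expect_false(classify_network(w$restricted)[["normal"]])

  expect_error(closure_counterexample(nm, fx_triangle()), "not in class")
})

test_that("maximal-closed membership matches the known characterizations", {
  tc <- class_spec("tree-child")
  nm <- class_spec("normal")
  expect_true(in_maximal_closed(tc, fx_bare_gall()))
  expect_false(in_maximal_closed(tc, fx_two_cycles()))
  expect_false(in_maximal_closed(nm, fx_normal_gall()))
  expect_true(in_maximal_closed(nm, read_enewick("((1,2),3);")))
  expect_error(in_maximal_closed(tc, fx_bare_gall(), guard = 2), "guard")
})

test_that("closure census agrees with predictions at n <= 3", {
  res <- closure_census(class_spec("tree-child"), n_max = 3, r_max = 1)
  expect_true(res$agreement)
  res <- closure_census(class_spec("normal"), n_max = 3, r_max = 1)
  expect_true(res$agreement)
  res <- closure_census(class_spec("galled-network"), n_max = 3, r_max = 1)
  expect_true(res$agreement)
  expect_true(all(res$in_maximal))
  expect_error(closure_census(class_spec("tree"), n_max = 9), "guard")
})
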