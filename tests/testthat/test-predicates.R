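test_that("reticulation cycles are enumerated per bottom reticulation", {
  expect_length(reticulation_cycles(read_enewick("((1,2),3);")), 0L)

  cyc <- reticulation_cycles(fx_bare_gall())
  expect_length(cyc, 1L)
  expect_identical(cyc[[1]]$top, "t")
  expect_identical(cyc[[1]]$bottom, "r")
  # internal vertices of the two paths are disjoint
  int_a <- setdiff(cyc[[1]]$path_a, c("t", "r"))
  int_b <- setdiff(cyc[[1]]$path_b, c("t", "r"))
  expect_length(intersect(int_a, int_b), 0L)

  # engineered fixture: bottom reticulation r2 has two cycles (tops t1, t0)
  cyc2 <- reticulation_cycles(fx_two_cycles())
  bottoms <- vapply(cyc2, function(cy) cy$bottom, character(1))
  expect_equal(sum(bottoms == "r2"), 2L)
  expect_equal(sum(bottoms == "r1"), 1L)
  expect_setequal(vapply(cyc2[bottoms == "r2"], function(cy) cy$top,
                         character(1)), c("t0", "t1"))
})

test_that("shortcut detection finds exactly the redundant edges", {
  expect_null(has_shortcut(read_enewick("((1,2),3);")))
  expect_null(has_shortcut(fx_bare_gall()))
  sc <- has_shortcut(fx_triangle())
  expect_identical(sc, c("a", "r"))
})

test_that("classification matches hand-checked fixtures", {
  for (tre in enumerate_trees(1:3)) {
    expect_true(all(classify_network(tre)))  # trees are in all seven classes
  }

  cls <- classify_network(fx_stacked())
  expect_false(cls["tree_child"])  # reticulation child is a reticulation

  cls <- classify_network(fx_triangle())
  expect_true(cls[["tree_child"]])
  expect_false(cls[["normal"]])
  expect_true(cls[["simplicial"]])

  cls <- classify_network(fx_two_cycles())
  expect_true(cls[["tree_child"]])
  expect_false(cls[["galled_network"]])  # r2 sits in two cycles

  cls <- classify_network(fx_normal_gall())
  expect_true(cls[["normal"]])
  expect_true(cls[["galled_tree"]])
})

test_that("the inclusion lattice holds on the full census", {
  for (n in 1:4) {
    for (r in 0:2) {
      for (net in enumerate_networks(n, r)) {
        cls <- classify_network(net)
        expect_true(!cls[["tree"]] || all(cls))
        expect_true(!cls[["normal"]] || cls[["tree_child"]])
        expect_true(!cls[["galled_tree"]] || cls[["galled_network"]])
        expect_true(!cls[["simplicial"]] || cls[["semi_simplicial"]])
        expect_true(!cls[["simplicial"]] || cls[["galled_network"]])
      }
    }
  }
})

test_that("every enumerated simplicial network is a galled network", {
  for (n in 1:4) {
    for (r in 0:2) {
      for (net in enumerate_networks(n, r)) {
        cls <- classify_network(net)
        if (cls[["simplicial"]]) expect_true(cls[["galled_network"]])
      }
    }
  }
})

test_that("galled classes reduce to cycle counts and edge-disjointness", {
  for (net in c(enumerate_networks(3, 2)[seq(1, 270, by = 9)],
                list(fx_two_cycles(), fx_bare_gall()))) {
    cls <- classify_network(net)
    cyc <- reticulation_cycles(net)
    bottoms <- vapply(cyc, function(cy) cy$bottom, character(1))
    r_ids <- unique(bottoms)
    per_retic_once <- length(cyc) == network_stats(net)$n_reticulations &&
      all(table(bottoms) == 1)
    expect_identical(unname(cls["galled_network"]), per_retic_once)
  }
})

test_that("class specs expose label-agnostic predicates and vertex bounds", {
  spec <- class_spec("max-reticulations", k = 1)
  expect_true(spec$predicate(fx_bare_gall()))
  expect_false(spec$predicate(fx_stacked()))
  expect_equal(spec$f(4), 2 * 4 + 2 * 1)

  h <- class_spec("max-height", k = 2)
  expect_true(h$predicate(read_enewick("(1,2);")))
  expect_false(h$predicate(read_enewick("((1,2),3);")))

  expect_error(class_spec("orchard"), "unknown class")
  expect_setequal(network_classes(),
                  c("tree", "tree-child", "normal", "galled-network",
                    "galled-tree", "simplicial", "semi-simplicial"))
})
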