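test_that("validation reports each violated invariant as a diagnostic", {
  ok <- phylo_network(rbind(c("rho", "a")), c(a = 1))
  expect_length(validate_network(ok), 0)

  # a vertex with in-degree 2 and out-degree 2
  bad_deg <- phylo_network(rbind(
    c("rho", "x"), c("x", "m"), c("x", "y"), c("y", "m"),
    c("m", "a"), c("m", "b"), c("y", "c")),
    c(a = 1, b = 2, c = 3), validate = FALSE)
  expect_match(paste(validate_network(bad_deg), collapse = " "),
               "degree \\(in=2,out=2\\)")

  cyc <- phylo_network(rbind(c("a", "b"), c("b", "c"), c("c", "a")),
                       c(), validate = FALSE)
  expect_match(paste(validate_network(cyc), collapse = " "), "cycle")

  dup <- phylo_network(rbind(c("rho", "t"), c("t", "a"), c("t", "b")),
                       c(a = 1, b = 1), validate = FALSE)
  expect_match(paste(validate_network(dup), collapse = " "), "distinct")
})

test_that("network statistics follow the degree-sum identity and the height convention", {
  single <- phylo_network(rbind(c("rho", "a")), c(a = 1))
  st <- network_stats(single)
  expect_equal(st[c("n_leaves", "n_reticulations", "height", "n_vertices")],
               list(n_leaves = 1L, n_reticulations = 0L, height = 1L,
                    n_vertices = 2L))

  cherry <- read_enewick("(1,2);")
  expect_equal(network_stats(cherry)$height, 2L)
  expect_equal(network_stats(cherry)$n_vertices, 4L)

  for (net in enumerate_networks(3, 1)) {
    st <- network_stats(net)
    expect_equal(st$n_vertices, 8L)
    expect_equal(st$n_vertices, 2 * st$n_leaves + 2 * st$n_reticulations)
  }
})

test_that("equivalence and canonical codes agree with the brute-force oracle", {
  cherry12 <- read_enewick("(1,2);")
  cherry13 <- read_enewick("(1,3);")
  shuffled <- phylo_network(rbind(c("R", "X"), c("X", "p"), c("X", "q")),
                            c(p = 1, q = 2))
  expect_true(is_equivalent(cherry12, shuffled))
  expect_false(is_equivalent(cherry12, cherry13))
  expect_false(canonical_code(cherry12) == canonical_code(cherry13))

  census <- census_n3r1()
  codes <- vapply(census, canonical_code, character(1))
  expect_false(anyDuplicated(codes) > 0)
  # full pairwise agreement between code equality and permutation search
  for (i in seq_along(census)) {
    for (j in seq_len(i)) {
      expect_identical(codes[i] == codes[j],
                       bf_equivalent(census[[i]], census[[j]]),
                       info = paste("pair", i, j))
    }
  }
})

test_that("canonical code is stable under random renaming of internal vertices", {
  set.seed(11)
  nets <- c(list(fx_bare_gall(), fx_two_cycles()),
            enumerate_networks(3, 1)[1:5])
  for (net in nets) {
    ref <- canonical_code(net)
    internal <- setdiff(unique(c(net$edges)), names(net$labels))
    for (trial in 1:10) {
      map <- stats::setNames(paste0("z", sample(1000, length(internal))),
                             internal)
      e2 <- net$edges
      hit <- e2 %in% names(map)
      e2[hit] <- map[e2[hit]]
      renamed <- phylo_network(e2, net$labels)
      expect_identical(canonical_code(renamed), ref)
    }
  }
})

test_that("relabelling is injective, reversible and preserves classification", {
  cherry <- read_enewick("(1,2);")
  expect_true(is_equivalent(relabel_leaves(cherry, c("1" = 1, "2" = 2)),
                            cherry))
  moved <- relabel_leaves(cherry, c("2" = 7))
  expect_setequal(unname(moved$labels), c(1L, 7L))
  expect_error(relabel_leaves(cherry, c("2" = 1)), "distinct")
  expect_error(relabel_leaves(cherry, c("1" = 5, "2" = 5)), "injective")

  set.seed(23)
  pool <- c(enumerate_networks(3, 1), enumerate_networks(2, 2))
  for (net in sample(pool, 25)) {
    labs <- sort(unname(net$labels))
    map <- stats::setNames(sample(50, length(labs)), labs)
    expect_identical(classify_network(relabel_leaves(net, map)),
                     classify_network(net))
  }
})

test_that("tree shapes ignore labels and separate topologies", {
  expect_identical(shape_of(read_enewick("(1,2);")),
                   shape_of(read_enewick("(5,9);")))
  shapes3 <- vapply(enumerate_trees(1:3),
                    function(t) unclass(shape_of(t)), character(1))
  expect_length(unique(shapes3), 1L)
  shapes4 <- vapply(enumerate_trees(1:4),
                    function(t) unclass(shape_of(t)), character(1))
  expect_length(unique(shapes4), 2L)
  expect_setequal(unique(shapes4),
                  c(unclass(shape_of("balanced4")),
                    unclass(shape_of("caterpillar4"))))
  expect_error(shape_of(fx_triangle()), "tree")
})
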