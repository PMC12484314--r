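# Membership predicates for the seven network classes, built on
# reticulation-cycle and shortcut detection.

# all directed paths ending at vertex x (vertex index sequences, each
# starting at an arbitrary ancestor and ending at x)
.paths_ending_at <- function(ix, x) {
  out <- list(c(x))
  for (p in ix$parents[[x]]) {
    for (pp in .paths_ending_at(ix, p)) out[[length(out) + 1L]] <- c(pp, x)
  }
  out
}

#' Reticulation cycles of a network
#'
#' A reticulation cycle (gall) is a pair of directed paths from a common top
#' tree vertex to a common bottom reticulation whose sets of internal
#' vertices are disjoint. All cycles are enumerated exhaustively (the
#' instances handled by this package are desk-scale), grouped by their
#' bottom reticulation, in a deterministic order.
#'
#' @param net a valid `phylo_network`.
#' @return A list of cycles; each is a list with elements `top`, `bottom`,
#'   `path_a`, `path_b` (vertex-id sequences from top to bottom, inclusive).
#' @examples
#' gall <- read_enewick("((1,(2)#H1),(#H1,3));")
#' length(reticulation_cycles(gall))
#' @export
reticulation_cycles <- function(net) {
  .stop_if_invalid(net)
  ix <- .net_index(net)
  retics <- which(ix$kind == "retic")
  retics <- retics[order(ix$ids[retics])]
  cycles <- list()
  for (b in retics) {
    pr <- ix$parents[[b]]
    paths1 <- .paths_ending_at(ix, pr[1])
    paths2 <- .paths_ending_at(ix, pr[2])
    found <- list()
    for (pa in paths1) {
      for (pb in paths2) {
        t <- pa[1]
        if (pb[1] != t) next
        if (ix$kind[t] != "tree") next
        int_a <- pa[-1]            # internal vertices of t -> ... -> pr1 -> b
        int_b <- pb[-1]
        if (length(intersect(int_a, int_b)) > 0) next
        pa_ids <- ix$ids[c(pa, b)]
        pb_ids <- ix$ids[c(pb, b)]
        if (paste(pa_ids, collapse = ",") > paste(pb_ids, collapse = ",")) {
          tmp <- pa_ids; pa_ids <- pb_ids; pb_ids <- tmp
        }
        found[[length(found) + 1L]] <-
          list(top = ix$ids[t], bottom = ix$ids[b],
               path_a = pa_ids, path_b = pb_ids)
      }
    }
    keys <- vapply(found, function(cy)
      paste(c(cy$path_a, "|", cy$path_b), collapse = ","), character(1))
    cycles <- c(cycles, found[order(keys)])
  }
  cycles
}

#' Find a shortcut edge
#'
#' A shortcut is an edge (u, v) such that another directed path from u to v
#' exists. Normal networks are exactly the tree-child networks without
#' shortcuts.
#'
#' @param net a valid `phylo_network`.
#' @return A character vector `c(u, v)` naming some shortcut edge, or `NULL`
#'   if the network has none. Deterministic: edges are scanned in a fixed
#'   order.
#' @examples
#' is.null(has_shortcut(read_enewick("((1,2),3);")))
#' @export
has_shortcut <- function(net) {
  .stop_if_invalid(net)
  ix <- .net_index(net)
  m <- length(ix$from)
  ord <- order(ix$ids[ix$from], ix$ids[ix$to])
  for (i in ord) {
    u <- ix$from[i]; v <- ix$to[i]
    # reachability u -> v avoiding edge i; the digraph is simple, so
    # avoiding the edge means dropping v from u's direct children
    seen <- rep(FALSE, ix$nv)
    stack <- ix$children[[u]][ix$children[[u]] != v]
    while (length(stack) > 0) {
      w <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[w]) next
      seen[w] <- TRUE
      if (w == v) return(c(ix$ids[u], ix$ids[v]))
      stack <- c(stack, ix$children[[w]])
    }
  }
  NULL
}

# descendant indicator matrix-free helper: indices reachable from v
# (excluding v itself unless on a cycle, which cannot happen in a DAG)
.descendants <- function(ix, v) {
  seen <- rep(FALSE, ix$nv)
  stack <- ix$children[[v]]
  while (length(stack) > 0) {
    w <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[w]) next
    seen[w] <- TRUE
    stack <- c(stack, ix$children[[w]])
  }
  which(seen)
}

#' Classify a network into the seven standard classes
#'
#' Computes membership of a network in each of: phylogenetic trees,
#' tree-child networks, normal networks, galled networks, galled trees,
#' simplicial networks and semi-simplicial networks.
#'
#' @details The predicates are:
#' * `tree`: no reticulations.
#' * `tree_child`: every non-leaf vertex has at least one child that is a
#'   tree vertex or a leaf.
#' * `normal`: tree-child with no shortcut edge.
#' * `galled_network`: every reticulation is the bottom of exactly one
#'   reticulation cycle.
#' * `galled_tree`: a galled network whose reticulation cycles are pairwise
#'   edge-disjoint (level-1 network).
#' * `simplicial`: the child of every reticulation is a leaf.
#' * `semi_simplicial`: the child of every reticulation is a leaf or the
#'   root of a pendant tree, implemented as: the child, together with all
#'   its descendants, contains no reticulation.
#'
#' The implied inclusions (tree implies everything; normal implies
#' tree-child; galled tree implies galled network; simplicial implies
#' semi-simplicial and galled network) are asserted internally after the
#' predicates are computed independently; a violation aborts, since it can
#' only be a bug.
#'
#' @param net a valid `phylo_network`.
#' @return Named logical vector with elements `tree`, `tree_child`,
#'   `normal`, `galled_network`, `galled_tree`, `simplicial`,
#'   `semi_simplicial`.
#' @examples
#' classify_network(read_enewick("((1,(2)#H1),(#H1,3));"))
#' @export
classify_network <- function(net) {
  .stop_if_invalid(net)
  ix <- .net_index(net)
  retics <- which(ix$kind == "retic")
  is_tree <- length(retics) == 0L

  tree_child <- all(vapply(which(ix$kind != "leaf"), function(v) {
    any(ix$kind[ix$children[[v]]] %in% c("tree", "leaf"))
  }, logical(1)))

  normal <- tree_child && is.null(has_shortcut(net))

  cycles <- reticulation_cycles(net)
  bottoms <- vapply(cycles, function(cy) cy$bottom, character(1))
  galled_network <- all(table(factor(bottoms, levels = ix$ids[retics])) == 1L)

  galled_tree <- FALSE
  if (galled_network) {
    edge_sets <- lapply(cycles, function(cy) {
      pa <- cy$path_a; pb <- cy$path_b
      c(paste(pa[-length(pa)], pa[-1], sep = ">"),
        paste(pb[-length(pb)], pb[-1], sep = ">"))
    })
    all_edges <- unlist(edge_sets)
    galled_tree <- !anyDuplicated(all_edges)
  }

  simplicial <- all(vapply(retics, function(b)
    ix$kind[ix$children[[b]]] == "leaf", logical(1)))

  semi_simplicial <- all(vapply(retics, function(b) {
    c0 <- ix$children[[b]]
    if (ix$kind[c0] == "leaf") return(TRUE)
    if (ix$kind[c0] == "retic") return(FALSE)
    !any(ix$kind[.descendants(ix, c0)] == "retic")
  }, logical(1)))

  out <- c(tree = is_tree, tree_child = tree_child, normal = normal,
           galled_network = galled_network, galled_tree = galled_tree,
           simplicial = simplicial, semi_simplicial = semi_simplicial)
  ok <- (!is_tree || all(out)) &&
    (!normal || tree_child) &&
    (!galled_tree || galled_network) &&
    (!simplicial || (semi_simplicial && galled_network))
  if (!ok) stop("internal inconsistency in classify_network (this is a bug): ",
                paste(names(out)[!out], collapse = ","))
  out
}

# ---- class specifications ----------------------------------------------

.class_names <- c("tree", "tree-child", "normal", "galled-network",
                  "galled-tree", "simplicial", "semi-simplicial")

#' Class specifications
#'
#' A class specification couples a class name with its membership predicate
#' and a vertex-bound function f(n) (the requirement that vertex counts in
#' the class are bounded by a function of the leaf number). All predicates
#' are invariant under leaf relabelling.
#'
#' @param name one of `"tree"`, `"tree-child"`, `"normal"`,
#'   `"galled-network"`, `"galled-tree"`, `"simplicial"`,
#'   `"semi-simplicial"`, or the parameterized `"max-reticulations"` /
#'   `"max-height"` (which require `k`).
#' @param k bound parameter for the parameterized classes.
#' @return An object of class `class_spec`: a list with `name`, `k`,
#'   `predicate` (function of a network), `f` (vertex bound, function of n)
#'   and `label_agnostic`.
#' @examples
#' spec <- class_spec("tree-child")
#' spec$predicate(read_enewick("((1,2),3);"))
#' @export
class_spec <- function(name, k = NULL) {
  key <- gsub("-", "_", name)
  if (name %in% .class_names) {
    pred <- function(net) unname(classify_network(net)[key])
    f <- switch(name,
      "tree" = function(n) 2 * n,
      # tree-child/normal/galled classes have at most n - 1 reticulations;
      # simplicial/semi-simplicial at most n (distinct reticulation children)
      "tree-child" = , "normal" = , "galled-tree" = ,
      "galled-network" = function(n) 4 * n - 2,
      "simplicial" = , "semi-simplicial" = function(n) 4 * n)
  } else if (name == "max-reticulations") {
    stopifnot(is.numeric(k), k >= 0)
    pred <- function(net) network_stats(net)$n_reticulations <= k
    f <- function(n) 2 * n + 2 * k
  } else if (name == "max-height") {
    stopifnot(is.numeric(k), k >= 1)
    pred <- function(net) network_stats(net)$height <= k
    f <- function(n) 2^(k + 1)
  } else {
    stop("unknown class name: ", name)
  }
  structure(list(name = name, k = k, predicate = pred, f = f,
                 label_agnostic = TRUE),
            class = "class_spec")
}

#' @rdname class_spec
#' @return `network_classes()`: the names of the seven unparameterized
#'   classes.
#' @export
network_classes <- function() .class_names

#' @export
print.class_spec <- function(x, ...) {
  cat("<class_spec> ", x$name,
      if (!is.null(x$k)) paste0(" (k = ", x$k, ")"), "\n", sep = "")
  invisible(x)
}
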