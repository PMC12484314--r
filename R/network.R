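# Core data model: rooted binary phylogenetic networks as simple DAGs.
#
# A network is stored as an m x 2 character edge matrix (parent, child)
# plus a named integer vector assigning labels to the leaf vertex ids.
# Vertex ids are opaque strings; two networks are ever compared only up to
# labeled isomorphism (is_equivalent), never by id equality.

#' Construct a rooted binary phylogenetic network
#'
#' A (binary) phylogenetic network on leaf labels drawn from the positive
#' integers is a simple directed acyclic graph in which every non-leaf vertex
#' is either the root (in-degree 0, out-degree 1, sitting atop the ancestral
#' root edge), a tree vertex (in-degree 1, out-degree 2) or a reticulation
#' (in-degree 2, out-degree 1); leaves have out-degree 0 and carry distinct
#' labels. A valid network with n leaves and r reticulations has exactly
#' 2n + 2r vertices.
#'
#' @param edges character matrix with two columns (parent id, child id).
#' @param labels named integer vector: names are leaf vertex ids, values are
#'   the (distinct, positive) leaf labels.
#' @param validate if `TRUE` (default), reject structurally invalid input.
#' @return An object of class `phylo_network` with components `edges` and
#'   `labels`.
#' @seealso [validate_network()], [network_stats()], [is_equivalent()]
#' @examples
#' # the smallest network: root -> leaf labeled 1
#' net <- phylo_network(rbind(c("rho", "a")), c(a = 1))
#' network_stats(net)
#' @export
phylo_network <- function(edges, labels, validate = TRUE) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  storage.mode(edges) <- "character"
  colnames(edges) <- c("parent", "child")
  labels <- stats::setNames(as.integer(labels), names(labels))
  net <- structure(list(edges = edges, labels = labels),
                   class = "phylo_network")
  if (validate) {
    rep <- validate_network(net)
    if (length(rep) > 0)
      stop("invalid phylogenetic network: ", paste(rep, collapse = "; "))
  }
  net
}

# Index form used internally by every algorithm: integer vertex indices,
# child/parent adjacency lists, degrees, vertex kinds and a topological order.
.net_index <- function(net) {
  e <- net$edges
  ids <- sort(unique(c(e[, 1], e[, 2])))
  nv <- length(ids)
  from <- match(e[, 1], ids)
  to <- match(e[, 2], ids)
  outd <- tabulate(from, nv)
  ind <- tabulate(to, nv)
  children <- lapply(seq_len(nv), function(i) to[from == i])
  parents <- lapply(seq_len(nv), function(i) from[to == i])
  labels <- rep(NA_integer_, nv)
  pos <- match(names(net$labels), ids)
  labels[pos[!is.na(pos)]] <- net$labels[!is.na(pos)]
  kind <- rep("tree", nv)
  kind[ind == 0] <- "root"
  kind[outd == 0] <- "leaf"
  kind[ind == 2 & outd == 1] <- "retic"
  # Kahn topological order (NA-padded if cyclic)
  topo <- integer(0)
  deg <- ind
  queue <- which(deg == 0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    topo <- c(topo, v)
    for (c in children[[v]]) {
      deg[c] <- deg[c] - 1L
      if (deg[c] == 0) queue <- c(queue, c)
    }
  }
  list(ids = ids, nv = nv, from = from, to = to, outd = outd, ind = ind,
       children = children, parents = parents, labels = labels, kind = kind,
       topo = topo, acyclic = length(topo) == nv)
}

#' Validate a phylogenetic network
#'
#' Checks every structural invariant of a rooted binary phylogenetic network
#' and reports the violations as diagnostics rather than raising conditions.
#'
#' @param net a `phylo_network` (possibly invalid).
#' @return Character vector naming each violated invariant; empty if valid.
#' @examples
#' bad <- phylo_network(rbind(c("a", "b"), c("b", "a")), c(), validate = FALSE)
#' validate_network(bad)
#' @export
validate_network <- function(net) {
  rep <- character(0)
  e <- net$edges
  if (!is.matrix(e) || ncol(e) != 2 || nrow(e) < 1)
    return("edge matrix must have two columns and at least one edge")
  if (any(e[, 1] == e[, 2]))
    rep <- c(rep, "self-loop edge present")
  if (anyDuplicated(paste(e[, 1], e[, 2])))
    rep <- c(rep, "parallel edges present (digraph must be simple)")
  if (length(rep) > 0) return(rep)
  ix <- .net_index(net)
  if (!ix$acyclic)
    rep <- c(rep, "directed cycle present (graph must be acyclic)")
  roots <- which(ix$ind == 0)
  if (length(roots) != 1) {
    rep <- c(rep, sprintf("expected exactly one in-degree-0 vertex, found %d",
                          length(roots)))
  } else if (ix$outd[roots] != 1) {
    rep <- c(rep, "root must have out-degree 1 (ancestral root edge)")
  }
  leaves <- which(ix$outd == 0)
  for (v in seq_len(ix$nv)) {
    if (v %in% roots || v %in% leaves) next
    ok <- (ix$ind[v] == 1 && ix$outd[v] == 2) ||
      (ix$ind[v] == 2 && ix$outd[v] == 1)
    if (!ok)
      rep <- c(rep, sprintf(
        "vertex '%s' has degree (in=%d,out=%d); internal vertices must be (1,2) or (2,1)",
        ix$ids[v], ix$ind[v], ix$outd[v]))
  }
  if (any(ix$ind[leaves] != 1))
    rep <- c(rep, "every leaf must have in-degree 1")
  lab <- ix$labels[leaves]
  if (anyNA(lab)) {
    rep <- c(rep, "every leaf must carry a label")
  } else {
    if (anyDuplicated(lab)) rep <- c(rep, "leaf labels must be distinct")
    if (any(lab < 1)) rep <- c(rep, "leaf labels must be positive integers")
  }
  extra <- setdiff(names(net$labels), ix$ids[leaves])
  if (length(extra) > 0)
    rep <- c(rep, "labels assigned to non-leaf vertices")
  if (length(rep) == 0) {
    n <- length(leaves)
    r <- sum(ix$kind == "retic")
    if (ix$nv != 2 * n + 2 * r)
      rep <- c(rep, "vertex count does not equal 2n + 2r")
  }
  rep
}

.stop_if_invalid <- function(net) {
  rep <- validate_network(net)
  if (length(rep) > 0)
    stop("invalid phylogenetic network: ", paste(rep, collapse = "; "))
  invisible(net)
}

#' Basic statistics of a network
#'
#' @param net a valid `phylo_network`.
#' @return A list with `n_leaves`, `n_reticulations`, `height` (edge count of
#'   the longest root-to-leaf path, which includes the ancestral root edge)
#'   and `n_vertices`. For every valid network
#'   `n_vertices == 2 * n_leaves + 2 * n_reticulations`.
#' @details Height is counted in edges along the longest directed path from
#'   the root; the ancestral root edge contributes one. The single-edge
#'   network root -> leaf therefore has height 1. This is the one convention
#'   used throughout the package (the closed class "height at most k" is
#'   defined with respect to it).
#' @examples
#' net <- read_enewick("((1,2),3);")
#' network_stats(net)
#' @export
network_stats <- function(net) {
  .stop_if_invalid(net)
  ix <- .net_index(net)
  dist <- rep(0L, ix$nv)
  for (v in ix$topo)
    for (c in ix$children[[v]])
      dist[c] <- max(dist[c], dist[v] + 1L)
  list(n_leaves = sum(ix$kind == "leaf"),
       n_reticulations = sum(ix$kind == "retic"),
       height = max(dist[ix$kind == "leaf"]),
       n_vertices = ix$nv)
}

#' @export
print.phylo_network <- function(x, ...) {
  st <- tryCatch(network_stats(x), error = function(e) NULL)
  if (is.null(st)) {
    cat("<phylo_network> (INVALID)\n")
    cat(paste0("  - ", validate_network(x), collapse = "\n"), "\n")
  } else {
    cat(sprintf(
      "<phylo_network> %d leaves, %d reticulation(s), height %d, %d vertices\n",
      st$n_leaves, st$n_reticulations, st$height, st$n_vertices))
    cat("  ", write_enewick(x), "\n", sep = "")
  }
  invisible(x)
}

# ---- labeled-isomorphism canonical form --------------------------------

# Sorted labels reachable from each vertex, as strings (used as a partition
# refinement invariant and by the restriction operator).
.reach_label_sets <- function(ix) {
  reach <- vector("list", ix$nv)
  for (v in rev(ix$topo)) {
    if (ix$kind[v] == "leaf") {
      reach[[v]] <- ix$labels[v]
    } else {
      reach[[v]] <- sort(unique(unlist(reach[ix$children[[v]]])))
    }
  }
  reach
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# Canonical code of a labeled tree (r = 0): recursive sorting of subtree
# encodings is already canonical, no search needed.
.tree_code <- function(ix) {
  code <- character(ix$nv)
  for (v in rev(ix$topo)) {
    if (ix$kind[v] == "leaf") {
      code[v] <- as.character(ix$labels[v])
    } else {
      ch <- sort(code[ix$children[[v]]])
      code[v] <- paste0("(", paste(ch, collapse = ","), ")")
    }
  }
  paste0("T:", code[ix$topo[1]])
}

#' Canonical code of a network
#'
#' Produces a string such that two valid networks receive the same code if
#' and only if they are equivalent, i.e. related by a directed-graph
#' isomorphism fixing every leaf label ([is_equivalent()]). Used as the
#' deduplication key by the enumeration machinery.
#'
#' @details Labeled trees are encoded directly by recursively sorting
#'   subtree encodings. For reticulate networks the vertices are first
#'   partitioned by iterated refinement of the invariant (vertex kind,
#'   reachable leaf-label set, neighbour colours); the code is then the
#'   lexicographic minimum of the edge-list encoding over all orderings
#'   consistent with the refined partition. All instances are desk-scale, so
#'   the residual search (typically 1--4 orderings) is cheap; a guard errors
#'   out if the partition leaves more than 40320 orderings.
#'
#' @param net a valid `phylo_network`.
#' @return A character scalar.
#' @examples
#' a <- read_enewick("((1,2),3);")
#' b <- read_enewick("(3,(2,1));")
#' canonical_code(a) == canonical_code(b)
#' @export
canonical_code <- function(net) {
  .stop_if_invalid(net)
  ix <- .net_index(net)
  if (!any(ix$kind == "retic")) return(.tree_code(ix))
  .canonicalize(ix)$code
}

# Refinement + backtracking canonicalization on the index form. Returns the
# canonical code and the vertex ordering (indices in canonical position
# order) realizing it.
.canonicalize <- function(ix) {
  reach <- .reach_label_sets(ix)
  col <- paste0(ix$kind, "|",
                vapply(reach, paste, character(1), collapse = ","))
  repeat {
    sig <- vapply(seq_len(ix$nv), function(v) {
      paste(col[v],
            paste(sort(col[ix$children[[v]]]), collapse = "+"),
            paste(sort(col[ix$parents[[v]]]), collapse = "+"),
            sep = " / ")
    }, character(1))
    newcol <- match(sig, sort(unique(sig)))
    if (length(unique(newcol)) == length(unique(col))) {
      col <- newcol
      break
    }
    col <- as.character(newcol)
  }
  cells <- split(seq_len(ix$nv), col)
  cells <- cells[order(as.integer(names(cells)))]
  n_orderings <- prod(vapply(cells, function(c) factorial(length(c)), 1))
  if (n_orderings > 40320)
    stop("canonicalization guard: partition too coarse (",
         n_orderings, " orderings)")
  # header: vertex kinds and leaf labels in position order (identical for
  # every consistent ordering since cells are colour-homogeneous)
  base_order <- unlist(cells, use.names = FALSE)
  header <- paste(vapply(base_order, function(v) {
    if (ix$kind[v] == "leaf") paste0("L", ix$labels[v]) else
      substr(ix$kind[v], 1, 1)
  }, character(1)), collapse = ",")
  cell_perms <- lapply(cells, function(cell) {
    if (length(cell) == 1) matrix(cell, 1, 1) else {
      p <- .permutations(length(cell))
      matrix(cell[p], nrow(p), ncol(p))
    }
  })
  best <- NULL
  best_order <- NULL
  rec <- function(i, order_so_far) {
    if (i > length(cell_perms)) {
      pos <- integer(ix$nv)
      pos[order_so_far] <- seq_len(ix$nv)
      enc <- paste(sort(sprintf("%02d>%02d", pos[ix$from], pos[ix$to])),
                   collapse = ";")
      if (is.null(best) || enc < best) {
        best <<- enc
        best_order <<- order_so_far
      }
      return(invisible(NULL))
    }
    pm <- cell_perms[[i]]
    for (rw in seq_len(nrow(pm)))
      rec(i + 1L, c(order_so_far, pm[rw, ]))
  }
  rec(1L, integer(0))
  list(code = paste0("N:", header, "#", best), order = best_order)
}

#' Test labeled-isomorphism equivalence of two networks
#'
#' Two phylogenetic networks are equivalent when a directed-graph
#' isomorphism between them maps each leaf labeled i to the leaf labeled i.
#'
#' @param a,b valid `phylo_network` objects.
#' @return `TRUE` or `FALSE`.
#' @export
is_equivalent <- function(a, b) {
  sa <- network_stats(a); sb <- network_stats(b)
  if (sa$n_leaves != sb$n_leaves || sa$n_reticulations != sb$n_reticulations)
    return(FALSE)
  if (!identical(sort(unname(a$labels)), sort(unname(b$labels))))
    return(FALSE)
  canonical_code(a) == canonical_code(b)
}

#' Relabel the leaves of a network
#'
#' Any injective relabelling of the leaves of a network yields another
#' network of the same shape; all class predicates in this package are
#' invariant under relabelling.
#'
#' @param net a valid `phylo_network`.
#' @param mapping named numeric vector: names are existing labels, values
#'   their replacements. Labels absent from `mapping` are kept. The result
#'   must again have distinct positive labels.
#' @return The relabelled `phylo_network`.
#' @examples
#' cherry <- read_enewick("(1,2);")
#' relabel_leaves(cherry, c("2" = 7))
#' @export
relabel_leaves <- function(net, mapping) {
  .stop_if_invalid(net)
  old <- as.integer(names(mapping))
  new <- as.integer(mapping)
  if (anyNA(old) || anyNA(new) || anyDuplicated(old) || anyDuplicated(new))
    stop("mapping must be an injective named label map")
  lab <- net$labels
  hit <- match(lab, old)
  lab[!is.na(hit)] <- new[hit[!is.na(hit)]]
  if (anyDuplicated(lab) || any(lab < 1))
    stop("mapping must keep leaf labels distinct and positive")
  phylo_network(net$edges, lab)
}

#' Unlabeled shape of a phylogenetic tree
#'
#' Strips leaf labels from a tree (a network with no reticulations) and
#' returns a canonical encoding of the resulting rooted binary tree shape.
#' Two trees have equal shapes iff their encodings are equal strings.
#'
#' @param tree a valid `phylo_network` with zero reticulations, or one of
#'   the preset names `"leaf"`, `"cherry"`, `"balanced4"`, `"caterpillar4"`.
#' @return An object of class `tree_shape` (a canonical string).
#' @examples
#' shape_of(read_enewick("(1,2);")) == shape_of("cherry")
#' @export
shape_of <- function(tree) {
  if (is.character(tree)) {
    return(switch(tree,
      leaf = structure("*", class = "tree_shape"),
      cherry = structure("(**)", class = "tree_shape"),
      balanced4 = structure("((**)(**))", class = "tree_shape"),
      caterpillar4 = structure("(((**)*)*)", class = "tree_shape"),
      stop("unknown shape preset: ", tree)))
  }
  .stop_if_invalid(tree)
  ix <- .net_index(tree)
  if (any(ix$kind == "retic"))
    stop("shape_of requires a tree (network with no reticulations)")
  structure(.shape_code(ix), class = "tree_shape")
}

.shape_code <- function(ix, at = NULL) {
  code <- character(ix$nv)
  for (v in rev(ix$topo)) {
    if (ix$kind[v] == "leaf") {
      code[v] <- "*"
    } else if (ix$kind[v] == "root") {
      code[v] <- code[ix$children[[v]][1]]
    } else {
      ch <- sort(code[ix$children[[v]]])
      code[v] <- paste0("(", paste(ch, collapse = ""), ")")
    }
  }
  if (is.null(at)) code[ix$topo[1]] else code
}

#' @export
print.tree_shape <- function(x, ...) {
  cat("<tree_shape> ", unclass(x), "\n", sep = "")
  invisible(x)
}
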