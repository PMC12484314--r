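# The induced-subnetwork operator N|Y, closure testing, and membership in
# the maximal closed subclass of a network class.

#' Restrict a network to a subset of its leaves
#'
#' The induced subnetwork N|Y keeps exactly the vertices and edges of N
#' lying on at least one path from the root to a leaf of Y, then repeatedly
#' merges double (parallel) edges into one and suppresses subdivision
#' vertices (in-degree and out-degree 1) until a fixpoint. The result is a
#' valid network on leaf set Y; restricting to the full leaf set returns a
#' network equivalent to the input. The ancestral root edge is always
#' retained (the root itself is never suppressed).
#'
#' @details Each sweep merges parallel edges before suppressing unary
#'   vertices; the fixpoint is independent of this order, but fixing it
#'   makes runs deterministic. Restriction never increases the reticulation
#'   count or the height.
#'
#' @param net a valid `phylo_network`.
#' @param leaves nonempty vector of leaf labels to keep (a subset of the
#'   network's labels).
#' @return A valid `phylo_network` on leaf set `leaves`.
#' @examples
#' gall <- read_enewick("((1,(2)#H1),(#H1,3));")
#' restrict_network(gall, c(1, 3))
#' @export
restrict_network <- function(net, leaves) {
  .stop_if_invalid(net)
  leaves <- as.integer(leaves)
  if (length(leaves) == 0) stop("restriction to the empty leaf set is not defined")
  if (!all(leaves %in% net$labels))
    stop("unknown leaf labels: ",
         paste(setdiff(leaves, net$labels), collapse = ", "))
  ix <- .net_index(net)
  reach <- .reach_label_sets(ix)
  keep <- vapply(reach, function(s) any(s %in% leaves), logical(1))
  e <- net$edges
  kv <- ix$ids[keep]
  e <- e[e[, 1] %in% kv & e[, 2] %in% kv, , drop = FALSE]
  lab <- net$labels[net$labels %in% leaves]
  # fixpoint: merge parallel edges, then suppress unary vertices, repeat
  repeat {
    changed <- FALSE
    dup <- duplicated(paste(e[, 1], e[, 2]))
    if (any(dup)) {
      e <- e[!dup, , drop = FALSE]
      changed <- TRUE
    }
    verts <- unique(c(e[, 1], e[, 2]))
    outd <- table(factor(e[, 1], levels = verts))
    ind <- table(factor(e[, 2], levels = verts))
    unary <- verts[ind == 1 & outd == 1]
    if (length(unary) > 0) {
      v <- sort(unary)[1]
      p <- e[e[, 2] == v, 1]
      c0 <- e[e[, 1] == v, 2]
      e <- e[e[, 1] != v & e[, 2] != v, , drop = FALSE]
      e <- rbind(e, c(p, c0))
      changed <- TRUE
    }
    if (!changed) break
  }
  out <- phylo_network(e, lab, validate = FALSE)
  rep <- validate_network(out)
  if (length(rep) > 0)
    stop("internal error: restriction produced an invalid network: ",
         paste(rep, collapse = "; "))
  out
}

.nonempty_subsets <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  out <- list()
  for (size in seq_len(n)) {
    cm <- utils::combn(labels, size)
    for (j in seq_len(ncol(cm))) out[[length(out) + 1L]] <- cm[, j]
  }
  out
}

#' Search for a closure counterexample
#'
#' A class is closed when every restriction of every member stays in the
#' class. Given a member network, this searches all nonempty leaf subsets Y
#' for a restriction N|Y falling outside the class.
#'
#' @param class a [class_spec()].
#' @param net a valid `phylo_network` satisfying `class$predicate`.
#' @return `NULL` if every restriction stays in the class; otherwise a
#'   `closure_witness`: a list with `leaf_subset`, `restricted` (the
#'   offending N|Y) and `violated_class`.
#' @examples
#' # a normal network with one reticulation: restricting to the reticulation
#' # child plus one cycle-side leaf creates a shortcut
#' net <- read_enewick("((1,(2)#H1),(#H1,3));")
#' closure_counterexample(class_spec("normal"), net)$leaf_subset
#' @export
closure_counterexample <- function(class, net) {
  stopifnot(inherits(class, "class_spec"))
  .stop_if_invalid(net)
  if (!isTRUE(class$predicate(net)))
    stop("network is not in class '", class$name, "'")
  for (Y in .nonempty_subsets(unname(net$labels))) {
    sub <- restrict_network(net, Y)
    if (!isTRUE(class$predicate(sub))) {
      return(structure(list(leaf_subset = Y, restricted = sub,
                            violated_class = class$name),
                       class = "closure_witness"))
    }
  }
  NULL
}

#' @export
print.closure_witness <- function(x, ...) {
  cat("<closure_witness> class '", x$violated_class, "' violated by Y = {",
      paste(x$leaf_subset, collapse = ","), "}\n", sep = "")
  cat("  N|Y: ", write_enewick(x$restricted), "\n", sep = "")
  invisible(x)
}

#' Membership in the maximal closed subclass
#'
#' Every class contains a unique maximal closed subclass (the union of all
#' its closed subclasses). Because restriction composes --
#' (N|Y)|Z is equivalent to N|Z for Z inside Y -- a network belongs to the
#' maximal closed subclass iff every one of its restrictions satisfies the
#' class predicate, which is what this function checks exhaustively over
#' all 2^n - 1 nonempty leaf subsets.
#'
#' @param class a [class_spec()].
#' @param net a valid `phylo_network` satisfying `class$predicate`.
#' @param guard abort when the network has more than `guard` leaves
#'   (default 6; the subset enumeration is exponential).
#' @return `TRUE` or `FALSE`.
#' @export
in_maximal_closed <- function(class, net, guard = 6) {
  if (length(net$labels) > guard)
    stop("in_maximal_closed: leaf count exceeds guard (", guard, ")")
  is.null(closure_counterexample(class, net))
}

#' Empirical census of a class's maximal closed subclass
#'
#' Enumerates all networks with leaf sets \[1\], ..., \[n_max\] and up to
#' `r_max` reticulations, identifies the members of the class, computes
#' membership in the maximal closed subclass exhaustively, and compares
#' against a predicted characterization where one is known (galled trees
#' for tree-child; trees for normal; the whole class for the closed
#' classes).
#'
#' @param class a [class_spec()].
#' @param n_max,r_max census bounds (guarded at 4 and 2 by default).
#' @param guard set `FALSE` to lift the budget guard.
#' @return A list with `members` (networks in the class), `in_maximal`
#'   (logical, empirical membership in the maximal closed subclass),
#'   `predicted` (logical or NULL when no characterization is known) and
#'   `agreement` (TRUE/FALSE/NA).
#' @export
closure_census <- function(class, n_max = 4, r_max = 2, guard = TRUE) {
  if (guard && (n_max > 4 || r_max > 2))
    stop("closure_census budget guard: n_max <= 4, r_max <= 2 (set guard = FALSE to override)")
  members <- list()
  for (n in seq_len(n_max)) {
    for (r in 0:r_max) {
      for (net in enumerate_networks(n, r, guard = guard)) {
        if (isTRUE(class$predicate(net)))
          members[[length(members) + 1L]] <- net
      }
    }
  }
  in_max <- vapply(members, function(net) in_maximal_closed(class, net),
                   logical(1))
  predicted <- switch(class$name,
    "tree-child" = vapply(members, function(net)
      unname(classify_network(net)["galled_tree"]), logical(1)),
    "normal" = vapply(members, function(net)
      unname(classify_network(net)["tree"]), logical(1)),
    "tree" = , "galled-tree" = , "galled-network" = , "simplicial" = ,
    "semi-simplicial" = , "max-reticulations" = , "max-height" =
      rep(TRUE, length(members)),
    NULL)
  agreement <- if (is.null(predicted)) NA else identical(in_max, predicted)
  list(members = members, in_maximal = in_max, predicted = predicted,
       agreement = agreement)
}
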