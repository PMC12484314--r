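# Exhaustive generation of labeled binary networks for small (n, r).
#
# Trees are generated by the classic leaf-insertion recursion (each labeled
# topology arises exactly once). Networks with r >= 1 reticulations are
# generated from tree skeletons: in any valid network one can delete one
# in-edge per reticulation, choosing tree-vertex sources that are pairwise
# distinct (always possible for r <= 2: the root is never a reticulation
# parent, and a reticulation with two reticulation parents needs r >= 3);
# what remains is a phylogenetic tree on [n] whose edges are subdivided by
# the 2r deleted-edge endpoints. Conversely, every candidate is a tree with
# 2r subdivision points and a source -> target hybrid edge per point pair.
# Enumerating all trees, all ordered placements of the role-labeled points
# and all acyclic, simple completions therefore reaches every network with
# r <= 2 at small multiplicity; duplicates are removed by canonical code.
# The construction is certified against closed forms ((2n-3)!! trees, the
# simplicial tree-child formula) rather than argued structurally alone.

.nc_cache <- new.env(parent = emptyenv())

#' Enumerate all labeled phylogenetic trees on a leaf set
#'
#' Generates each rooted binary tree topology on the given label set exactly
#' once via leaf insertion; the number of topologies is (2|X|-3)!! (with the
#' empty product equal to 1).
#'
#' @param labels integer vector: the leaf label set X.
#' @return List of `phylo_network` objects, each with r = 0.
#' @examples
#' length(enumerate_trees(1:4))  # 15
#' @export
enumerate_trees <- function(labels) {
  labels <- sort(unique(as.integer(labels)))
  if (length(labels) < 1) stop("label set must be nonempty")
  leaf_id <- function(lab) paste0("L", lab)
  nets <- list(matrix(c("rho", leaf_id(labels[1])), ncol = 2))
  counter <- 0L
  for (lab in labels[-1]) {
    nxt <- list()
    for (em in nets) {
      for (i in seq_len(nrow(em))) {
        counter <- counter + 1L
        t <- paste0("i", counter)
        e2 <- em
        child <- e2[i, 2]
        e2[i, 2] <- t
        e2 <- rbind(e2, c(t, child), c(t, leaf_id(lab)))
        nxt[[length(nxt) + 1L]] <- e2
      }
    }
    nets <- nxt
  }
  lapply(nets, function(em)
    phylo_network(em, stats::setNames(labels, leaf_id(labels)),
                  validate = FALSE))
}

# all placements of `npts` role-labeled subdivision points p1, ..., p<npts>
# into the edges of `em` (each placement subdivides one current edge);
# returns a list of edge matrices
.place_points <- function(em, npts) {
  states <- list(em)
  for (k in seq_len(npts)) {
    pid <- paste0("p", k)
    nxt <- vector("list", 0L)
    for (st in states) {
      for (i in seq_len(nrow(st))) {
        e2 <- st
        child <- e2[i, 2]
        e2[i, 2] <- pid
        e2 <- rbind(e2, c(pid, child))
        nxt[[length(nxt) + 1L]] <- e2
      }
    }
    states <- nxt
  }
  states
}

.is_acyclic_em <- function(em) {
  ids <- unique(c(em[, 1], em[, 2]))
  from <- match(em[, 1], ids)
  to <- match(em[, 2], ids)
  nv <- length(ids)
  ind <- tabulate(to, nv)
  queue <- which(ind == 0)
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[length(queue)]; queue <- queue[-length(queue)]
    seen <- seen + 1L
    ch <- to[from == v]
    for (c in ch) {
      ind[c] <- ind[c] - 1L
      if (ind[c] == 0L) queue <- c(queue, c)
    }
  }
  seen == nv
}

# every network on [n] with r reticulations (r <= 2), via tree skeletons
.networks_from_trees <- function(n, r) {
  if (r > 2)
    stop("exhaustive generation is certified complete only for r <= 2")
  # role layout: sources p1, p3; targets p2, p4 (pairs (p1 -> p2),
  # (p3 -> p4)); for r = 1 only (p1 -> p2)
  src <- paste0("p", seq(1, 2 * r, by = 2))
  tgt <- paste0("p", seq(2, 2 * r, by = 2))
  # pair-swap symmetry of the two hybrid edges: cheap pre-deduplication key
  swap <- if (r == 2) c(p1 = "p3", p2 = "p4", p3 = "p1", p4 = "p2") else NULL
  seen_pre <- new.env(hash = TRUE, parent = emptyenv())
  seen <- new.env(hash = TRUE, parent = emptyenv())
  found <- list()
  for (tree in enumerate_trees(seq_len(n))) {
    for (st in .place_points(tree$edges, 2 * r)) {
      em <- rbind(st, cbind(src, tgt))
      if (anyDuplicated(paste(em[, 1], em[, 2]))) next
      if (!.is_acyclic_em(em)) next
      key <- paste(sort(paste(em[, 1], em[, 2])), collapse = ";")
      if (!is.null(swap)) {
        em2 <- em
        hit <- em2 %in% names(swap)
        em2[hit] <- swap[em2[hit]]
        key2 <- paste(sort(paste(em2[, 1], em2[, 2])), collapse = ";")
        if (key2 < key) key <- key2
      }
      if (!is.null(seen_pre[[key]])) next
      seen_pre[[key]] <- TRUE
      cand <- phylo_network(em, tree$labels, validate = FALSE)
      if (length(validate_network(cand)) > 0) next
      code <- canonical_code(cand)
      if (is.null(seen[[code]])) {
        seen[[code]] <- TRUE
        found[[length(found) + 1L]] <- cand
      }
    }
  }
  found
}

#' Enumerate all labeled binary networks with n leaves and r reticulations
#'
#' Generates every valid binary phylogenetic network on leaf set
#' `{1, ..., n}` with exactly `r` reticulations, exactly once up to
#' equivalence. Results for each (n, r) stratum are memoised for the
#' session.
#'
#' @param n number of leaves (>= 1).
#' @param r number of reticulations (0, 1 or 2; the generation scheme is
#'   certified complete only up to two reticulations).
#' @param class optional [class_spec()]; only members are returned.
#' @param guard keep the default desk-scale budget n <= 4 for r >= 1 (and
#'   n <= 6 for r = 0); set `FALSE` to lift it.
#' @return List of `phylo_network` objects.
#' @examples
#' length(enumerate_networks(3, 0))  # 3 labeled trees
#' @export
enumerate_networks <- function(n, r, class = NULL, guard = TRUE) {
  stopifnot(n >= 1, r >= 0)
  if (r > 2)
    stop("exhaustive generation is certified complete only for r <= 2")
  if (guard && ((r == 0 && n > 6) || (r > 0 && n > 4)))
    stop("enumeration budget guard: n <= 4 for r in 1..2, n <= 6 for r = 0 ",
         "(set guard = FALSE to override)")
  key <- paste0("n", n, ".r", r)
  if (is.null(.nc_cache[[key]])) {
    .nc_cache[[key]] <- if (r == 0) enumerate_trees(seq_len(n)) else
      .networks_from_trees(n, r)
  }
  nets <- .nc_cache[[key]]
  if (!is.null(class)) {
    stopifnot(inherits(class, "class_spec"))
    nets <- Filter(function(net) isTRUE(class$predicate(net)), nets)
  }
  nets
}

#' Exact census counts for all classes at small (n, r)
#'
#' Tabulates, for every leaf number n up to `n_max` and reticulation number
#' r up to `r_max`, the number of networks on leaf set \[n\] in each of the
#' seven classes (plus the count of all networks), and derives the
#' leaf-subset aggregates |N_n| via the binomial convolution
#' sum_j C(n, j) * count(j) (aggregates are computed arithmetically, never
#' by re-enumerating over subsets).
#'
#' @param n_max,r_max census bounds.
#' @param guard forwarded to [enumerate_networks()].
#' @return An object of class `count_table`: a list with `counts` (long
#'   data frame n / r / class / count) and `union_counts` (data frame
#'   n / class / count of networks with leaf set any nonempty subset of \[n\]
#'   and at most `r_max` reticulations).
#' @examples
#' ct <- count_table(3, 1)
#' subset(ct$counts, class == "tree")
#' @export
count_table <- function(n_max, r_max, guard = TRUE) {
  class_names <- c("all", network_classes())
  rows <- list()
  for (n in seq_len(n_max)) {
    for (r in 0:r_max) {
      nets <- enumerate_networks(n, r, guard = guard)
      keys <- gsub("-", "_", network_classes())
      cnt <- stats::setNames(numeric(length(keys) + 1), c("all", keys))
      cnt["all"] <- length(nets)
      if (length(nets) > 0) {
        cls <- vapply(nets, classify_network, logical(length(keys)))
        cnt[keys] <- rowSums(cls)[keys]
      }
      rows[[length(rows) + 1L]] <-
        data.frame(n = n, r = r, class = class_names,
                   count = unname(cnt), row.names = NULL)
    }
  }
  counts <- do.call(rbind, rows)
  per_n <- stats::aggregate(count ~ n + class, data = counts, FUN = sum)
  union_rows <- list()
  for (cl in class_names) {
    tot <- per_n$count[per_n$class == cl][order(per_n$n[per_n$class == cl])]
    for (n in seq_len(n_max)) {
      j <- seq_len(n)
      union_rows[[length(union_rows) + 1L]] <-
        data.frame(n = n, class = cl,
                   count = sum(choose(n, j) * tot[j]))
    }
  }
  structure(list(counts = counts, union_counts = do.call(rbind, union_rows),
                 n_max = n_max, r_max = r_max),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> n <= %d, r <= %d\n", x$n_max, x$r_max))
  wide <- stats::reshape(x$counts, direction = "wide",
                         idvar = c("n", "r"), timevar = "class")
  names(wide) <- sub("^count\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
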