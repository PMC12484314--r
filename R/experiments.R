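# Monte-Carlo experiments: uniform random trees, pendant subtree-shape
# containment, and empirical/asymptotic class-ratio tables.

# array-based uniform sampler over tree topologies on a fixed label set:
# leaf j+1 attaches to one of the 2j-1 edges (the ancestral root edge
# included) uniformly, which makes every labeled topology equally likely
.sample_tree_arrays <- function(labels) {
  n <- length(labels)
  nv <- 2L * n
  par <- integer(nv)                 # parent of each vertex (0 = none)
  lab <- rep(NA_integer_, nv)
  # vertex 1 = root, vertex 2 = first leaf
  par[2] <- 1L
  lab[2] <- labels[1]
  epar <- integer(2L * n - 1L)       # edge list: epar[i] -> echi[i]
  echi <- integer(2L * n - 1L)
  epar[1] <- 1L; echi[1] <- 2L
  n_edges <- 1L
  nxt <- 2L
  for (j in seq_len(n - 1L)) {
    e <- sample.int(n_edges, 1L)
    t <- nxt + 1L; v <- nxt + 2L; nxt <- nxt + 2L
    old_child <- echi[e]
    par[t] <- epar[e]; par[old_child] <- t; par[v] <- t
    lab[v] <- labels[j + 1L]
    echi[e] <- t
    epar[n_edges + 1L] <- t; echi[n_edges + 1L] <- old_child
    epar[n_edges + 2L] <- t; echi[n_edges + 2L] <- v
    n_edges <- n_edges + 2L
  }
  list(epar = epar, echi = echi, lab = lab, nv = nxt)
}

.arrays_to_network <- function(ar) {
  ids <- paste0("x", seq_len(ar$nv))
  em <- cbind(ids[ar$epar], ids[ar$echi])
  leaves <- which(!is.na(ar$lab))
  phylo_network(em, stats::setNames(ar$lab[leaves], ids[leaves]),
                validate = FALSE)
}

#' Sample a tree uniformly from the topologies on \[n\]
#'
#' Draws a labeled rooted binary tree uniformly at random from the
#' (2n-3)!! topologies on leaf set \{1, ..., n\}, by sequentially attaching
#' leaf j+1 to one of the 2j-1 edges (ancestral root edge included) chosen
#' uniformly. Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param n number of leaves (>= 1).
#' @return A `phylo_network` with r = 0.
#' @examples
#' set.seed(1)
#' sample_tree(5)
#' @export
sample_tree <- function(n) {
  stopifnot(n >= 1)
  .arrays_to_network(.sample_tree_arrays(seq_len(n)))
}

# log (2j-3)!! for vectors of j >= 1
.ldfact <- function(j) {
  ifelse(j == 1, 0, lgamma(2 * j - 1) - (j - 1) * log(2) - lgamma(j))
}

#' Sample a tree uniformly from all leaf subsets of \[n\]
#'
#' Draws uniformly from the set of trees whose leaf set is any nonempty
#' subset of \{1, ..., n\}: the leaf-set size j is drawn with probability
#' `C(n, j) (2j-3)!! / |T_n|`, the subset uniformly among size-j subsets,
#' and the topology uniformly on that subset.
#'
#' @param n maximal label (>= 1).
#' @return A `phylo_network` with r = 0 and leaf labels a subset of \[n\].
#' @examples
#' set.seed(1)
#' sort(unname(sample_from_union(6)$labels))
#' @export
sample_from_union <- function(n) {
  stopifnot(n >= 1)
  j <- seq_len(n)
  lw <- lchoose(n, j) + .ldfact(j)
  w <- exp(lw - max(lw))
  size <- sample.int(n, 1L, prob = w)
  subset <- sort(sample.int(n, size))
  .arrays_to_network(.sample_tree_arrays(subset))
}

#' Pendant subtree-shape containment
#'
#' Tests whether some vertex of a tree has a pendant subtree (the full
#' subtree descending from that vertex) of exactly the given unlabeled
#' shape.
#'
#' @param tree a valid `phylo_network` with r = 0.
#' @param shape a `tree_shape` (see [shape_of()]), or a preset name.
#' @return `TRUE` or `FALSE`.
#' @examples
#' cat4 <- read_enewick("(((1,2),3),4);")
#' contains_pendant_shape(cat4, "balanced4")  # FALSE: one cherry only
#' contains_pendant_shape(cat4, "cherry")
#' @export
contains_pendant_shape <- function(tree, shape) {
  if (is.character(shape)) shape <- shape_of(shape)
  .stop_if_invalid(tree)
  ix <- .net_index(tree)
  if (any(ix$kind == "retic"))
    stop("contains_pendant_shape requires a tree (r = 0)")
  codes <- .shape_code(ix, at = TRUE)
  unclass(shape) %in% codes
}

# fast internal containment check on sampler arrays: bottom-up shape codes,
# pruned to subtrees no larger than the target shape
.arrays_contain_shape <- function(ar, shape_str, shape_leaves) {
  nv <- ar$nv
  nl <- integer(nv)                  # leaves below
  code <- character(nv)
  kids <- vector("list", nv)
  for (i in seq_along(ar$epar))
    kids[[ar$epar[i]]] <- c(kids[[ar$epar[i]]], ar$echi[i])
  # children precede parents nowhere in construction order, so process by
  # decreasing depth: compute an order via repeated passes is wasteful --
  # instead do an explicit post-order traversal from the root
  stack <- 1L
  order_out <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_out <- c(order_out, v)
    stack <- c(stack, kids[[v]])
  }
  for (v in rev(order_out)) {
    ks <- kids[[v]]
    if (length(ks) == 0) {
      nl[v] <- 1L
      code[v] <- "*"
      if (shape_str == "*") return(TRUE)
    } else if (length(ks) == 1L) {   # root
      nl[v] <- nl[ks]
      code[v] <- code[ks]
    } else {
      nl[v] <- nl[ks[1]] + nl[ks[2]]
      if (nl[v] > shape_leaves) {
        code[v] <- ""
      } else {
        a <- code[ks[1]]; b <- code[ks[2]]
        if (nzchar(a) && nzchar(b)) {
          code[v] <- if (a <= b) paste0("(", a, b, ")") else
            paste0("(", b, a, ")")
          if (code[v] == shape_str) return(TRUE)
        } else code[v] <- ""
      }
    }
  }
  FALSE
}

.wilson_ci <- function(hits, reps, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- hits / reps
  den <- 1 + z^2 / reps
  centre <- (p + z^2 / (2 * reps)) / den
  half <- z * sqrt(p * (1 - p) / reps + z^2 / (4 * reps^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Monte-Carlo estimate of pendant-shape containment probability
#'
#' Estimates the probability that a tree drawn uniformly from all trees
#' with leaf set a nonempty subset of \[n\] (or, with `sampler = "fixed"`,
#' from the topologies on exactly \[n\]) contains a pendant subtree of the
#' given shape. Reports a Wilson 95% confidence interval. Deterministic for
#' a given seed.
#'
#' @details Two short-circuits avoid pointless simulation: the single-leaf
#'   shape is contained in every tree, and every binary tree with at least
#'   two leaves contains a cherry, so for the cherry shape the estimate is
#'   reported as exactly 1 for n >= 2 without sampling (under the union
#'   sampler this is the probability conditional on the sampled tree having
#'   at least two leaves; the single-leaf atom has probability
#'   n / |T_n|, already below 1e-3 at n = 8).
#'
#' @param n leaf-set parameter.
#' @param shape a `tree_shape` or preset name (see [shape_of()]).
#' @param reps number of Monte-Carlo draws.
#' @param seed RNG seed (applied locally; the global RNG state is
#'   restored).
#' @param sampler `"union"` (default, all leaf subsets of \[n\]) or
#'   `"fixed"` (leaf set exactly \[n\]).
#' @return A list with `n`, `shape`, `reps`, `hits`, `estimate`, `ci95`,
#'   `seed`.
#' @examples
#' containment_probability(16, "balanced4", reps = 200, seed = 42)$estimate
#' @export
containment_probability <- function(n, shape, reps = 2000, seed = 42,
                                    sampler = c("union", "fixed")) {
  sampler <- match.arg(sampler)
  stopifnot(reps >= 1)
  if (is.character(shape)) shape <- shape_of(shape)
  shape_str <- unclass(shape)
  res <- list(n = n, shape = shape_str, reps = reps, seed = seed)
  if (shape_str == "*" || (shape_str == "(**)" && n >= 2)) {
    res$hits <- reps
    res$estimate <- 1
    res$ci95 <- c(lower = 1, upper = 1)
    return(res)
  }
  shape_leaves <- lengths(regmatches(shape_str,
                                     gregexpr("\\*", shape_str)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(reps)) {
    ar <- if (sampler == "union") {
      j <- seq_len(n)
      lw <- lchoose(n, j) + .ldfact(j)
      w <- exp(lw - max(lw))
      size <- sample.int(n, 1L, prob = w)
      .sample_tree_arrays(sort(sample.int(n, size)))
    } else {
      .sample_tree_arrays(seq_len(n))
    }
    if (.arrays_contain_shape(ar, shape_str, shape_leaves)) hits <- hits + 1L
  }
  res$hits <- hits
  res$estimate <- hits / reps
  res$ci95 <- .wilson_ci(hits, reps)
  res
}

#' Ratio table of one class inside another
#'
#' Tabulates |A intersect B_n| / |B_n| over a range of n, either from the
#' exact enumeration census (`mode = "census"`: counts aggregated over all
#' leaf subsets of \[n\] with reticulation number up to `r_max`) or from the
#' registered asymptotic forms after binomial transfer
#' (`mode = "asymptotic"`). In asymptotic mode the limit from
#' [limit_ratio()] is attached as attribute `"limit"`.
#'
#' @param numerator,denominator in census mode, [class_spec()] objects (or
#'   class names); in asymptotic mode, registry names (see
#'   [asym_registry()]).
#' @param n_range integer vector of n values.
#' @param mode `"census"` or `"asymptotic"`.
#' @param r_max census reticulation bound.
#' @param guard forwarded to the enumerator.
#' @return A data frame with columns `n` and `ratio`.
#' @examples
#' ratio_table("SN", "GN", c(10, 100), mode = "asymptotic")
#' @export
ratio_table <- function(numerator, denominator, n_range,
                        mode = c("census", "asymptotic"), r_max = 2,
                        guard = TRUE) {
  mode <- match.arg(mode)
  if (mode == "census") {
    if (is.character(numerator)) numerator <- class_spec(numerator)
    if (is.character(denominator)) denominator <- class_spec(denominator)
    ratios <- vapply(n_range, function(n) {
      num <- 0; den <- 0
      for (jj in seq_len(n)) {
        cnum <- 0; cden <- 0
        for (r in 0:r_max) {
          nets <- enumerate_networks(jj, r, guard = guard)
          inb <- vapply(nets, function(nw) isTRUE(denominator$predicate(nw)),
                        logical(1))
          ina <- vapply(nets, function(nw) isTRUE(numerator$predicate(nw)),
                        logical(1))
          cden <- cden + sum(inb)
          cnum <- cnum + sum(ina & inb)
        }
        num <- num + choose(n, jj) * cnum
        den <- den + choose(n, jj) * cden
      }
      num / den
    }, numeric(1))
    return(data.frame(n = n_range, ratio = ratios))
  }
  fa <- binomial_transfer(asym_registry(numerator))
  fb <- binomial_transfer(asym_registry(denominator))
  ratios <- exp(asymptotic_value(fa, n_range) -
                  asymptotic_value(fb, n_range))
  out <- data.frame(n = n_range, ratio = ratios)
  attr(out, "limit") <- limit_ratio(fa, fb)
  out
}
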