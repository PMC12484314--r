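# Fixtures built in code, and a brute-force labeled-isomorphism oracle that
# is independent of the package's canonicalization.

`%||%` <- function(a, b) if (is.null(a)) b else a

# bare gall: top t with side vertices u, v meeting in reticulation r whose
# child is leaf 1; side leaves 2 and 3
fx_bare_gall <- function() {
  phylo_network(rbind(
    c("rho", "t"), c("t", "u"), c("t", "v"),
    c("u", "r"), c("v", "r"), c("r", "l1"),
    c("u", "l2"), c("v", "l3")),
    c(l1 = 1, l2 = 2, l3 = 3))
}

# triangle: a -> b, a -> r, b -> r; the edge (a, r) is a shortcut;
# reticulation child is a leaf
fx_triangle <- function() {
  phylo_network(rbind(
    c("rho", "a"), c("a", "b"), c("a", "r"),
    c("b", "r"), c("b", "l1"), c("r", "l2")),
    c(l1 = 1, l2 = 2))
}

# smallest network with a reticulation whose child is a reticulation:
# w -> u, w -> r1, u -> r1, u -> r2, r1 -> r2, r2 -> leaf
fx_stacked <- function() {
  phylo_network(rbind(
    c("rho", "w"), c("w", "u"), c("w", "r1"),
    c("u", "r1"), c("u", "r2"), c("r1", "r2"),
    c("r2", "l1")),
    c(l1 = 1))
}

# tree-child network whose bottom reticulation r2 lies in two reticulation
# cycles (tops t1 and t0); r1 is internal to one of r2's cycles
fx_two_cycles <- function() {
  phylo_network(rbind(
    c("rho", "t0"), c("t0", "t1"), c("t0", "t2"),
    c("t1", "r1"), c("t1", "w"), c("t2", "r1"), c("t2", "l3"),
    c("r1", "u"), c("u", "r2"), c("u", "l2"),
    c("w", "r2"), c("w", "l1"), c("r2", "l4")),
    c(l1 = 1, l2 = 2, l3 = 3, l4 = 4))
}

# the single-reticulation normal gall used throughout: reticulation child
# is leaf 2, side leaves 1 and 3
fx_normal_gall <- function() read_enewick("((1,(2)#H1),(#H1,3));")

perms_of <- function(n) {
  if (n == 0) return(matrix(integer(0), 1, 0))
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

# brute-force equivalence: try every assignment of internal vertices, with
# leaves matched by label
bf_equivalent <- function(a, b) {
  ea <- a$edges; eb <- b$edges
  va <- sort(unique(c(ea))); vb <- sort(unique(c(eb)))
  if (length(va) != length(vb) || nrow(ea) != nrow(eb)) return(FALSE)
  la <- a$labels; lb <- b$labels
  if (!identical(sort(unname(la)), sort(unname(lb)))) return(FALSE)
  leaf_a <- names(la)[order(la)]; leaf_b <- names(lb)[order(lb)]
  int_a <- setdiff(va, leaf_a); int_b <- setdiff(vb, leaf_b)
  if (length(int_a) != length(int_b)) return(FALSE)
  key_b <- paste(sort(paste(eb[, 1], eb[, 2])), collapse = ";")
  pm <- perms_of(length(int_a))
  for (rw in seq_len(nrow(pm))) {
    map <- c(stats::setNames(leaf_b, leaf_a),
             stats::setNames(int_b[pm[rw, ]], int_a))
    key_a <- paste(sort(paste(map[ea[, 1]], map[ea[, 2]])), collapse = ";")
    if (key_a == key_b) return(TRUE)
  }
  FALSE
}

# small censuses shared across test files (memoised by the package)
census_n3r1 <- function() {
  c(enumerate_networks(3, 0), enumerate_networks(3, 1))
}
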