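# Exact counting sequences: double factorials, Catalan numbers, the
# leaf-subset union of trees, the simplicial tree-child closed form, and
# exact binomial convolutions of counting sequences. All values are exact
# big integers.

#' Number of labeled rooted binary trees
#'
#' The number of rooted binary tree topologies on a fixed set of l labeled
#' leaves is the double factorial (2l-3)!! = (2l-3)(2l-5)...1, with the
#' empty product equal to 1 (so one tree on a single leaf).
#'
#' @param l number of leaves (>= 1).
#' @return A [bigint()].
#' @examples
#' as.numeric(trees_count(4))  # 15
#' @export
trees_count <- function(l) {
  stopifnot(l >= 1)
  out <- bigint(1)
  if (l >= 2)
    for (odd in seq(1, 2 * l - 3, by = 2)) out <- bi_mul_small(out, odd)
  out
}

#' Catalan numbers
#'
#' C_j = choose(2j, j) / (j + 1), computed exactly.
#'
#' @param j index (>= 0).
#' @return A [bigint()].
#' @examples
#' as.numeric(catalan(5))  # 42
#' @export
catalan <- function(j) {
  stopifnot(j >= 0)
  out <- bigint(1)
  if (j >= 1) {
    for (i in seq_len(j)) {
      # C_i = C_{i-1} * 2(2i - 1) / (i + 1)
      out <- bi_div_small(bi_mul_small(out, 2 * (2 * i - 1)), i + 1)
    }
  }
  out
}

#' Number of trees over all nonempty leaf subsets of \[n\]
#'
#' Counts the trees whose leaf set is any nonempty subset of {1, ..., n}:
#' the binomial sum over subset sizes, sum_j C(n, j) (2j-3)!!. Two
#' rewritings in terms of Catalan numbers evaluate to the same integer and
#' are provided as independent computation routes:
#' `"catalan"` computes n! * sum_j C_{j-1} / ((n-j)! 2^(j-1)) and
#' `"catalan2"` computes (n!/2^(n-1)) * sum_j 2^j C_{n-j-1} / j!,
#' both carried out exactly over big integers (division last).
#'
#' @param n maximal label (>= 1).
#' @param method computation route; all agree exactly.
#' @return A [bigint()].
#' @examples
#' as.numeric(forest_union_count(5))  # 225
#' @export
forest_union_count <- function(n, method = c("binomial", "catalan", "catalan2")) {
  stopifnot(n >= 1)
  method <- match.arg(method)
  if (method == "binomial") {
    # term_j = C(n, j) (2j-3)!!; term_1 = n
    term <- bigint(n)
    total <- term
    j <- 1
    while (j < n) {
      # term_{j+1} = term_j * (n - j) / (j + 1) * (2j - 1)
      term <- bi_mul_small(
        bi_div_small(bi_mul_small(term, n - j), j + 1), 2 * j - 1)
      total <- bi_add(total, term)
      j <- j + 1
    }
    return(total)
  }
  cats <- vector("list", n)          # catalan(0), ..., catalan(n - 1)
  cats[[1]] <- bigint(1)
  for (i in seq_len(n - 1))
    cats[[i + 1]] <- bi_div_small(bi_mul_small(cats[[i]], 2 * (2 * i - 1)),
                                  i + 1)
  .pow2_div <- function(x, e) {
    while (e > 0) {
      chunk <- min(e, 20)
      x <- bi_div_small(x, 2^chunk)
      e <- e - chunk
    }
    x
  }
  .pow2_mul <- function(x, e) {
    while (e > 0) {
      chunk <- min(e, 30)
      x <- bi_mul_small(x, 2^chunk)
      e <- e - chunk
    }
    x
  }
  if (method == "catalan") {
    # sum_j [ n!/(n-j)! * C_{j-1} ] / 2^(j-1), divisions exact per term
    total <- bigint(0)
    falling <- bigint(1)             # n! / (n - j)!
    for (j in seq_len(n)) {
      falling <- bi_mul_small(falling, n - j + 1)
      term <- .pow2_div(bi_mul(falling, cats[[j]]), j - 1)
      total <- bi_add(total, term)
    }
    return(total)
  }
  # catalan2: (n!/2^(n-1)) sum_{j=0}^{n-1} 2^j C_{n-j-1} / j!
  # computed as sum_j [ 2^j * C_{n-j-1} * n!/j! ], then one division
  total <- bigint(0)
  for (j in 0:(n - 1)) {
    nf_over_jf <- bigint(1)          # n!/j! = (j+1) * ... * n
    for (i in seq(j + 1, n)) nf_over_jf <- bi_mul_small(nf_over_jf, i)
    term <- .pow2_mul(bi_mul(nf_over_jf, cats[[n - j]]), j)
    total <- bi_add(total, term)
  }
  .pow2_div(total, n - 1)
}

#' Simplicial tree-child networks: exact closed form
#'
#' The number of simplicial tree-child networks with exactly k
#' reticulations on leaf set {1, ..., l} has the closed form
#' `choose(l, k) * (2l-2)! / (2^(l-1) * (l-k-1)!)`. At k = 0 this reduces
#' to the tree count (2l-3)!!.
#'
#' @param l number of leaves (>= 1).
#' @param k number of reticulations, `0 <= k <= l - 1`.
#' @return A [bigint()].
#' @examples
#' as.numeric(stc_count(3, 1))  # 18
#' @export
stc_count <- function(l, k) {
  stopifnot(l >= 1, k >= 0)
  if (k >= l) stop("stc_count requires k <= l - 1")
  # (2l-2)!/(l-k-1)! = (l-k) * (l-k+1) * ... * (2l-2)
  out <- bigint(1)
  if (2 * l - 2 >= l - k)
    for (i in seq(l - k, 2 * l - 2)) out <- bi_mul_small(out, i)
  # multiply by choose(l, k) via falling factorial / k!
  for (i in seq_len(k)) out <- bi_div_small(bi_mul_small(out, l - i + 1), i)
  e <- l - 1
  while (e > 0) {
    chunk <- min(e, 20)
    out <- bi_div_small(out, 2^chunk)
    e <- e - chunk
  }
  out
}

#' Exact binomial convolution of a counting sequence
#'
#' Computes sum_{j=1}^{n} C(n, j) a_j exactly, where a_j is supplied as a
#' function returning a [bigint()]. This is the operation that aggregates a
#' fixed-leaf-set counting sequence over all nonempty leaf subsets of \[n\].
#'
#' @param seq_fun function of j returning a [bigint()] (e.g. [trees_count()]).
#' @param n upper limit (>= 1).
#' @return A [bigint()].
#' @examples
#' # constant sequence 1 gives 2^n - 1
#' as.numeric(binomial_convolution(function(j) bigint(1), 5))
#' @export
binomial_convolution <- function(seq_fun, n) {
  stopifnot(n >= 1)
  total <- bigint(0)
  binom <- bigint(1)                 # C(n, 0)
  for (j in seq_len(n)) {
    binom <- bi_div_small(bi_mul_small(binom, n - j + 1), j)
    term <- bi_mul(binom, bigint(seq_fun(j)))
    total <- bi_add(total, term)
  }
  total
}
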