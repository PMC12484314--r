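# Minimal exact big-integer arithmetic on nonnegative integers.
#
# Representation: little-endian numeric vector of limbs in base 1e6, stored
# as doubles. All intermediate products stay below 2^53 (limb * limb * nlimbs
# <= 1e12 * ~4000 for the sizes used here), so arithmetic is exact.

.BI_BASE <- 1e6

#' Exact big integers
#'
#' Arbitrary-precision nonnegative integers used by the counting routines
#' (double factorials, Catalan numbers, binomial convolutions) where exact
#' values exceed the range of doubles. Supports addition, multiplication,
#' exact division, comparison, `log()`, `format()` and `as.numeric()`.
#'
#' @param x a single nonnegative integer-valued number, or a decimal string.
#' @return An object of class `bigint`.
#' @examples
#' format(bi_mul(bigint(2^30), bigint(2^30)))
#' log(bigint("1000000000000"))
#' @export
bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L, grepl("^[0-9]+$", x))
    digs <- as.integer(strsplit(x, "")[[1]])
    v <- bigint(0)
    for (d in digs) v <- bi_add(bi_mul_small(v, 10), bigint(d))
    return(v)
  }
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% .BI_BASE)
    x <- x %/% .BI_BASE
    if (x == 0) break
  }
  structure(list(limbs = limbs), class = "bigint")
}

.bi_trim <- function(limbs) {
  n <- length(limbs)
  while (n > 1L && limbs[n] == 0) n <- n - 1L
  structure(list(limbs = limbs[seq_len(n)]), class = "bigint")
}

.bi_carry <- function(limbs) {
  # propagate carries; limbs may exceed base but must be < 2^53
  i <- 1L
  while (i <= length(limbs)) {
    if (limbs[i] >= .BI_BASE) {
      q <- limbs[i] %/% .BI_BASE
      limbs[i] <- limbs[i] %% .BI_BASE
      if (i == length(limbs)) limbs <- c(limbs, 0)
      limbs[i + 1L] <- limbs[i + 1L] + q
    }
    i <- i + 1L
  }
  limbs
}

#' @rdname bigint
#' @param a,b `bigint` objects (or single numbers coerced with [bigint()]).
#' @export
bi_add <- function(a, b) {
  a <- bigint(a); b <- bigint(b)
  n <- max(length(a$limbs), length(b$limbs))
  la <- c(a$limbs, numeric(n - length(a$limbs)))
  lb <- c(b$limbs, numeric(n - length(b$limbs)))
  .bi_trim(.bi_carry(la + lb))
}

#' @rdname bigint
#' @param s a single nonnegative integer scalar (< 2^40).
#' @export
bi_mul_small <- function(a, s) {
  a <- bigint(a)
  stopifnot(s >= 0, s == floor(s), s * .BI_BASE < 2^53)
  if (s == 0) return(bigint(0))
  .bi_trim(.bi_carry(a$limbs * s))
}

#' @rdname bigint
#' @details `bi_div_small` performs exact division and errors on a nonzero
#'   remainder; the counting formulas only ever divide exactly.
#' @export
bi_div_small <- function(a, s) {
  a <- bigint(a)
  stopifnot(s >= 1, s == floor(s), s < 2^26)
  limbs <- a$limbs
  rem <- 0
  for (i in rev(seq_along(limbs))) {
    cur <- rem * .BI_BASE + limbs[i]
    limbs[i] <- cur %/% s
    rem <- cur %% s
  }
  if (rem != 0) stop("bi_div_small: division is not exact")
  .bi_trim(limbs)
}

#' @rdname bigint
#' @export
bi_mul <- function(a, b) {
  a <- bigint(a); b <- bigint(b)
  la <- a$limbs; lb <- b$limbs
  if (length(la) < length(lb)) { tmp <- la; la <- lb; lb <- tmp }
  if (length(lb) > 9000) stop("bigint multiplication size guard exceeded")
  out <- numeric(length(la) + length(lb))
  for (j in seq_along(lb)) {
    if (lb[j] == 0) next
    idx <- seq_along(la) + j - 1L
    # partial sums stay below 9000 * (1e6)^2 < 2^53, so one carry pass at
    # the end is exact
    out[idx] <- out[idx] + la * lb[j]
  }
  .bi_trim(.bi_carry(out))
}

#' @export
format.bigint <- function(x, ...) {
  limbs <- rev(x$limbs)
  head <- format(limbs[1], scientific = FALSE)
  rest <- vapply(limbs[-1], function(l) formatC(l, width = 6, flag = "0",
                                               format = "d"), character(1))
  paste0(head, paste(rest, collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.numeric.bigint <- function(x, ...) {
  n <- length(x$limbs)
  sum(x$limbs * .BI_BASE^(seq_len(n) - 1))
}

#' @export
log.bigint <- function(x, base = exp(1)) {
  limbs <- x$limbs
  n <- length(limbs)
  if (n == 1L) {
    if (limbs[1] == 0) return(-Inf)
    return(log(limbs[1], base = base))
  }
  k <- min(n, 3L)  # top ~18 decimal digits carry full double precision
  top <- sum(limbs[n - seq_len(k) + 1L] * .BI_BASE^(-(seq_len(k) - 1L)))
  (log(top) + (n - 1) * log(.BI_BASE)) / log(base)
}

#' @export
`==.bigint` <- function(e1, e2) {
  e1 <- bigint(e1); e2 <- bigint(e2)
  length(e1$limbs) == length(e2$limbs) && all(e1$limbs == e2$limbs)
}
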