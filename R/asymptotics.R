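# Registry of first-order asymptotic growth forms
#     a_l ~ C * l^alpha * gamma^l * l^(m*l) * exp(s * (3l)^(1/3)),
# the Laplace-method transfer of binomial convolutions, and limit-ratio
# computation. Constants are stored as exact closed-form log-expressions;
# all l-dependent evaluation happens in log space.

# least-negative real zero of the Airy function Ai (DLMF 9.9.1, a_1)
.AIRY_A1 <- -2.338107410459767

#' Asymptotic growth forms
#'
#' Represents a first-order growth law
#' `C * l^alpha * gamma^l * l^(m l) * exp(s (3l)^(1/3))` for a counting
#' sequence, together with the kind of bound it expresses (`"tilde"` for an
#' asymptotic equivalent, `"Theta"` or `"Omega"` for order bounds with
#' unspecified constant).
#'
#' @param name identifier.
#' @param logC natural log of the multiplicative constant C (NA for
#'   Theta/Omega forms whose constant is unspecified).
#' @param alpha polynomial exponent (rational, as double).
#' @param log_gamma natural log of the geometric base gamma.
#' @param m superexponential order: the sequence grows like `l^(m l)`
#'   (m = 1 is tree scale, m = 2 network scale).
#' @param s coefficient of the stretched-exponential term `(3l)^(1/3)`
#'   (0 for all printed tilde-forms; the Airy-root constant for the
#'   tree-child Theta form).
#' @param bound one of `"tilde"`, `"Theta"`, `"Omega"`.
#' @param gamma_label the geometric base as printed (e.g. `"8/e^2"`).
#' @return An object of class `asym_form`.
#' @seealso [asym_registry()], [asymptotic_value()], [binomial_transfer()],
#'   [limit_ratio()]
#' @export
asym_form <- function(name, logC, alpha, log_gamma, m, s = 0,
                      bound = c("tilde", "Theta", "Omega"),
                      gamma_label = "") {
  bound <- match.arg(bound)
  if (bound == "tilde" && is.na(logC))
    stop("a tilde-form needs an explicit constant")
  structure(list(name = name, logC = logC, alpha = alpha,
                 log_gamma = log_gamma, m = m, s = s, bound = bound,
                 gamma_label = gamma_label),
            class = "asym_form")
}

#' @export
print.asym_form <- function(x, ...) {
  cat(sprintf("<asym_form> %s [%s]: C = %s, alpha = %g, gamma = %s, l^(%d l), s = %g\n",
              x$name, x$bound,
              if (is.na(x$logC)) "unspecified" else format(exp(x$logC)),
              x$alpha,
              if (nzchar(x$gamma_label)) x$gamma_label else
                format(exp(x$log_gamma)),
              x$m, x$s))
  invisible(x)
}

#' Registry of the printed asymptotic counting forms
#'
#' Returns the first-order asymptotic form of one of the counting sequences
#' handled by the package. Fixed-leaf-set sequences (per-l counts on leaf
#' set \{1, ..., l\}):
#' * `TREES`: labeled trees, `(2l-3)!! ~ (1/sqrt(2)) l^-1 (2/e)^l l^l`.
#' * `GN`: galled networks, `C = sqrt(2 e e^(1/4))/4`, gamma `8/e^2`, m = 2.
#' * `SN`: simplicial networks, `C = sqrt(2 sqrt(e))/4`, same scale.
#' * `SSN`: semi-simplicial networks, `C = sqrt(2 sqrt(e e^(1/4)))/4`.
#' * `GT`: galled trees, `C = sqrt(34)(sqrt(17)-1)/136`, gamma `8/e`, m = 1.
#' * `TC_k`, `NN_k`: tree-child / normal networks with exactly k
#'   reticulations, `C = 2^(k-1) sqrt(2)/k!`, alpha `2k-1`, gamma `2/e`.
#' * `GT_k`: galled trees with exactly k reticulations,
#'   `C = 2^(2k-1) sqrt(2)/(2k)!`.
#' * `STC_k`: simplicial tree-child networks with exactly k reticulations,
#'   `C = sqrt(2)/(2 k!)`.
#' * `TC_le_k`, `NN_le_k`, `GT_le_k`, `STC_le_k`: the at-most-k variants;
#'   first-order asymptotics equal the exactly-k forms since the k-th term
#'   dominates.
#' * `T_UNION`: trees over all leaf subsets of \[n\],
#'   `C = sqrt(e/2)` (equals the transfer of `TREES`).
#' * `TC_THETA`: the Theta-refinement of the tree-child growth order with
#'   the stretched-exponential Airy term (`s` = least-negative zero of Ai,
#'   about -2.3381074105); constant unspecified, so it supports evaluation
#'   up to a constant but not limit ratios.
#' * `TC_OMEGA`, `NN_OMEGA`: the Omega lower bounds `c^l l^(2l)` with both
#'   constants unspecified.
#'
#' @param name sequence identifier as above (use the `_k` spellings with
#'   the `k` argument).
#' @param k reticulation bound for the parameterized families.
#' @return An [asym_form()].
#' @examples
#' asym_registry("GN")
#' limit_ratio(binomial_transfer(asym_registry("SN")),
#'             binomial_transfer(asym_registry("GN")))  # exp(-3/8)
#' @export
asym_registry <- function(name, k = NULL) {
  lg2e <- log(2) - 1                       # log(2/e)
  if (name %in% c("TC_k", "NN_k", "GT_k", "STC_k",
                  "TC_le_k", "NN_le_k", "GT_le_k", "STC_le_k")) {
    stopifnot(is.numeric(k), k >= 1)
    base <- sub("_le_k$", "", name)
    base <- sub("_k$", "", base)
    logC <- switch(base,
      TC = , NN = (k - 1) * log(2) + 0.5 * log(2) - lfactorial(k),
      GT = (2 * k - 1) * log(2) + 0.5 * log(2) - lfactorial(2 * k),
      STC = 0.5 * log(2) - log(2) - lfactorial(k))
    return(asym_form(name, logC, alpha = 2 * k - 1, log_gamma = lg2e,
                     m = 1, gamma_label = "2/e"))
  }
  switch(name,
    TREES = asym_form("TREES", -0.5 * log(2), -1, lg2e, 1,
                      gamma_label = "2/e"),
    T_UNION = asym_form("T_UNION", 0.5 * (1 - log(2)), -1, lg2e, 1,
                        gamma_label = "2/e"),
    GN = asym_form("GN", 0.5 * (log(2) + 1 + 1 / 4) - log(4), -1,
                   log(8) - 2, 2, gamma_label = "8/e^2"),
    SN = asym_form("SN", 0.5 * (log(2) + 1 / 2) - log(4), -1,
                   log(8) - 2, 2, gamma_label = "8/e^2"),
    SSN = asym_form("SSN", 0.5 * (log(2) + 5 / 8) - log(4), -1,
                    log(8) - 2, 2, gamma_label = "8/e^2"),
    GT = asym_form("GT", 0.5 * log(34) + log(sqrt(17) - 1) - log(136), -1,
                   log(8) - 1, 1, gamma_label = "8/e"),
    TC_THETA = asym_form("TC_THETA", NA, -2 / 3, log(12) - 2, 2,
                         s = .AIRY_A1, bound = "Theta",
                         gamma_label = "12/e^2"),
    TC_OMEGA = asym_form("TC_OMEGA", NA, 0, NA, 2, bound = "Omega"),
    NN_OMEGA = asym_form("NN_OMEGA", NA, 0, NA, 2, bound = "Omega"),
    stop("unknown asymptotic form: ", name))
}

#' Evaluate an asymptotic form in log space
#'
#' Returns `log(C) + alpha log(l) + l log(gamma) + m l log(l) +
#' s (3l)^(1/3)`. For a `Theta` form the unspecified constant is taken as 1
#' (the value is meaningful up to an additive constant on the log scale);
#' for an `Omega` form with unspecified geometric base only the dominant
#' `m l log l + alpha log l` witness is returned, a lower bound up to
#' constants.
#'
#' @param form an [asym_form()].
#' @param l evaluation point (>= 2); vectorized.
#' @return Log-scale value(s).
#' @examples
#' exp(asymptotic_value(asym_registry("TREES"), 500) -
#'     log(trees_count(500)))  # close to 1
#' @export
asymptotic_value <- function(form, l) {
  stopifnot(inherits(form, "asym_form"), all(l >= 2))
  logC <- if (is.na(form$logC)) 0 else form$logC
  lgam <- if (is.na(form$log_gamma)) 0 else form$log_gamma
  val <- logC + form$alpha * log(l) + l * lgam + form$m * l * log(l) +
    form$s * (3 * l)^(1 / 3)
  if (form$bound != "tilde") attr(val, "bound") <- form$bound
  val
}

#' Laplace-method transfer of a binomial convolution
#'
#' If a_l follows a registered tilde-form, the leaf-subset aggregate
#' `sum_j C(n, j) a_j` follows the same form with the constant multiplied
#' by sqrt(e) when m = 1 (tree scale: the sum near j = n contributes a
#' convergent factor summing to e^(1/2)) and unchanged when m = 2 (network
#' scale: the last term dominates outright).
#'
#' @param form a tilde [asym_form()] with m in \{1, 2\}.
#' @return The transferred [asym_form()] (name suffixed `_UNION`).
#' @examples
#' binomial_transfer(asym_registry("TREES"))  # constant sqrt(e/2)
#' @export
binomial_transfer <- function(form) {
  stopifnot(inherits(form, "asym_form"))
  if (form$bound != "tilde")
    stop("binomial_transfer requires a tilde-form (asymptotic equivalent)")
  if (!form$m %in% c(1, 2)) stop("unsupported superexponential order m")
  logC <- if (form$m == 1) form$logC + 0.5 else form$logC
  asym_form(paste0(form$name, "_UNION"), logC, form$alpha, form$log_gamma,
            form$m, s = form$s, gamma_label = form$gamma_label)
}

#' Limiting ratio of two asymptotic forms
#'
#' Computes `lim a_n / b_n` for two tilde-forms: the ratio of constants
#' when the growth scales (m, gamma, s, alpha) agree; 0 when the
#' denominator dominates; an error when the numerator dominates (for class
#' ratios |C intersect N_n| / |N_n| this would contradict C being a
#' subclass of N).
#'
#' @param numerator,denominator tilde [asym_form()] objects (transfer them
#'   with [binomial_transfer()] first when comparing leaf-subset unions).
#' @return The limit as a double; when 0, the attribute `"dominance"`
#'   explains which growth component dominates.
#' @examples
#' limit_ratio(binomial_transfer(asym_registry("SN")),
#'             binomial_transfer(asym_registry("SSN")))  # exp(-1/16)
#' @export
limit_ratio <- function(numerator, denominator) {
  stopifnot(inherits(numerator, "asym_form"),
            inherits(denominator, "asym_form"))
  if (numerator$bound != "tilde" || denominator$bound != "tilde")
    stop("limit_ratio requires tilde-forms; Theta/Omega bounds lack the ",
         "constants needed for a limit")
  tol <- 1e-12
  comps <- list(
    c("superexponential order m", numerator$m, denominator$m),
    c("geometric base", numerator$log_gamma, denominator$log_gamma),
    c("stretched-exponential coefficient", numerator$s, denominator$s),
    c("polynomial exponent", numerator$alpha, denominator$alpha))
  for (cp in comps) {
    d <- as.numeric(cp[2]) - as.numeric(cp[3])
    if (d < -tol) {
      out <- 0
      attr(out, "dominance") <- paste0("denominator dominates: ", cp[1])
      return(out)
    }
    if (d > tol)
      stop("numerator dominates denominator (", cp[1],
           "); inconsistent with a subclass ratio")
  }
  exp(numerator$logC - denominator$logC)
}
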