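# The three kernels of the alpha-model, plus the published (erroneous)
# doubling variant kept as a comparator.

#' The model's factorial analogue Gamma_alpha
#'
#' `Gamma_alpha(n)` is the product `(1-alpha)(2-alpha)...(n-1-alpha)` (empty
#' for `n = 1`), the normalizing constant of the alpha-model on `n` leaves.
#' At `alpha = 0` it reduces to `(n-1)!`; at `alpha = 1/2` it equals
#' `(2n-3)!!/2^(n-1)`.
#'
#' @param n number of leaves, a positive integer.
#' @return An `alpha_fun`: a polynomial in alpha of degree `n - 1`.
#' @examples
#' gamma_alpha(2)                     # 1 - alpha
#' evaluate_at(gamma_alpha(8), "1/2") # 135135/128
#' @export
gamma_alpha <- function(n) {
  stopifnot(length(n) == 1, n == round(n))
  if (n < 1) stop("gamma_alpha is defined for n >= 1", call. = FALSE)
  P <- 1
  if (n >= 2) for (i in seq_len(n - 1)) P <- pmul(P, c(i, -1))
  new_alpha_fun(P, 1)
}

# integer polynomial 2*phi_alpha(a,b) = 2*C(a+b-2,a-1) + alpha*(C(a+b,a) - 4*C(a+b-2,a-1))
phi2_poly <- function(a, b) {
  cc <- ichoose(a + b, a)
  cp <- ichoose(a + b - 2, a - 1)
  ptrim(c(imul(2, cp), cc - imul(4, cp)))
}

# value of 2*phi at alpha = p/q, as an unreduced rational pair over q
phi2_rat <- function(a, b, p, q) {
  cc <- ichoose(a + b, a)
  cp <- ichoose(a + b - 2, a - 1)
  c(iadd(imul(2 * cp, q), imul(p, cc - 4 * cp)), q)
}

#' The split kernel phi_alpha
#'
#' `phi_alpha(a, b) = (alpha/2) * C(a+b, a) + (1 - 2*alpha) * C(a+b-2, a-1)`,
#' the unnormalized weight the model assigns to an internal node whose two
#' pending subtrees have `a` and `b` leaves.  It is symmetric in `(a, b)` and
#' linear in alpha; at `alpha = 0` it reduces to the Yule weight
#' `C(a+b-2, a-1)` and at `alpha = 1/2` to `C(a+b, a)/4`.
#'
#' @param a,b positive integer leaf counts of the two child subtrees.
#' @return An `alpha_fun`, a polynomial of degree at most 1 in alpha.
#' @examples
#' phi_alpha(1, 1)  # 1 - alpha
#' phi_alpha(4, 4)  # 20 - 5*alpha
#' @export
phi_alpha <- function(a, b) {
  check_split_args(a, b)
  rf_mul(rf_const(1, 2), new_alpha_fun(phi2_poly(a, b), 1))
}

#' The ordered-shape split kernel q_alpha
#'
#' `q_alpha(a, b) = Gamma_alpha(a) * Gamma_alpha(b) / Gamma_alpha(a + b) *
#' phi_alpha(a, b)`, returned canonically reduced.  The probability of an
#' ordered tree shape is the product of `q_alpha` over its numerical splits,
#' and `q_alpha` is the factor in the Markov branching recurrence for ordered
#' shapes.
#'
#' @inheritParams phi_alpha
#' @return An `alpha_fun`, symmetric in `(a, b)`.
#' @examples
#' q_alpha(1, 1)  # 1
#' q_alpha(2, 2)  # (1-a)/(3-a)
#' @export
q_alpha <- function(a, b) {
  check_split_args(a, b)
  num <- pmul(gamma_alpha(a)$num, gamma_alpha(b)$num)
  rf_mul(rf_make(num, gamma_alpha(a + b)$num), phi_alpha(a, b))
}

#' Ford's published (erroneous) split kernel
#'
#' The kernel of the published product formula for cladogram probabilities:
#' `qhat_alpha(a, b) = 2 * q_alpha(a, b)` when `a != b` and `q_alpha(a, b)`
#' when `a = b`.  It is shipped purely as a comparator: plugging it into the
#' published formula undercounts by a factor of 2 on any cladogram having an
#' internal node whose children carry equally many leaves but differently
#' shaped subtrees (see [prob_cladogram_ford_published()]).
#'
#' @inheritParams phi_alpha
#' @return An `alpha_fun`.
#' @export
qhat_alpha <- function(a, b) {
  check_split_args(a, b)
  q <- q_alpha(a, b)
  if (a == b) q else rf_mul(rf_const(2), q)
}

# Gamma_alpha(n) at alpha = p/q as the unreduced pair (prod(i*q - p), q^(n-1))
gamma_rat <- function(n, p, q) {
  acc <- 1
  if (n >= 2) for (i in seq_len(n - 1)) acc <- imul(acc, i * q - p)
  c(acc, ipow(q, n - 1))
}

check_split_args <- function(a, b) {
  if (length(a) != 1 || length(b) != 1 || a != round(a) || b != round(b) ||
      a < 1 || b < 1) {
    stop("split arguments must be positive integers", call. = FALSE)
  }
  invisible(TRUE)
}
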