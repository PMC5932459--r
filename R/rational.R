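# Exact rationals over guarded integer doubles.
#
# Internal fast path: a rational is the pair (num, den), den > 0, reduced.
# Addition goes through the lcm of the denominators rather than the plain
# cross-product, which keeps intermediates small when summing probabilities
# that share a common denominator (as all alpha-model probabilities at a fixed
# rational alpha do).

rat_norm <- function(n, d) {
  if (d == 0) stop("rational with zero denominator", call. = FALSE)
  if (d < 0) { n <- -n; d <- -d }
  if (n == 0) return(c(0, 1))
  g <- igcd(n, d)
  c(n / g, d / g)
}

rat_add_ <- function(a, b) {
  g <- igcd(a[2], b[2])
  db <- b[2] / g
  n <- iadd(imul(a[1], db), imul(b[1], a[2] / g))
  rat_norm(n, imul(a[2], db))
}

rat_mul_ <- function(a, b) {
  g1 <- igcd(abs(a[1]), b[2])
  g2 <- igcd(abs(b[1]), a[2])
  rat_norm(imul(a[1] / g1, b[1] / g2), imul(a[2] / g2, b[2] / g1))
}

rat_div_ <- function(a, b) {
  if (b[1] == 0) stop("division by zero rational", call. = FALSE)
  rat_mul_(a, c(b[2], b[1]))
}

rat_sub_ <- function(a, b) rat_add_(a, c(-b[1], b[2]))

# exact comparison: sign of a - b
rat_cmp_ <- function(a, b) {
  lhs <- imul(a[1], b[2])
  rhs <- imul(b[1], a[2])
  sign(lhs - rhs)
}

#' Exact rational numbers
#'
#' A minimal exact rational type used for all numeric probabilities in the
#' package.  Values are stored reduced, with a positive denominator, over
#' integer-valued doubles guarded against leaving the exactly representable
#' range (so arithmetic either is exact or raises an error).
#'
#' The usual arithmetic and comparison operators (`+`, `-`, `*`, `/`, `^`,
#' `==`, `<`, ...) work on `alpha_rational` objects (and mix with plain
#' integer-valued numerics).
#'
#' @param num integer-valued numerator.
#' @param den integer-valued denominator (nonzero).
#' @return An object of class `alpha_rational`.
#' @examples
#' rational(2520, 135135)            # reduces to 8/429
#' rational(1, 3) + rational(1, 6)   # 1/2
#' @export
rational <- function(num, den = 1) {
  if (inherits(num, "alpha_rational") && den == 1) return(num)
  stopifnot(length(num) == 1, length(den) == 1,
            num == round(num), den == round(den))
  chk_exact(num); chk_exact(den)
  new_rational(rat_norm(num, den))
}

new_rational <- function(nd) {
  structure(list(num = nd[1], den = nd[2]),
            class = c("alpha_rational", "alpha_num"))
}

as_rat_pair <- function(x) {
  if (inherits(x, "alpha_rational")) return(c(x$num, x$den))
  if (is.numeric(x) && length(x) == 1 && x == round(x)) return(c(chk_exact(x), 1))
  stop("cannot interpret object as an exact rational", call. = FALSE)
}

# arithmetic for exact rationals; the shared Ops.alpha_num group generic (see
# alpha-fun.R) routes here when no symbolic operand is involved
rational_ops <- function(generic, e1, e2) {
  if (missing(e2)) {  # unary
    a <- as_rat_pair(e1)
    return(switch(generic,
                  "+" = new_rational(a),
                  "-" = new_rational(c(-a[1], a[2])),
                  stop("unsupported unary operator for alpha_rational")))
  }
  if (generic == "^") {
    a <- as_rat_pair(e1)
    stopifnot(is.numeric(e2), e2 == round(e2))
    if (e2 < 0) { a <- c(a[2], a[1]); e2 <- -e2 }
    r <- c(1, 1)
    for (i in seq_len(e2)) r <- rat_mul_(r, a)
    return(new_rational(rat_norm(r[1], r[2])))
  }
  a <- as_rat_pair(e1); b <- as_rat_pair(e2)
  if (generic %in% c("+", "-", "*", "/")) {
    r <- switch(generic,
                "+" = rat_add_(a, b), "-" = rat_sub_(a, b),
                "*" = rat_mul_(a, b), "/" = rat_div_(a, b))
    return(new_rational(r))
  }
  s <- rat_cmp_(a, b)
  switch(generic,
         "==" = s == 0, "!=" = s != 0, "<" = s < 0,
         ">" = s > 0, "<=" = s <= 0, ">=" = s >= 0,
         stop(sprintf("operator '%s' not defined for alpha_rational", generic),
              call. = FALSE))
}

#' @export
as.double.alpha_rational <- function(x, ...) x$num / x$den

#' @export
format.alpha_rational <- function(x, ...) {
  if (x$den == 1) sprintf("%.0f", x$num) else sprintf("%.0f/%.0f", x$num, x$den)
}

#' @export
print.alpha_rational <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.alpha_rational <- function(x, ...) format(x)

is_rat_one <- function(x) x$num == 1 && x$den == 1
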