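# Rational functions of the parameter alpha.
#
# An `alpha_fun` is a canonically reduced ratio of two integer-coefficient
# polynomials: the polynomial gcd and any common integer content are divided
# out and the denominator's leading coefficient is positive, so two equal
# rational functions have identical representations and equality is
# structural.  This is the value type of every symbolic probability in the
# package (rational constants are the degree-0 case).

new_alpha_fun <- function(num, den) {
  structure(list(num = num, den = den), class = c("alpha_fun", "alpha_num"))
}

rf_make <- function(num, den) {
  num <- ptrim(num); den <- ptrim(den)
  if (!length(den)) stop("rational function with zero denominator", call. = FALSE)
  if (!length(num)) return(new_alpha_fun(double(0), 1))
  g <- pgcd_smart(num, den)
  if (pdeg(g) > 0) {
    num <- pdiv_exact(num, g)
    den <- pdiv_exact(den, g)
  }
  cg <- igcd(pcontent(num), pcontent(den))
  if (cg > 1) { num <- num / cg; den <- den / cg }
  if (den[length(den)] < 0) { num <- -num; den <- -den }
  new_alpha_fun(num, den)
}

rf_const <- function(p, q = 1) {
  if (q < 0) { p <- -p; q <- -q }
  g <- igcd(abs(p), q)
  if (g > 1) { p <- p / g; q <- q / g }
  if (p == 0) return(new_alpha_fun(double(0), 1))
  new_alpha_fun(p, q)
}

rf_alpha <- function() new_alpha_fun(c(0, 1), 1)

rf_from_rational <- function(r) rf_const(r$num, r$den)

rf_is_zero <- function(f) length(f$num) == 0
rf_is_one <- function(f) identical(f$num, 1) && identical(f$den, 1)

rf_add <- function(a, b) {
  if (rf_is_zero(a)) return(b)
  if (rf_is_zero(b)) return(a)
  g <- pgcd_smart(a$den, b$den)
  bd <- if (pdeg(g) > 0 || g[1] > 1) pdiv_exact(b$den, g) else b$den
  ad <- if (pdeg(g) > 0 || g[1] > 1) pdiv_exact(a$den, g) else a$den
  num <- padd(pmul(a$num, bd), pmul(b$num, ad))
  rf_make(num, pmul(a$den, bd))
}

rf_neg <- function(a) new_alpha_fun(-a$num, a$den)
rf_sub <- function(a, b) rf_add(a, rf_neg(b))

rf_mul <- function(a, b) {
  if (rf_is_zero(a) || rf_is_zero(b)) return(new_alpha_fun(double(0), 1))
  # cross-reduce before multiplying to keep coefficients small
  g1 <- pgcd_smart(a$num, b$den)
  g2 <- pgcd_smart(b$num, a$den)
  an <- if (length(g1) && (pdeg(g1) > 0)) pdiv_exact(a$num, g1) else a$num
  bd <- if (length(g1) && (pdeg(g1) > 0)) pdiv_exact(b$den, g1) else b$den
  bn <- if (length(g2) && (pdeg(g2) > 0)) pdiv_exact(b$num, g2) else b$num
  ad <- if (length(g2) && (pdeg(g2) > 0)) pdiv_exact(a$den, g2) else a$den
  rf_make(pmul(an, bn), pmul(ad, bd))
}

rf_div <- function(a, b) {
  if (rf_is_zero(b)) stop("division by the zero rational function", call. = FALSE)
  rf_mul(a, new_alpha_fun(b$den, b$num))
}

rf_pow <- function(a, e) {
  stopifnot(e == round(e))
  if (e < 0) { a <- rf_div(rf_const(1), a); e <- -e }
  r <- rf_const(1)
  for (i in seq_len(e)) r <- rf_mul(r, a)
  r
}

rf_equal <- function(a, b) identical(a$num, b$num) && identical(a$den, b$den)

#' Fix the model parameter alpha
#'
#' Builds the parameter object used throughout the package: alpha may be left
#' symbolic, fixed to an exact rational in `[0, 1]` (kept exact in all
#' downstream arithmetic), or fixed to a double (downstream results become
#' floating point).
#'
#' @param x `"sym"` (or `NULL`) for symbolic alpha; a string `"p/q"` or an
#'   integer-valued number for an exact rational; any other single double for
#'   the floating-point mode.  Rationals and floats must lie in `[0, 1]`.
#' @return An object of class `alpha_value`.
#' @examples
#' alpha_value("sym")
#' alpha_value("1/3")
#' alpha_value(0)      # exact rational 0 (the Yule model)
#' alpha_value(0.37)   # floating point
#' @export
alpha_value <- function(x = "sym") {
  if (inherits(x, "alpha_value")) return(x)
  if (is.null(x)) x <- "sym"
  if (inherits(x, "alpha_rational")) {
    return(alpha_value_rational(x$num, x$den))
  }
  if (is.character(x)) {
    stopifnot(length(x) == 1)
    if (x %in% c("sym", "symbolic")) {
      return(structure(list(kind = "symbolic"), class = "alpha_value"))
    }
    if (grepl("^\\s*-?[0-9]+\\s*/\\s*[0-9]+\\s*$", x)) {
      parts <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
      return(alpha_value_rational(parts[1], parts[2]))
    }
    xn <- suppressWarnings(as.numeric(x))
    if (is.na(xn)) stop("cannot parse alpha value: ", x, call. = FALSE)
    x <- xn
  }
  stopifnot(is.numeric(x), length(x) == 1, is.finite(x))
  if (x == round(x)) return(alpha_value_rational(x, 1))
  if (x < 0 || x > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  structure(list(kind = "float", x = x), class = "alpha_value")
}

alpha_value_rational <- function(p, q) {
  r <- rational(p, q)
  if (r < 0 || r > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  structure(list(kind = "rational", p = r$num, q = r$den), class = "alpha_value")
}

#' @export
format.alpha_value <- function(x, ...) {
  switch(x$kind,
         symbolic = "a (symbolic)",
         rational = if (x$q == 1) sprintf("%.0f", x$p)
                    else sprintf("%.0f/%.0f", x$p, x$q),
         float = format(x$x, ...))
}

#' @export
print.alpha_value <- function(x, ...) {
  cat("alpha = ", format(x), "\n", sep = "")
  invisible(x)
}

alpha_is_symbolic <- function(a) a$kind == "symbolic"

#' Evaluate a rational function of alpha
#'
#' Substitutes a fixed alpha into a rational function.  Because `alpha_fun`
#' objects are always stored in reduced form, removable singularities have
#' already been cancelled before substitution (so e.g. expressions whose naive
#' numerator and denominator both vanish at alpha = 1 evaluate correctly); a
#' zero of the reduced denominator is a true pole and raises an error naming
#' the offending point.
#'
#' @param f an `alpha_fun`.
#' @param alpha an [alpha_value()] (or anything it accepts).
#' @return `f` itself for symbolic alpha; an [rational()] for rational alpha;
#'   a double for float alpha.
#' @examples
#' f <- prob_shape(parse_newick("((,),((,),));", "shape"))$fun
#' evaluate_at(f, "1/2")
#' @export
evaluate_at <- function(f, alpha) {
  stopifnot(inherits(f, "alpha_fun"))
  alpha <- alpha_value(alpha)
  switch(alpha$kind,
         symbolic = f,
         rational = {
           nv <- peval_rat(f$num, alpha$p, alpha$q)
           dv <- peval_rat(f$den, alpha$p, alpha$q)
           if (dv[1] == 0) {
             stop(sprintf("true pole of the rational function at alpha = %s",
                          format(alpha)), call. = FALSE)
           }
           new_rational(rat_div_(nv, dv))
         },
         float = {
           dv <- peval_num(f$den, alpha$x)
           if (dv == 0) {
             stop(sprintf("true pole of the rational function at alpha = %s",
                          format(alpha)), call. = FALSE)
           }
           peval_num(f$num, alpha$x) / dv
         })
}

# One Ops group generic covers both exact value types (rational functions of
# alpha and exact rationals), so mixed expressions like `fun * rational(2)`
# dispatch cleanly: if any operand is symbolic the arithmetic happens in the
# rational-function layer, otherwise in the exact rational layer.
#' @export
Ops.alpha_num <- function(e1, e2) {
  symbolic <- inherits(e1, "alpha_fun") || (!missing(e2) && inherits(e2, "alpha_fun"))
  if (!symbolic) {
    if (missing(e2)) return(rational_ops(.Generic, e1))
    return(rational_ops(.Generic, e1, e2))
  }
  as_rf <- function(x) {
    if (inherits(x, "alpha_fun")) return(x)
    if (inherits(x, "alpha_rational")) return(rf_const(x$num, x$den))
    if (is.numeric(x) && length(x) == 1 && x == round(x)) return(rf_const(x))
    stop("cannot combine object with alpha_fun", call. = FALSE)
  }
  if (missing(e2)) {
    a <- as_rf(e1)
    return(switch(.Generic, "+" = a, "-" = rf_neg(a),
                  stop("unsupported unary operator for alpha_fun")))
  }
  if (.Generic == "^") {
    return(rf_pow(as_rf(e1), e2))
  }
  if (.Generic %in% c("+", "-", "*", "/")) {
    a <- as_rf(e1); b <- as_rf(e2)
    return(switch(.Generic, "+" = rf_add(a, b), "-" = rf_sub(a, b),
                  "*" = rf_mul(a, b), "/" = rf_div(a, b)))
  }
  if (.Generic %in% c("==", "!=")) {
    eq <- rf_equal(as_rf(e1), as_rf(e2))
    return(if (.Generic == "==") eq else !eq)
  }
  stop(sprintf("operator '%s' not defined for alpha_fun", .Generic),
       call. = FALSE)
}

#' @export
print.alpha_fun <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}
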