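# Canonical ASCII rendering of rational functions in alpha, and the matching
# parser.  The symbol `a` denotes alpha.  Probabilities under the model always
# factor into linear pieces with rational roots, which are rendered in the
# fixed order "by root, ascending" (e.g. "2*(1-a)/(4-a)") so rendered output
# is stable; polynomials with no full rational factorization fall back to the
# expanded form (e.g. "(2 - 3*a + a^2)").

# Full factorization of an integer polynomial into rational linear factors,
# arranged for rendering: P = const * a^m0 * prod (rendered factors), where a
# factor with a positive root s/t renders as (s - t*a) and one with a negative
# root as (|s| + t*a) (the sign is absorbed into the constant).  Returns NULL
# when the polynomial does not split over the rationals.
factor_linear <- function(P) {
  f <- split_linear(P)
  if (is.null(f)) return(NULL)
  zero <- which(f$s == 0)
  m0 <- if (length(zero)) f$mult[zero] else 0L
  keep <- f$s != 0
  s <- f$s[keep]; t <- f$t[keep]; mult <- f$mult[keep]
  # the split uses factors (s - t*a); the rendered "a" (root 0) and the
  # rendered (|s| + t*a) (s < 0) each absorb one sign flip per power
  flips <- m0 + sum(mult[s < 0])
  const <- f$const * (-1)^(flips %% 2)
  list(const = const, m0 = m0, p = s, q = t, mult = mult)
}

factor_string <- function(p, q, mult) {
  base <- if (p > 0) {
    if (q == 1) sprintf("(%.0f-a)", p) else sprintf("(%.0f-%.0f*a)", p, q)
  } else {
    if (q == 1) sprintf("(%.0f+a)", -p) else sprintf("(%.0f+%.0f*a)", -p, q)
  }
  if (mult > 1) paste0(base, "^", mult) else base
}

# expanded polynomial, ascending powers: "2 - 3*a + a^2"
poly_string <- function(P) {
  if (!length(P)) return("0")
  parts <- character(0)
  for (i in seq_along(P)) {
    c_i <- P[i]
    if (c_i == 0) next
    pow <- i - 1L
    mag <- abs(c_i)
    body <- if (pow == 0) sprintf("%.0f", mag)
            else if (pow == 1) { if (mag == 1) "a" else sprintf("%.0f*a", mag) }
            else { if (mag == 1) sprintf("a^%d", pow) else sprintf("%.0f*a^%d", mag, pow) }
    parts <- c(parts, if (!length(parts)) {
      if (c_i < 0) paste0("-", body) else body
    } else {
      paste(if (c_i < 0) "-" else "+", body)
    })
  }
  paste(parts, collapse = " ")
}

# Render one side (numerator or denominator) given its factorization and the
# integer constant to display.  Returns the string and whether it is atomic
# (safe to use as a division operand without extra parentheses).
render_side <- function(const, fac) {
  pieces <- character(0)
  if (!is.null(fac)) {
    if (fac$m0 > 0) pieces <- c(pieces, if (fac$m0 > 1) paste0("a^", fac$m0) else "a")
    if (length(fac$p)) {
      pieces <- c(pieces, mapply(factor_string, fac$p, fac$q, fac$mult))
    }
  }
  neg <- const < 0
  cmag <- abs(const)
  if (cmag != 1 || !length(pieces)) pieces <- c(sprintf("%.0f", cmag), pieces)
  s <- paste(pieces, collapse = "*")
  if (neg) s <- paste0("-", s)
  list(s = s, n_pieces = length(pieces) + as.integer(neg))
}

#' @rdname parse_alpha_fun
#' @param x an `alpha_fun` object.
#' @param ... unused.
#' @export
format.alpha_fun <- function(x, ...) {
  if (rf_is_zero(x)) return("0")
  fn <- factor_linear(x$num)
  fd <- factor_linear(x$den)
  if (is.null(fn) || is.null(fd)) {
    # expanded fallback
    ns <- poly_string(x$num)
    if (identical(x$den, 1)) {
      return(if (pdeg(x$num) >= 1 && grepl(" ", ns)) paste0("(", ns, ")") else ns)
    }
    ds <- poly_string(x$den)
    wrap <- function(s, P) if (pdeg(P) >= 1) paste0("(", s, ")") else s
    return(paste0(wrap(ns, x$num), "/", wrap(ds, x$den)))
  }
  if (!is.null(fd) && fd$const < 0) {  # push the sign to the numerator side
    fd$const <- -fd$const
    fn$const <- -fn$const
  }
  num <- render_side(fn$const, fn)
  if (identical(x$den, 1)) return(num$s)
  den <- render_side(fd$const, fd)
  den_s <- if (den$n_pieces > 1) paste0("(", den$s, ")") else den$s
  paste0(num$s, "/", den_s)
}

#' Parse and render rational functions of alpha
#'
#' `parse_alpha_fun()` reads the package's canonical ASCII notation for
#' rational functions of alpha (the symbol `a`), e.g. `"2*(1-a)/(4-a)"`, and
#' returns the corresponding canonically reduced [`alpha_fun`][gamma_alpha]
#' object; `format()` renders one.  `parse_alpha_fun(format(f))` recovers `f`
#' exactly for any `f` the package produces.
#'
#' @param text a single string: integers, `a`, `+ - * / ^ ( )`.
#' @return An `alpha_fun`.
#' @examples
#' f <- parse_alpha_fun("2*(1-a)/(4-a)")
#' format(f)
#' evaluate_at(f, "1/2")
#' @export
parse_alpha_fun <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(gsub("\\s+", "", text), "")[[1]]
  if (!length(chars)) stop("empty expression", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() pos <<- pos + 1L
  fail <- function(msg) stop(sprintf("parse error at character %d: %s", pos, msg),
                             call. = FALSE)

  parse_expr <- function() {
    neg <- FALSE
    if (peek() == "-") { neg <- TRUE; advance() }
    else if (peek() == "+") advance()
    acc <- parse_term()
    if (neg) acc <- rf_neg(acc)
    while (peek() %in% c("+", "-")) {
      op <- peek(); advance()
      rhs <- parse_term()
      acc <- if (op == "+") rf_add(acc, rhs) else rf_sub(acc, rhs)
    }
    acc
  }
  parse_term <- function() {
    acc <- parse_factor()
    while (peek() %in% c("*", "/")) {
      op <- peek(); advance()
      rhs <- parse_factor()
      acc <- if (op == "*") rf_mul(acc, rhs) else rf_div(acc, rhs)
    }
    acc
  }
  parse_factor <- function() {
    base <- parse_primary()
    if (peek() == "^") {
      advance()
      neg <- FALSE
      if (peek() == "-") { neg <- TRUE; advance() }
      if (!grepl("[0-9]", peek())) fail("expected integer exponent")
      e <- parse_integer()
      base <- rf_pow(base, if (neg) -e else e)
    }
    base
  }
  parse_integer <- function() {
    digits <- character(0)
    while (grepl("[0-9]", peek())) { digits <- c(digits, peek()); advance() }
    as.numeric(paste(digits, collapse = ""))
  }
  parse_primary <- function() {
    c0 <- peek()
    if (c0 == "(") {
      advance()
      e <- parse_expr()
      if (peek() != ")") fail("expected ')'")
      advance()
      return(e)
    }
    if (c0 == "a") { advance(); return(rf_alpha()) }
    if (grepl("[0-9]", c0)) return(rf_const(parse_integer()))
    fail(sprintf("unexpected '%s'", c0))
  }

  out <- parse_expr()
  if (pos <= length(chars)) fail("trailing input")
  out
}
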