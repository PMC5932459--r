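# Integer-coefficient univariate polynomials in alpha.
#
# Representation: a double vector of exact integer coefficients in ascending
# powers, with no trailing zeros; the zero polynomial is double(0).  Rational
# functions store a numerator/denominator pair of such vectors with the mixed
# content removed, so rational coefficients never appear explicitly.

ptrim <- function(p) {
  n <- length(p)
  while (n > 0 && p[n] == 0) n <- n - 1
  p[seq_len(n)]
}

pdeg <- function(p) length(p) - 1L  # zero polynomial has degree -1

padd <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0) return(double(0))
  a <- c(a, double(n - length(a)))
  b <- c(b, double(n - length(b)))
  ptrim(chk_exact(a + b))
}

psub <- function(a, b) padd(a, pneg(b))
pneg <- function(a) -a

pmul <- function(a, b) {
  if (!length(a) || !length(b)) return(double(0))
  out <- double(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- seq_along(b) + i - 1L
    out[idx] <- chk_exact(out[idx] + chk_exact(a[i] * b))
  }
  ptrim(out)
}

pscale <- function(a, s) if (s == 0) double(0) else ptrim(chk_exact(a * s))

pcontent <- function(p) igcd_vec(p)

pprim <- function(p) {
  if (!length(p)) return(p)
  c0 <- pcontent(p)
  p / c0
}

# Pseudo-remainder of integer polynomials: prem(A, B) with deg A >= deg B >= 0.
pprem <- function(A, B) {
  dB <- pdeg(B)
  lB <- B[dB + 1L]
  while (pdeg(A) >= dB && length(A)) {
    dA <- pdeg(A)
    lA <- A[dA + 1L]
    # A <- lB*A - lA * x^(dA-dB) * B
    A2 <- pscale(A, lB)
    shift <- c(double(dA - dB), pscale(B, lA))
    A <- psub(A2, shift)
    # keep growth down
    if (length(A)) A <- pprim(A)
  }
  A
}

# GCD of integer polynomials via the primitive Euclidean remainder sequence.
# Returns a primitive polynomial with positive leading coefficient.
pgcd <- function(A, B) {
  A <- ptrim(A); B <- ptrim(B)
  if (!length(A)) return(pgcd_done(B))
  if (!length(B)) return(pgcd_done(A))
  if (pdeg(A) < pdeg(B)) { t <- A; A <- B; B <- t }
  while (length(B)) {
    R <- pprem(A, B)
    A <- B
    B <- R
  }
  pgcd_done(A)
}

pgcd_done <- function(P) {
  if (!length(P)) return(P)
  P <- pprim(P)
  if (P[length(P)] < 0) P <- -P
  P
}

# Exact division A / B where B is known to divide A over the rationals and the
# quotient is integral (the case that arises when dividing out a gcd of
# primitive polynomials up to content bookkeeping done by the caller).
pdiv_exact <- function(A, B) {
  if (!length(B)) stop("polynomial division by zero", call. = FALSE)
  if (!length(A)) return(double(0))
  dB <- pdeg(B)
  lB <- B[dB + 1L]
  q <- double(pdeg(A) - dB + 1L)
  R <- A
  while (pdeg(R) >= dB && length(R)) {
    dR <- pdeg(R)
    ci <- R[dR + 1L] / lB
    if (ci != round(ci)) stop("internal: inexact polynomial division", call. = FALSE)
    q[dR - dB + 1L] <- ci
    R <- psub(R, c(double(dR - dB), pscale(B, ci)))
  }
  if (length(R)) stop("internal: nonzero remainder in exact division", call. = FALSE)
  ptrim(q)
}

# --- rational-root machinery -------------------------------------------------
#
# Every polynomial the model produces in a denominator is a product of linear
# factors with small rational roots (the Gamma factors (i - a), the linear
# split kernels, powers of a).  Polynomial gcds are therefore computed by
# locating rational roots numerically, verifying them exactly, and dividing
# the shared linear factors out; the generic primitive-remainder-sequence gcd
# is kept only as a fallback for polynomials that do not split (its
# intermediate coefficient growth is caught by the overflow guard).

# continued-fraction rationalization of x with denominator at most qmax
rationalize_root <- function(x, qmax = 1e6, tol = 1e-7) {
  p0 <- 1; q0 <- 0; p1 <- floor(x); q1 <- 1
  frac <- x - p1
  while (abs(p1 / q1 - x) > tol * max(1, abs(x)) && q1 <= qmax && frac > 1e-12) {
    y <- 1 / frac
    a <- floor(y)
    frac <- y - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  if (q1 > qmax || abs(p1 / q1 - x) > tol * max(1, abs(x))) return(NULL)
  g <- igcd(abs(p1), q1)
  c(p1 / g, q1 / g)
}

# exactly verified rational roots of an integer polynomial, as rows (s, t)
rational_root_candidates <- function(P) {
  if (pdeg(P) < 1) return(matrix(numeric(0), ncol = 2))
  out <- matrix(numeric(0), ncol = 2)
  seen <- character(0)
  add <- function(s, t) {
    key <- paste0(s, "/", t)
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    # a candidate whose exact evaluation would overflow cannot be divided out
    # exactly anyway; skip it
    is_root <- tryCatch(peval_rat(P, s, t)[1] == 0, error = function(e) FALSE)
    if (is_root) out <<- rbind(out, c(s, t))
  }
  if (P[1] == 0) add(0, 1)
  z <- tryCatch(polyroot(P), error = function(e) complex(0))
  for (r in z) {
    if (abs(Im(r)) > 1e-6 * max(1, abs(Re(r)))) next
    x <- Re(r)
    cand <- rationalize_root(x, qmax = 1e4)
    if (!is.null(cand)) add(cand[1], cand[2])
    xr <- round(x)
    if (abs(x - xr) < 1e-6) add(xr, 1)
  }
  out
}

# Full factorization into verified rational linear factors (s - t*a); NULL if
# the polynomial does not split completely over the rationals.
split_linear <- function(P) {
  P <- ptrim(P)
  if (!length(P)) return(NULL)
  if (pdeg(P) == 0) {
    return(list(const = P[1], s = numeric(0), t = numeric(0), mult = integer(0)))
  }
  roots <- rational_root_candidates(P)
  s <- numeric(0); t <- numeric(0); mult <- integer(0)
  for (i in seq_len(nrow(roots))) {
    si <- roots[i, 1]; ti <- roots[i, 2]
    fac <- c(si, -ti)
    m <- 0L
    while (pdeg(P) >= 1 && peval_rat(P, si, ti)[1] == 0) {
      P <- pdiv_exact(P, fac)
      m <- m + 1L
    }
    if (m > 0) { s <- c(s, si); t <- c(t, ti); mult <- c(mult, m) }
  }
  if (pdeg(P) != 0) return(NULL)
  ord <- order(s / t)
  list(const = P[1], s = s[ord], t = t[ord], mult = mult[ord])
}

# gcd of A with a fully split B: shared linear factors to their common power
gcd_against_split <- function(A, fb) {
  g <- 1
  for (i in seq_along(fb$s)) {
    fac <- c(fb$s[i], -fb$t[i])
    m <- 0L
    while (m < fb$mult[i] && pdeg(A) >= 1 && peval_rat(A, fb$s[i], fb$t[i])[1] == 0) {
      A <- pdiv_exact(A, fac)
      m <- m + 1L
      g <- pmul(g, fac)
    }
  }
  pgcd_done(g)
}

# gcd preferring the rational-root route; PRS only when neither side splits
pgcd_smart <- function(A, B) {
  A <- ptrim(A); B <- ptrim(B)
  if (!length(A)) return(pgcd_done(B))
  if (!length(B)) return(pgcd_done(A))
  if (pdeg(A) == 0 || pdeg(B) == 0) return(1)
  fb <- split_linear(B)
  if (!is.null(fb)) return(gcd_against_split(A, fb))
  fa <- split_linear(A)
  if (!is.null(fa)) return(gcd_against_split(B, fa))
  pgcd(A, B)
}

# Evaluate an integer polynomial at the exact rational p/q: returns the pair
# (sum_i c_i p^i q^(d-i), q^d) unreduced.
peval_rat <- function(P, p, q) {
  if (!length(P)) return(c(0, 1))
  d <- pdeg(P)
  acc <- 0
  pw_p <- 1
  # c_i * p^i * q^(d-i), accumulate from i = 0 upward
  for (i in 0:d) {
    term <- imul(imul(P[i + 1L], pw_p), ipow(q, d - i))
    acc <- iadd(acc, term)
    if (i < d) pw_p <- imul(pw_p, p)
  }
  c(acc, ipow(q, d))
}

peval_num <- function(P, x) {
  if (!length(P)) return(0)
  acc <- 0
  for (i in rev(seq_along(P))) acc <- acc * x + P[i]
  acc
}
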