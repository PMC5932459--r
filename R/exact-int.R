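# Exact integer arithmetic on integer-valued doubles.
#
# Every quantity the alpha-model pipeline manipulates is an integer or a ratio
# of integers.  IEEE doubles represent integers exactly up to 2^53, which is
# ample for the enumeration range the model's exact tables cover (cladograms
# with up to 8 leaves, shapes with up to 10).  Every arithmetic step is guarded:
# an operation whose result would reach 2^53 raises an error instead of
# silently rounding, so results are either exact or absent.

.EXACT_MAX <- 2^53

chk_exact <- function(x) {
  if (any(abs(x) >= .EXACT_MAX)) {
    stop("exact integer overflow: an intermediate value reached 2^53; ",
         "this input lies outside the package's exact-arithmetic range",
         call. = FALSE)
  }
  x
}

imul <- function(a, b) chk_exact(a * b)
iadd <- function(a, b) chk_exact(a + b)

igcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

igcd_vec <- function(v) {
  g <- 0
  for (x in v) {
    g <- igcd(g, x)
    if (g == 1) break
  }
  g
}

ifactorial <- function(n) {
  r <- 1
  if (n >= 2) for (i in 2:n) r <- imul(r, i)
  r
}

# (2n-3)!! for n >= 2: the number of cladograms on n leaves.
idouble_factorial_odd <- function(m) {
  # product of odd numbers 1, 3, ..., m (m odd); m <= 0 gives 1
  r <- 1
  if (m >= 3) for (i in seq(3, m, by = 2)) r <- imul(r, i)
  r
}

ichoose <- function(n, k) {
  if (k < 0 || k > n) return(0)
  k <- min(k, n - k)
  r <- 1
  if (k > 0) for (i in seq_len(k)) {
    r <- imul(r, n - k + i)
    r <- r / i   # exact: running product of i consecutive integers
  }
  r
}

ipow <- function(a, e) {
  r <- 1
  while (e > 0) {
    r <- imul(r, a)
    e <- e - 1
  }
  r
}
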