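## Internal exact rational arithmetic.
##
## LRI scores are ratios of small integers (denominators are products of node
## degrees and the active-gene count), and the method's defining identities --
## triple equivalence of the closed form, the star-sum form and the Shapley
## oracle, and the efficiency axiom sum(F) == 1 -- are exact statements that
## floating point would only hold approximately. All score computation
## therefore runs on integer numerator/denominator pairs held in doubles
## (exact up to 2^53), reduced by gcd at every step, with an overflow guard.

.RAT_MAX <- 2^53

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    r <- a %% b
    nz <- b > 0
    a[nz] <- b[nz]
    b[nz] <- r[nz]
  }
  a
}

## Construct a reduced rational vector; den must be positive integers.
rational <- function(num, den = rep(1, length(num))) {
  stopifnot(length(num) == length(den))
  if (any(den == 0)) stop("rational: zero denominator")
  sgn <- sign(den)
  num <- num * sgn
  den <- den * sgn
  g <- .gcd(num, den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  if (any(abs(num) > .RAT_MAX) || any(den > .RAT_MAX))
    stop("rational: integer overflow beyond 2^53; network too large for exact arithmetic")
  structure(list(num = num, den = den), class = "rational")
}

ratLength <- function(x) length(x$num)

ratAdd <- function(x, y) {
  ## a/b + c/d with cross-gcd reduction to postpone overflow
  g <- .gcd(x$den, y$den)
  g[g == 0] <- 1
  db <- x$den / g
  dd <- y$den / g
  num <- x$num * dd + y$num * db
  den <- db * y$den
  rational(num, den)
}

ratMul <- function(x, y) {
  g1 <- .gcd(x$num, y$den); g1[g1 == 0] <- 1
  g2 <- .gcd(y$num, x$den); g2[g2 == 0] <- 1
  rational((x$num / g1) * (y$num / g2), (x$den / g2) * (y$den / g1))
}

ratSum <- function(x) {
  out <- rational(0, 1)
  for (k in seq_len(ratLength(x)))
    out <- ratAdd(out, rational(x$num[k], x$den[k]))
  out
}

ratEqual <- function(x, y) x$num == y$num & x$den == y$den

ratAsNumeric <- function(x) x$num / x$den

ratFormat <- function(x) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat(ratFormat(x), sep = " ")
  cat("\n")
  invisible(x)
}
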