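# Minimal arbitrary-precision non-negative integer arithmetic, used to carry
# the multiplicative Zagreb indices exactly: a product over thousands of edges
# overflows double precision long before it overflows interest.
#
# Representation: little-endian numeric vector of base-10^4 digits, class
# "bigint". Only the operations the package needs are provided (multiply,
# integer power, decimal string, log10, equality); no negative numbers.

.BIG_BASE <- 1e4

big_from_num <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x),
            x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(structure(0, class = "bigint"))
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% .BIG_BASE)
    x <- x %/% .BIG_BASE
  }
  structure(d, class = "bigint")
}

# Propagate carries until every digit < base, then strip high-order zeros.
# Digits entering here are bounded by ~1e11 (see big_mul), so carries fit in
# doubles with room to spare; the loop settles in a handful of passes.
.big_norm <- function(d) {
  repeat {
    carry <- d %/% .BIG_BASE
    if (!any(carry > 0)) break
    d <- d - carry * .BIG_BASE
    top <- carry[length(carry)]
    d <- d + c(0, carry[-length(carry)])
    if (top > 0) d <- c(d, top)
  }
  n <- length(d)
  while (n > 1L && d[n] == 0) n <- n - 1L
  structure(d[seq_len(n)], class = "bigint")
}

big_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
  res <- numeric(length(a) + length(b))
  for (i in seq_along(b)) {
    idx <- i:(i + length(a) - 1L)
    res[idx] <- res[idx] + b[i] * a
  }
  .big_norm(res)
}

big_pow <- function(a, n) {
  stopifnot(length(n) == 1L, n >= 0, n == floor(n))
  result <- big_from_num(1)
  base <- a
  while (n > 0) {
    if (n %% 2 == 1) result <- big_mul(result, base)
    n <- n %/% 2
    if (n > 0) base <- big_mul(base, base)
  }
  result
}

big_eq <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  length(a) == length(b) && all(a == b)
}

big_to_string <- function(a) {
  a <- unclass(a)
  n <- length(a)
  head <- as.character(as.integer(a[n]))
  if (n == 1L) return(head)
  paste0(head, paste(sprintf("%04d", as.integer(rev(a[-n]))), collapse = ""))
}

big_log10 <- function(a) {
  a <- unclass(a)
  n <- length(a)
  k <- min(n, 4L)
  top <- sum(a[(n - k + 1L):n] * .BIG_BASE^(0:(k - 1L)))
  if (top == 0) return(-Inf)
  log10(top) + 4 * (n - k)
}
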