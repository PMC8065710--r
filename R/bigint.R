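# Arbitrary-precision non-negative integers for Goedel numbers.
#
# Goedel numbers of composite programs (sigma indices, composed codes) exceed
# 2^53 by construction, so they are carried throughout the package as canonical
# decimal strings.  The handful of arithmetic operations the model needs
# (add, subtract, multiply, small divmod, integer square root for the Cantor
# unpairing) are implemented on base-1e4 limb vectors.

.BIG_BASE <- 10000L

# decimal string -> little-endian limb vector
.big_limbs <- function(s) {
  n <- nchar(s)
  if (n == 0L || s == "0") return(0L)
  starts <- seq(n, 1L, by = -4L)
  out <- integer(length(starts))
  for (k in seq_along(starts)) {
    hi <- starts[k]
    lo <- max(1L, hi - 3L)
    out[k] <- as.integer(substr(s, lo, hi))
  }
  out
}

.big_str <- function(v) {
  # drop leading zero limbs
  top <- length(v)
  while (top > 1L && v[top] == 0L) top <- top - 1L
  v <- v[seq_len(top)]
  parts <- sprintf("%04d", v[-top])
  paste0(c(as.character(v[top]), rev(parts)), collapse = "")
}

.big_norm <- function(s) {
  s <- sub("^0+", "", s)
  if (s == "") "0" else s
}

#' Normalise a Goedel number
#'
#' Goedel numbers in this package are canonical decimal strings because
#' composite codes routinely exceed the exactly-representable integer range of
#' doubles.  `gn()` accepts a non-negative whole number or a decimal string and
#' returns the canonical string form.
#'
#' @param x a non-negative whole number, or a string of decimal digits.
#' @return a canonical decimal string (no sign, no leading zeros).
#' @examples
#' gn(42)
#' gn("0042")
#' @export
gn <- function(x) {
  if (length(x) != 1L) stop("gn() expects a single value")
  if (is.numeric(x)) {
    if (is.na(x) || x < 0 || x != trunc(x)) {
      stop("Goedel numbers are non-negative integers; got ", x)
    }
    if (x > 2^53) stop("numeric input too large to be exact; pass a string")
    return(sprintf("%.0f", x))
  }
  x <- as.character(x)
  if (!grepl("^[0-9]+$", x)) {
    stop("not a non-negative integer: ", x)
  }
  .big_norm(x)
}

.big_add <- function(a, b) {
  la <- .big_limbs(a); lb <- .big_limbs(b)
  n <- max(length(la), length(lb))
  la <- c(la, integer(n - length(la)))
  lb <- c(lb, integer(n - length(lb)))
  s <- la + lb
  carry <- 0L
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% .BIG_BASE
    s[i] <- s[i] %% .BIG_BASE
  }
  if (carry > 0L) s <- c(s, carry)
  .big_str(s)
}

# a - b, requires a >= b
.big_sub <- function(a, b) {
  if (.big_cmp(a, b) < 0L) stop("big subtraction underflow")
  la <- .big_limbs(a); lb <- .big_limbs(b)
  lb <- c(lb, integer(length(la) - length(lb)))
  d <- la - lb
  for (i in seq_along(d)) {
    if (d[i] < 0L) {
      d[i] <- d[i] + .BIG_BASE
      d[i + 1L] <- d[i + 1L] - 1L
    }
  }
  .big_str(d)
}

.big_cmp <- function(a, b) {
  a <- .big_norm(a); b <- .big_norm(b)
  if (nchar(a) != nchar(b)) return(if (nchar(a) < nchar(b)) -1L else 1L)
  if (a == b) 0L else if (a < b) -1L else 1L
}

.big_mul <- function(a, b) {
  la <- .big_limbs(a); lb <- .big_limbs(b)
  if ((length(la) == 1L && la == 0L) || (length(lb) == 1L && lb == 0L)) return("0")
  # accumulate in doubles: products < 1e8, partial sums stay far below 2^53
  acc <- numeric(length(la) + length(lb))
  for (i in seq_along(la)) {
    if (la[i] == 0L) next
    idx <- (i - 1L) + seq_along(lb)
    acc[idx] <- acc[idx] + as.numeric(la[i]) * lb
  }
  carry <- 0
  out <- integer(length(acc))
  for (i in seq_along(acc)) {
    tot <- acc[i] + carry
    carry <- trunc(tot / .BIG_BASE)
    out[i] <- as.integer(tot - carry * .BIG_BASE)
  }
  while (carry > 0) {
    out <- c(out, as.integer(carry %% .BIG_BASE))
    carry <- trunc(carry / .BIG_BASE)
  }
  .big_str(out)
}

.big_mul_small <- function(a, m) {
  la <- .big_limbs(a)
  acc <- as.numeric(la) * m
  carry <- 0
  out <- integer(length(acc))
  for (i in seq_along(acc)) {
    tot <- acc[i] + carry
    carry <- trunc(tot / .BIG_BASE)
    out[i] <- as.integer(tot - carry * .BIG_BASE)
  }
  while (carry > 0) {
    out <- c(out, as.integer(carry %% .BIG_BASE))
    carry <- trunc(carry / .BIG_BASE)
  }
  .big_str(out)
}

.big_add_small <- function(a, m) .big_add(a, sprintf("%.0f", m))

# divmod by a small positive integer m (m * BASE must stay exact in doubles)
.big_divmod_small <- function(a, m) {
  la <- rev(.big_limbs(a)) # big-endian
  q <- integer(length(la))
  r <- 0
  for (i in seq_along(la)) {
    cur <- r * .BIG_BASE + la[i]
    q[i] <- as.integer(cur %/% m)
    r <- cur %% m
  }
  list(q = .big_str(rev(q)), r = as.integer(r))
}

.big_half <- function(a) .big_divmod_small(a, 2L)$q

.big_is_small <- function(a) nchar(a) <= 15L

.big_isqrt <- function(n) {
  if (.big_cmp(n, "2") < 0L) return(n)
  # binary search on digit-length bounds
  lo <- "1"
  hi <- paste0("1", strrep("0", ceiling(nchar(n) / 2) + 1L))
  while (.big_cmp(lo, .big_sub(hi, "1")) < 0L) {
    mid <- .big_half(.big_add(lo, hi))
    if (.big_cmp(.big_mul(mid, mid), n) <= 0L) lo <- mid else hi <- mid
  }
  lo
}

#' Cantor pairing of Goedel numbers
#'
#' Bijection between pairs of non-negative integers and the non-negative
#' integers: `pair(x, y) = (x + y)(x + y + 1)/2 + y`.  Used to give every
#' two-place sigma index a single canonical composite identifier that can be
#' matched exactly.  Inputs may be numbers or decimal strings of any size;
#' the result is a canonical decimal string (see [gn()]).
#'
#' @param x,y non-negative integers (numbers or decimal strings).
#' @return decimal-string integer.
#' @examples
#' pair(0, 0) # "0"
#' pair(1, 2) # "8"
#' unpair(pair(1, 2))
#' @seealso [unpair()]
#' @export
pair <- function(x, y) {
  x <- gn(x); y <- gn(y)
  s <- .big_add(x, y)
  .big_add(.big_half(.big_mul(s, .big_add_small(s, 1))), y)
}

#' Invert the Cantor pairing
#'
#' @param n a non-negative integer (number or decimal string).
#' @return list with components `x` and `y` (decimal strings),
#'   satisfying `pair(x, y) == gn(n)`.
#' @export
unpair <- function(n) {
  n <- gn(n)
  w <- .big_half(.big_sub(.big_isqrt(.big_add_small(.big_mul_small(n, 8), 1)), "1"))
  t <- .big_half(.big_mul(w, .big_add_small(w, 1)))
  y <- .big_sub(n, t)
  x <- .big_sub(w, y)
  list(x = x, y = y)
}
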