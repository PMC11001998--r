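#' Largest prime strictly below an upper bound
#'
#' Used to derive the default protein-fingerprint length: the largest prime
#' below 2^14 is 16,381. Prime-length arrays spread hashed indices more
#' evenly than power-of-two lengths under modular reduction.
#'
#' @param upper Exclusive upper bound (integer > 2).
#' @return The largest prime p with p < upper.
#' @examples
#' largest_prime_below(2^14)  # 16381
#' @export
largest_prime_below <- function(upper) {
  stopifnot(is.numeric(upper), length(upper) == 1, upper > 2)
  for (p in seq(floor(upper) - 1, 2)) {
    if (is_prime(p)) return(as.integer(p))
  }
  stop("no prime below ", upper)
}

is_prime <- function(n) {
  if (n < 2) return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= n) {
    if (n %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

#' Default protein fingerprint length in bits
#'
#' @return 16381L, the largest prime strictly below 2^14.
#' @export
default_nbits <- function() largest_prime_below(2^14)

# 32-bit FNV-1a digest of an ASCII string, returned as a double in
# [0, 2^32). Pure-R modular arithmetic: the multiply is split into 16-bit
# halves so every intermediate stays below 2^53.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  if (any(bytes > 127L)) stop("fnv1a32 expects ASCII input")
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' @noRd
geometric_mean <- function(x) 10^mean(log10(x))

the20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
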