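# Independent oracles used across test files.

# exact two-sided Mann-Whitney p by direct enumeration over all subset
# assignments, midranks for ties
enum_mw <- function(a, b) {
  na <- length(a); n <- na + length(b)
  rk <- rank(c(a, b))
  U_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  Us <- apply(utils::combn(n, na), 2, function(i) sum(rk[i]) - na * (na + 1) / 2)
  m <- na * length(b)
  lo <- min(U_obs, m - U_obs); hi <- max(U_obs, m - U_obs)
  p <- (sum(Us <= lo + 1e-9) + sum(Us >= hi - 1e-9)) / length(Us)
  list(U = U_obs, p = min(1, p))
}

# number of strict inversions against a non-increasing expectation
count_inversions <- function(x, tol = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0L)
  sum(diff(x) > tol)
}
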