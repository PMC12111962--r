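## Independent brute-force oracles used to pin expected values. These are
## deliberately written from first principles (binomial coefficients and
## exhaustive enumeration), not by calling the package routines they check.

## Two-sided Fisher p by direct hypergeometric enumeration over all tables
## with the observed margins, using choose() products.
fisher_enum_oracle <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  support <- max(0, K - n2):min(n1, K)
  tot <- choose(n1 + n2, K)
  prob <- choose(n1, support) * choose(n2, K - support) / tot
  obs <- choose(n1, k1) * choose(n2, k2) / tot
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

## Exact two-sided Mann-Whitney p for tie-free samples by exhaustive
## enumeration of all rank assignments.
mwu_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  w_all <- colSums(matrix(seq_len(nx + ny)[splits], nrow = nx)) -
    nx * (nx + 1) / 2
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

## Exact null distribution of |A' intersect B'| for independent uniform
## random subsets of sizes a and b from a universe of size U, by exhaustive
## enumeration of all subset pairs. Returns P(X = 0..min(a,b)).
overlap_enum_oracle <- function(a, b, U) {
  As <- utils::combn(U, a)
  Bs <- utils::combn(U, b)
  counts <- integer(min(a, b) + 1)
  for (i in seq_len(ncol(As))) {
    inA <- logical(U); inA[As[, i]] <- TRUE
    for (j in seq_len(ncol(Bs))) {
      k <- sum(inA[Bs[, j]])
      counts[k + 1] <- counts[k + 1] + 1L
    }
  }
  counts / sum(counts)
}

## Upper-tail Poisson probability P(X >= x) by direct series summation.
pois_tail_oracle <- function(x, lambda) {
  sum(stats::dpois(x:(x + 400), lambda))
}
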