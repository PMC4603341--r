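# Independent brute-force oracles used to pin down expected values.

# hypergeometric upper tail P(X >= k) by direct enumeration of the pmf
# through binomial coefficients (no phyper)
brute_hyper_upper <- function(k, n_pos, n_mut, n_total) {
  js <- k:min(n_pos, n_mut)
  if (k > min(n_pos, n_mut)) return(0)
  sum(choose(n_mut, js) * choose(n_total - n_mut, n_pos - js)) /
    choose(n_total, n_pos)
}

# Benjamini-Hochberg step-up by its definition: q_(i) = min_{j >= i} m p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# product-limit estimator computed by a hand loop over event times
brute_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# consensus CDF area closed form for perfect two-block structure:
# entries are 1 for within-block pairs, 0 for between-block pairs,
# and the area is the between-block pair fraction
block_area_closed_form <- function(n1, n2) {
  n <- n1 + n2
  within <- choose(n1, 2) + choose(n2, 2)
  1 - within / choose(n, 2)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
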