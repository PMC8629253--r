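# Independent oracles used by the tests. These deliberately avoid the
# package's internal code paths: probabilities are written out from
# the model definition, root finding is plain bisection, and the tiny
# mixture likelihood is maximized by coarse-to-fine grid search.

# Rasch success probability, written directly.
oracle_p <- function(theta, b) 1 / (1 + exp(-(theta - b)))

# PCM category probabilities from the definition (no shared code with
# pcm_prob beyond the model itself).
oracle_pcm <- function(theta, delta, w) {
  m <- length(delta)
  num <- vapply(0:m, function(k)
    exp(k * w * theta - sum(delta[seq_len(k)])), 1)
  num / sum(num)
}

# WLE estimating equation solved by bisection, with the information
# derivative obtained by central finite differences.
oracle_wle <- function(raw, deltas, weights, lo = -12, hi = 12) {
  info <- function(theta) {
    s <- 0
    for (i in seq_along(deltas)) {
      p <- oracle_pcm(theta, deltas[[i]], weights[i])
      k <- 0:(length(p) - 1)
      s <- s + weights[i]^2 * (sum(p * k^2) - sum(p * k)^2)
    }
    s
  }
  expected <- function(theta) {
    s <- 0
    for (i in seq_along(deltas)) {
      p <- oracle_pcm(theta, deltas[[i]], weights[i])
      s <- s + weights[i] * sum(p * (0:(length(p) - 1)))
    }
    s
  }
  g <- function(theta) {
    h <- 1e-5
    iprime <- (info(theta + h) - info(theta - h)) / (2 * h)
    (raw - expected(theta)) + iprime / (2 * info(theta))
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  (lo + hi) / 2
}

# Observed-data log-likelihood of a 2-class constrained mixture Rasch
# model on 3 dichotomous items, from pattern counts.
oracle_mix_loglik <- function(pat_counts, pi1, th1, th2, b) {
  ll <- 0
  for (pat in 0:7) {
    n <- pat_counts[pat + 1]
    if (n == 0) next
    x <- as.integer(intToBits(pat)[1:3])
    lik <- 0
    for (cls in 1:2) {
      th <- if (cls == 1) th1 else th2
      w <- if (cls == 1) pi1 else 1 - pi1
      p <- oracle_p(th, b)
      lik <- lik + w * prod(ifelse(x == 1, p, 1 - p))
    }
    ll <- ll + n * log(lik)
  }
  ll
}

# Coarse-to-fine grid maximization of the 2-class likelihood under the
# identification constraint pi1*th1 + (1-pi1)*th2 = 0 (th2 implied).
# Returns the best log-likelihood found.
oracle_grid_search <- function(rm, passes = 5) {
  x <- unclass(rm)
  pat <- x[, 1] + 2L * x[, 2] + 4L * x[, 3]
  pat_counts <- tabulate(pat + 1L, nbins = 8L)
  centers <- list(pi1 = 0.5, th1 = -1.25,
                  b1 = 0, b2 = 0, b3 = 0)
  span <- list(pi1 = 0.4, th1 = 1.25, b1 = 2.5, b2 = 2.5, b3 = 2.5)
  npts <- 7
  best <- -Inf; best_par <- centers
  for (pass in seq_len(passes)) {
    gr <- lapply(names(centers), function(nm)
      seq(centers[[nm]] - span[[nm]], centers[[nm]] + span[[nm]],
          length.out = npts))
    names(gr) <- names(centers)
    gr$pi1 <- pmin(pmax(gr$pi1, 0.02), 0.98)
    gr$th1 <- pmin(gr$th1, -1e-6)  # class 1 below the weighted mean 0
    for (pi1 in gr$pi1) for (th1 in gr$th1) {
      th2 <- -pi1 * th1 / (1 - pi1)
      for (b1 in gr$b1) for (b2 in gr$b2) for (b3 in gr$b3) {
        ll <- oracle_mix_loglik(pat_counts, pi1, th1, th2,
                                c(b1, b2, b3))
        if (ll > best) {
          best <- ll
          best_par <- list(pi1 = pi1, th1 = th1, b1 = b1, b2 = b2, b3 = b3)
        }
      }
    }
    centers <- best_par
    span <- lapply(span, function(s) s * 2 / (npts - 1))
  }
  best
}

# Small standard banks reused across tests.
test_bank_dichot <- function(n = 10, range = c(-2, 2), seed = 5)
  gen_item_bank(n, 0, range, seed)

test_bank_mixed <- function(seed = 6)
  gen_item_bank(25, 5, c(-3, 3), seed)

# Adult-like discrete ability profile (3 classes; entropy and ACP in
# the range reported for the adult reading samples).
adult_like_mixture <- function() ability_mixture(c(.15, .5, .35),
                                                 c(-1.7, -0.3, 1.05))
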