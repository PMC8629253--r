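#' Weighted likelihood (WLE) ability estimates
#'
#' Warm-type bias-corrected maximum likelihood ability estimates. For
#' the (weighted) partial credit family the estimator solves
#' `S(theta) + I'(theta) / (2 I(theta)) = 0`, where `S` is the score
#' function, `I` the test information and `I'` its derivative. The
#' correction keeps the estimate finite at perfect and zero raw
#' scores. Because `(S, I, I')` depend on the data only through the
#' set of administered items and the weighted raw score, persons are
#' grouped accordingly before root finding.
#'
#' @param fit a [fit_pcm] result.
#' @param rm the `response_matrix` the scores are computed for.
#' @return An object of class `person_scores`: a data frame with
#'   columns `person_id`, `raw_score` (weighted sum score), `wle` and
#'   `se` (`1 / sqrt(I)` at the estimate). Persons with no observed
#'   responses get `NA` scores with a warning.
#' @export
wle_estimates <- function(fit, rm) {
  stopifnot(inherits(fit, "pcm_fit"), inherits(rm, "response_matrix"))
  bank <- fit$bank
  if (ncol(rm) != nrow(bank))
    stop("response matrix does not match the fitted item bank")
  n <- nrow(rm)
  w <- bank$category_weight
  obs <- !is.na(unclass(rm))
  raw <- as.numeric((ifelse(obs, unclass(rm), 0L)) %*% w)
  raw[rowSums(obs) == 0L] <- NA_real_

  key <- paste(apply(obs, 1L, paste0, collapse = ""), raw)
  wle <- se <- rep(NA_real_, n)
  none <- rowSums(obs) == 0L
  if (any(none))
    warning(sum(none), " person(s) with no observed responses: scores set NA")

  for (k in unique(key[!none])) {
    rows <- which(key == k)
    items <- which(obs[rows[1L], ])
    r <- raw[rows[1L]]
    sol <- wle_solve(r, bank$step_params[items], w[items])
    wle[rows] <- sol$theta
    se[rows] <- sol$se
  }
  structure(data.frame(person_id = attr(rm, "person_id"),
                       raw_score = raw, wle = wle, se = se,
                       stringsAsFactors = FALSE),
            class = c("person_scores", "data.frame"))
}

# Solve the WLE estimating equation for one (item set, raw score)
# combination. The equation g(theta) = S + I'/(2I) is strictly
# decreasing apart from the small correction term; uniroot on a wide
# bracket is robust for every raw score including the extremes.
wle_solve <- function(raw, deltas, weights, lower = -12, upper = 12) {
  g <- function(theta) {
    s <- 0; info <- 0; iprime <- 0
    for (i in seq_along(deltas)) {
      mom <- pcm_moments(theta, deltas[[i]], weights[i])
      s <- s + weights[i] * mom$E
      info <- info + weights[i]^2 * mom$V
      iprime <- iprime + weights[i]^3 * mom$M3
    }
    (raw - s) + iprime / (2 * pmax(info, 1e-12))
  }
  gl <- g(lower); gu <- g(upper)
  if (gl <= 0) theta <- lower
  else if (gu >= 0) theta <- upper
  else theta <- stats::uniroot(g, c(lower, upper), tol = 1e-9)$root
  info <- 0
  for (i in seq_along(deltas))
    info <- info + weights[i]^2 * pcm_moments(theta, deltas[[i]], weights[i])$V
  list(theta = theta, se = 1 / sqrt(max(info, 1e-12)))
}

#' @export
print.person_scores <- function(x, ...) {
  ok <- !is.na(x$wle)
  cat(sprintf("Person scores: %d persons (%d scored)\n", nrow(x), sum(ok)))
  cat(sprintf("  WLE mean %.3f, sd %.3f, range [%.2f, %.2f]\n",
              mean(x$wle[ok]), stats::sd(x$wle[ok]),
              min(x$wle[ok]), max(x$wle[ok])))
  invisible(x)
}
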