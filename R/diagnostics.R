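#' Item infit (information-weighted mean square)
#'
#' Information-weighted mean-square residual per item, computed at the
#' WLE ability estimates: `sum((x - E)^2) / sum(Var)` on the weighted
#' score scale. Values inside `[0.8, 1.2]` are conventionally taken as
#' acceptable fit; items outside the band are flagged.
#'
#' @param fit a [fit_pcm] result.
#' @param rm the `response_matrix`.
#' @param scores optional precomputed [wle_estimates] result.
#' @param bounds acceptable infit band.
#' @return Data frame with columns `item_id`, `infit`, `flagged`.
#' @export
infit <- function(fit, rm, scores = NULL, bounds = c(0.8, 1.2)) {
  stopifnot(inherits(fit, "pcm_fit"))
  if (is.null(scores)) scores <- wle_estimates(fit, rm)
  bank <- fit$bank
  theta <- scores$wle
  out <- data.frame(item_id = bank$item_id, infit = NA_real_,
                    flagged = NA, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(bank))) {
    xi <- rm[, i]
    ok <- !is.na(xi) & !is.na(theta)
    if (!any(ok)) next
    mom <- pcm_moments(theta[ok], bank$step_params[[i]],
                       bank$category_weight[i])
    w <- bank$category_weight[i]
    res2 <- (w * (xi[ok] - mom$E))^2
    v <- w^2 * mom$V
    out$infit[i] <- sum(res2) / sum(v)
  }
  out$flagged <- !is.na(out$infit) &
    (out$infit < bounds[1] | out$infit > bounds[2])
  out
}

#' Adjusted Q3 local-dependence statistic
#'
#' Pairwise correlations of item score residuals at the WLE abilities,
#' centred by the mean off-diagonal correlation (the adjustment that
#' removes the small negative bias the estimated ability induces).
#' Absolute values above `threshold` flag locally dependent pairs.
#'
#' @inheritParams infit
#' @param threshold flag level for `|adjusted Q3|` (default .20).
#' @return A list with the symmetric `q3` matrix (adjusted, diagonal
#'   `NA`), `max_abs`, and a data frame `flagged_pairs`.
#' @export
adjusted_q3 <- function(fit, rm, scores = NULL, threshold = 0.20) {
  stopifnot(inherits(fit, "pcm_fit"))
  bank <- fit$bank
  if (nrow(bank) < 2L) stop("adjusted Q3 needs at least 2 items")
  if (is.null(scores)) scores <- wle_estimates(fit, rm)
  theta <- scores$wle
  res <- matrix(NA_real_, nrow(rm), nrow(bank),
                dimnames = list(NULL, bank$item_id))
  for (i in seq_len(nrow(bank))) {
    xi <- rm[, i]
    ok <- !is.na(xi) & !is.na(theta)
    mom <- pcm_moments(theta[ok], bank$step_params[[i]],
                       bank$category_weight[i])
    res[ok, i] <- bank$category_weight[i] * (xi[ok] - mom$E)
  }
  q3 <- suppressWarnings(stats::cor(res, use = "pairwise.complete.obs"))
  off <- q3[upper.tri(q3)]
  adj <- q3 - mean(off, na.rm = TRUE)
  diag(adj) <- NA_real_
  pairs <- which(upper.tri(adj) & abs(adj) > threshold, arr.ind = TRUE)
  flagged <- data.frame(item_1 = bank$item_id[pairs[, 1]],
                        item_2 = bank$item_id[pairs[, 2]],
                        q3 = adj[pairs], stringsAsFactors = FALSE)
  list(q3 = adj, max_abs = max(abs(adj), na.rm = TRUE),
       flagged_pairs = flagged, threshold = threshold)
}

#' Marginal reliability of the person scores
#'
#' One minus the ratio of the mean squared standard error to the total
#' observed score variance: `1 - mean(se^2) / var(wle)`.
#'
#' @param fit a [fit_pcm] result.
#' @param scores a [wle_estimates] result.
#' @return A single proportion.
#' @export
marginal_reliability <- function(fit, scores) {
  ok <- !is.na(scores$wle)
  v <- stats::var(scores$wle[ok])
  if (!is.finite(v) || v <= 0)
    stop("marginal reliability undefined: zero score variance")
  1 - mean(scores$se[ok]^2) / v
}

#' Item diagnostics report
#'
#' One row per item: estimated difficulty, standard error, infit and
#' the largest absolute adjusted Q3 involving the item.
#'
#' @inheritParams infit
#' @param path optional CSV output path.
#' @return The report data frame (invisibly written to `path` if
#'   given).
#' @export
item_diagnostics <- function(fit, rm, scores = NULL, path = NULL) {
  if (is.null(scores)) scores <- wle_estimates(fit, rm)
  inf <- infit(fit, rm, scores)
  q3 <- adjusted_q3(fit, rm, scores)
  se <- vapply(fit$item_se, function(s) sqrt(mean(s^2)), 1)
  rep <- data.frame(item_id = fit$bank$item_id,
                    difficulty = fit$bank$difficulty,
                    se = se, infit = inf$infit,
                    infit_flagged = inf$flagged,
                    max_abs_q3 = apply(abs(q3$q3), 1L, max, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(rep, path, row.names = FALSE)
  invisible(rep)
}
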