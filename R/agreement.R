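#' 2x2 classification contingency table
#'
#' Cross-classifies the model-based (cMRM) and bookmark labels with
#' the orientation: rows = cMRM, columns = bookmark;
#' `A` = both low, `B` = cMRM low / bookmark literate, `C` = cMRM
#' literate / bookmark low, `D` = both literate.
#'
#' @param A,B,C,D non-negative cell counts.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_table <- function(A, B, C, D) {
  cells <- c(A = A, B = B, C = C, D = D)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (sum(cells) < 1) stop("table must contain at least one person")
  structure(as.list(cells), N = sum(cells), class = "contingency_2x2")
}

#' @param cmrm_labels binary labels from the model-based procedure
#'   (`"low"`/`"literate"`, logical `TRUE` = low, or integer class
#'   labels where 1 = low).
#' @param bm_labels bookmark labels in the same codings.
#' @rdname contingency_table
#' @return `contingency()` additionally records the number of persons
#'   excluded for a missing label (attribute `n_excluded`).
#' @export
contingency <- function(cmrm_labels, bm_labels) {
  if (length(cmrm_labels) != length(bm_labels))
    stop("label vectors must have equal length")
  lowify <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x == 1)
    x <- as.character(x)
    if (!all(x %in% c("low", "literate", NA))) stop("unknown label values")
    x == "low"
  }
  cm <- lowify(cmrm_labels); bm <- lowify(bm_labels)
  keep <- !is.na(cm) & !is.na(bm)
  t <- contingency_table(A = sum(cm[keep] & bm[keep]),
                         B = sum(cm[keep] & !bm[keep]),
                         C = sum(!cm[keep] & bm[keep]),
                         D = sum(!cm[keep] & !bm[keep]))
  attr(t, "n_excluded") <- sum(!keep)
  t
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  N <- attr(x, "N")
  cat("              BM low   BM literate   Total\n")
  cat(sprintf("cMRM low     %7d   %11d   %5d\n", x$A, x$B, x$A + x$B))
  cat(sprintf("cMRM literate%7d   %11d   %5d\n", x$C, x$D, x$C + x$D))
  cat(sprintf("Total        %7d   %11d   %5d\n", x$A + x$C, x$B + x$D, N))
  invisible(x)
}

#' McNemar's chi-squared test
#'
#' Tests whether the two procedures produce the same marginal rate of
#' literate readers, using only the discordant cells. With the
#' continuity correction (default) the statistic is
#' `(max(0, |B - C| - 1))^2 / (B + C)`; without it,
#' `(B - C)^2 / (B + C)`. When `B + C = 0` the statistic is defined
#' as 0 with p = 1.
#'
#' @param t a `contingency_2x2`.
#' @param continuity apply the continuity correction (default TRUE).
#' @return List with `chi2`, `p_value`, `df = 1`.
#' @export
mcnemar_test <- function(t, continuity = TRUE) {
  stopifnot(inherits(t, "contingency_2x2"))
  disc <- t$B + t$C
  if (disc < 1) return(list(chi2 = 0, p_value = 1, df = 1L))
  num <- if (continuity) max(0, abs(t$B - t$C) - 1)^2 else (t$B - t$C)^2
  chi2 <- num / disc
  list(chi2 = chi2, p_value = stats::pchisq(chi2, 1L, lower.tail = FALSE),
       df = 1L)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected global agreement,
#' `kappa = 2(AD - CB) / [(A+B)(B+D) + (A+C)(C+D)]`, algebraically
#' identical to `(p0 - pe) / (1 - pe)`. The default standard error is
#' the simplified Fleiss large-sample form
#' `sqrt(p0 (1 - p0)) / ((1 - pe) sqrt(N))`; `se = "exact"` uses the
#' full Fleiss-Cohen-Everitt asymptotic variance. The 95% confidence
#' interval is `kappa +/- 1.96 se`.
#'
#' @param t a `contingency_2x2`.
#' @param se `"fleiss"` (simplified, default) or `"exact"`.
#' @return List with `kappa`, `se`, `ci95`, `p0`, `pe`.
#' @export
cohens_kappa <- function(t, se = c("fleiss", "exact")) {
  stopifnot(inherits(t, "contingency_2x2"))
  se <- match.arg(se)
  A <- t$A; B <- t$B; C <- t$C; D <- t$D
  N <- attr(t, "N")
  if ((A + B) == 0 || (C + D) == 0 || (A + C) == 0 || (B + D) == 0)
    stop("kappa undefined: a procedure assigns only one label")
  p0 <- (A + D) / N
  pe <- ((A + B) * (A + C) + (C + D) * (B + D)) / N^2
  if (1 - pe < .Machine$double.eps) stop("kappa undefined: pe = 1")
  kap <- 2 * (A * D - C * B) / ((A + B) * (B + D) + (A + C) * (C + D))
  se_val <- if (se == "fleiss") {
    sqrt(p0 * (1 - p0)) / ((1 - pe) * sqrt(N))
  } else {
    p <- matrix(c(A, B, C, D), 2, 2, byrow = TRUE) / N
    pr <- rowSums(p); pc <- colSums(p)
    t1 <- sum(vapply(1:2, function(i)
      p[i, i] * (1 - (pr[i] + pc[i]) * (1 - kap))^2, 1))
    t2 <- (1 - kap)^2 *
      (p[1, 2] * (pc[1] + pr[2])^2 + p[2, 1] * (pc[2] + pr[1])^2)
    t3 <- (kap - pe * (1 - kap))^2
    sqrt(max(t1 + t2 - t3, 0)) / ((1 - pe) * sqrt(N))
  }
  list(kappa = kap, se = se_val,
       ci95 = c(kap - 1.96 * se_val, kap + 1.96 * se_val),
       p0 = p0, pe = pe)
}

#' Sensitivity and specificity (bookmark as reference)
#'
#' With the bookmark procedure as the reference ("gold standard"):
#' sensitivity `= 100 A / (A + C)` is the percentage of
#' bookmark-low readers the model also labels low; specificity
#' `= 100 D / (D + B)` the percentage of bookmark-literate readers
#' the model also labels literate.
#'
#' @param t a `contingency_2x2`.
#' @return A percentage.
#' @export
sensitivity_pct <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$A + t$C < 1) stop("sensitivity undefined: no bookmark-low persons")
  100 * t$A / (t$A + t$C)
}

#' @rdname sensitivity_pct
#' @export
specificity_pct <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$B + t$D < 1) stop("specificity undefined: no bookmark-literate persons")
  100 * t$D / (t$D + t$B)
}

#' Within-proficiency disagreement rates
#'
#' Symmetric alternatives to sensitivity/specificity that need no
#' gold standard: `DIS_low = 100 (B + C) / (A + B + C)` (disagreement
#' relative to everyone either procedure calls low) and
#' `DIS_lit = 100 (B + C) / (B + C + D)` (relative to everyone either
#' procedure calls literate).
#'
#' @param t a `contingency_2x2`.
#' @return A percentage.
#' @export
dis_low <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$A + t$B + t$C < 1) stop("DIS_low undefined: empty denominator")
  100 * (t$B + t$C) / (t$A + t$B + t$C)
}

#' @rdname dis_low
#' @export
dis_lit <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$B + t$C + t$D < 1) stop("DIS_lit undefined: empty denominator")
  100 * (t$B + t$C) / (t$B + t$C + t$D)
}

#' Landis-Koch verbal band for kappa
#'
#' @param kappa a kappa value (<= 1).
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`, `"perfect"`.
#' @export
kappa_band <- function(kappa) {
  stopifnot(kappa <= 1)
  if (kappa >= 1) "perfect"
  else if (kappa > 0.80) "almost perfect"
  else if (kappa > 0.60) "substantial"
  else if (kappa > 0.40) "moderate"
  else if (kappa > 0.20) "fair"
  else "poor"
}

#' Full agreement report for a 2x2 table
#'
#' Computes every agreement measure: McNemar's continuity-corrected
#' chi-squared with p-value, Cohen's kappa with SE, 95% CI and
#' Landis-Koch band, sensitivity, specificity and the two
#' within-proficiency disagreement rates.
#'
#' @param t a `contingency_2x2`.
#' @param alpha significance level for flagging the McNemar test
#'   (default .01).
#' @param continuity continuity-correct the McNemar statistic.
#' @return An object of class `agreement_report` (a list of the
#'   measures).
#' @export
agreement_report <- function(t, alpha = 0.01, continuity = TRUE) {
  mc <- mcnemar_test(t, continuity)
  kp <- cohens_kappa(t)
  structure(list(table = t,
                 mcnemar_chi2 = mc$chi2, mcnemar_p = mc$p_value,
                 mcnemar_significant = mc$p_value < alpha, alpha = alpha,
                 kappa = kp$kappa, kappa_se = kp$se, kappa_ci95 = kp$ci95,
                 kappa_band = kappa_band(kp$kappa),
                 p0 = kp$p0, pe = kp$pe,
                 sensitivity = sensitivity_pct(t),
                 specificity = specificity_pct(t),
                 dis_low = dis_low(t), dis_lit = dis_lit(t)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  chi <- if (x$mcnemar_chi2 >= 10) sprintf("%.0f", x$mcnemar_chi2)
         else sprintf("%.2f", x$mcnemar_chi2)
  pfmt <- function(p) if (p < .001) "< .001" else sub("^0", "", sprintf("%.3f", p))
  cat(sprintf(
    "McNemar chi2(1) = %s, p %s | kappa = %.2f (SE %.3f) [%.2f, %.2f] (%s)\n",
    chi, pfmt(x$mcnemar_p), x$kappa, x$kappa_se,
    x$kappa_ci95[1], x$kappa_ci95[2], x$kappa_band))
  cat(sprintf(
    "sensitivity %.2f%% | specificity %.2f%% | DIS_low %.2f%% | DIS_lit %.2f%%\n",
    x$sensitivity, x$specificity, x$dis_low, x$dis_lit))
  invisible(x)
}

#' Serialize an agreement report
#'
#' @param report an [agreement_report].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  out <- report[setdiff(names(report), "table")]
  out$cells <- report$table[c("A", "B", "C", "D")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
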