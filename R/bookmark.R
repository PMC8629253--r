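#' Build an ordered item booklet (OIB)
#'
#' Sorts the items of an estimated bank from easiest to hardest by
#' their difficulty (for polytomous super-items, the mean step
#' parameter on the ability scale — each super-item appears once).
#' Ties break lexicographically by item id.
#'
#' @param bank an [item_bank] with estimated difficulties (e.g.
#'   `fit$bank` from [fit_pcm]).
#' @return Data frame with columns `rank`, `item_id`, `difficulty`.
#' @export
build_oib <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  if (any(!is.finite(bank$difficulty)))
    stop("all items need a finite estimated difficulty")
  ord <- order(bank$difficulty, bank$item_id)
  data.frame(rank = seq_len(nrow(bank)),
             item_id = bank$item_id[ord],
             difficulty = bank$difficulty[ord],
             stringsAsFactors = FALSE)
}

#' Response-probability cut score
#'
#' Converts a bookmarked item's difficulty into a cut score on the
#' logit ability scale by adding the response-probability offset: the
#' ability at which a borderline examinee solves the item with the
#' target probability. The default offset of 0.701 logits corresponds
#' to the RP67 convention as operationalized in the reading
#' assessments emulated here (the exact logit of .67 is
#' `log(.67/.33) = 0.708`; the offset is kept configurable).
#'
#' @param difficulty bookmarked item difficulty in logits.
#' @param rp_offset logit offset added to the difficulty.
#' @return Cut score in logits.
#' @export
rp_cutscore <- function(difficulty, rp_offset = 0.701) {
  stopifnot(is.finite(difficulty))
  difficulty + rp_offset
}

#' Bookmark specification
#'
#' Bundles the ordered item booklet, the bookmarked item, the RP
#' convention and the resulting cut score.
#'
#' @param bank an [item_bank] with estimated difficulties.
#' @param bookmark_item id of the bookmarked item.
#' @param rp_value target response probability in `(0.5, 1)`
#'   (descriptive; the offset does the arithmetic).
#' @param rp_offset logits added to the bookmarked difficulty.
#' @return An object of class `bookmark_spec`.
#' @export
bookmark_spec <- function(bank, bookmark_item, rp_value = 0.67,
                          rp_offset = 0.701) {
  stopifnot(rp_value > 0.5, rp_value < 1)
  oib <- build_oib(bank)
  if (!bookmark_item %in% oib$item_id)
    stop("bookmark_item not in the item bank: ", bookmark_item)
  d <- oib$difficulty[oib$item_id == bookmark_item]
  structure(list(oib = oib, rp_value = rp_value, rp_offset = rp_offset,
                 bookmark_item = bookmark_item,
                 cut_score = rp_cutscore(d, rp_offset)),
            class = "bookmark_spec")
}

#' @export
print.bookmark_spec <- function(x, ...) {
  cat(sprintf("Bookmark: item '%s' (difficulty %.3f) + RP offset %.3f -> cut %.3f logits\n",
              x$bookmark_item,
              x$cut_score - x$rp_offset, x$rp_offset, x$cut_score))
  invisible(x)
}

#' Classify persons against a bookmark cut score
#'
#' Labels a person `low` if the WLE ability estimate is strictly
#' below the cut score and `literate` otherwise (a score exactly at
#' the cut counts as literate). Persons without a WLE are excluded
#' and counted.
#'
#' @param scores a [wle_estimates] result (or numeric vector of
#'   abilities).
#' @param cut cut score in logits (or a [bookmark_spec]).
#' @return Factor with levels `low`, `literate` (NA for unscored
#'   persons) and attributes `n_low`, `n_literate`, `n_excluded`,
#'   `pct_low`.
#' @export
classify_bookmark <- function(scores, cut) {
  theta <- if (inherits(scores, "person_scores")) scores$wle else scores
  if (inherits(cut, "bookmark_spec")) cut <- cut$cut_score
  lab <- factor(ifelse(theta < cut, "low", "literate"),
                levels = c("low", "literate"))
  n_low <- sum(lab == "low", na.rm = TRUE)
  n_lit <- sum(lab == "literate", na.rm = TRUE)
  structure(lab, n_low = n_low, n_literate = n_lit,
            n_excluded = sum(is.na(theta)),
            pct_low = 100 * n_low / max(n_low + n_lit, 1L))
}

#' Write a bookmark specification as JSON and its OIB as CSV
#'
#' @param spec a [bookmark_spec].
#' @param path_json,path_csv optional output paths.
#' @return `spec`, invisibly.
#' @export
write_bookmark_spec <- function(spec, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(list(bookmark_item = spec$bookmark_item,
                              rp_value = spec$rp_value,
                              rp_offset = spec$rp_offset,
                              cut_score = spec$cut_score),
                         path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_csv))
    utils::write.csv(spec$oib, path_csv, row.names = FALSE)
  invisible(spec)
}
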