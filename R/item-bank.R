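#' Item banks
#'
#' An item bank holds the definition of every item on a test form:
#' dichotomous items with a single difficulty in logits, and polytomous
#' "super-items" (several subtasks scored against one stimulus) with
#' ordered step parameters and a category weight giving the score
#' points awarded per category step (0.5 for the reading super-items
#' emulated here, 1 for dichotomous items).
#'
#' @param item_id character vector of unique item identifiers.
#' @param item_type `"dichotomous"` or `"polytomous"`, one per item.
#' @param step_params list of numeric step-parameter vectors (logits);
#'   a dichotomous item has exactly one step, its difficulty.
#' @param category_weight numeric vector of score points per category
#'   step; must be positive.
#'
#' @return An object of class `item_bank`: a data frame with columns
#'   `item_id`, `item_type`, `n_categories`, `difficulty` (the mean
#'   step parameter divided by the weight, i.e. the item location on
#'   the ability scale), `category_weight`, and the list column
#'   `step_params`.
#' @export
item_bank <- function(item_id, item_type, step_params, category_weight) {
  n <- length(item_id)
  stopifnot(n >= 1L, !anyDuplicated(item_id),
            length(item_type) == n, length(step_params) == n,
            length(category_weight) == n)
  item_type <- match.arg(item_type, c("dichotomous", "polytomous"),
                         several.ok = TRUE)
  ncat <- vapply(step_params, length, 1L) + 1L
  if (any(!vapply(step_params, function(d) all(is.finite(d)), TRUE)))
    stop("step parameters must be finite")
  if (any(category_weight <= 0)) stop("category_weight must be > 0")
  if (any((ncat == 2L) != (item_type == "dichotomous")))
    stop("n_categories = 2 exactly for dichotomous items")
  bank <- data.frame(
    item_id = as.character(item_id),
    item_type = item_type,
    n_categories = ncat,
    difficulty = vapply(step_params, mean, 1) / category_weight,
    category_weight = category_weight,
    stringsAsFactors = FALSE
  )
  bank$step_params <- lapply(step_params, as.numeric)
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' Generate a synthetic item bank
#'
#' Draws item locations uniformly over a difficulty range and equips
#' polytomous items with centred, ordered step parameters around their
#' location. Deterministic given `seed`.
#'
#' @param n_dichot,n_poly counts of dichotomous and polytomous items;
#'   their sum must be at least 2.
#' @param difficulty_range numeric length-2 interval of item locations
#'   in logits (`min <= max`; a degenerate interval is allowed).
#' @param seed integer RNG seed.
#' @param n_categories_poly categories per polytomous item (default 3,
#'   i.e. two steps).
#' @param poly_weight score points per category step for polytomous
#'   items (default 0.5).
#' @param step_spread half-width in logits of the step offsets around a
#'   polytomous item's location.
#' @return An [item_bank].
#' @export
gen_item_bank <- function(n_dichot, n_poly, difficulty_range, seed,
                          n_categories_poly = 3L, poly_weight = 0.5,
                          step_spread = 0.8) {
  n <- n_dichot + n_poly
  if (n < 2L) stop("item bank needs at least 2 items")
  if (length(difficulty_range) != 2L || difficulty_range[1] > difficulty_range[2])
    stop("invalid difficulty_range (min > max)")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  loc <- stats::runif(n, difficulty_range[1], difficulty_range[2])
  type <- rep(c("dichotomous", "polytomous"), c(n_dichot, n_poly))
  ids <- c(sprintf("d%02d", seq_len(n_dichot)),
           if (n_poly > 0) sprintf("p%02d", seq_len(n_poly)))
  m_poly <- n_categories_poly - 1L
  steps <- vector("list", n)
  weight <- ifelse(type == "polytomous", poly_weight, 1)
  for (i in seq_len(n)) {
    if (type[i] == "dichotomous") {
      steps[[i]] <- loc[i]
    } else {
      off <- sort(stats::runif(m_poly, -step_spread, step_spread))
      off <- off - mean(off)
      steps[[i]] <- weight[i] * (loc[i] + off)
    }
  }
  item_bank(ids, type, steps, weight)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: %d items (%d dichotomous, %d polytomous)\n",
              nrow(x), sum(x$item_type == "dichotomous"),
              sum(x$item_type == "polytomous")))
  cat(sprintf("  difficulty range [%.2f, %.2f] logits\n",
              min(x$difficulty), max(x$difficulty)))
  invisible(x)
}

#' Read / write an item bank as JSON
#'
#' @param bank an [item_bank].
#' @param path file path.
#' @return `read_item_bank` returns an [item_bank]; `write_item_bank`
#'   returns `path` invisibly.
#' @export
write_item_bank <- function(bank, path) {
  items <- lapply(seq_len(nrow(bank)), function(i) list(
    item_id = bank$item_id[i],
    item_type = bank$item_type[i],
    n_categories = bank$n_categories[i],
    category_weight = bank$category_weight[i],
    step_params = bank$step_params[[i]]
  ))
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  items <- jsonlite::read_json(path, simplifyVector = FALSE)
  item_bank(
    item_id = vapply(items, `[[`, "", "item_id"),
    item_type = vapply(items, `[[`, "", "item_type"),
    step_params = lapply(items, function(it) unlist(it$step_params)),
    category_weight = vapply(items, function(it) it$category_weight, 1)
  )
}

# Save/restore the global RNG state so generators with their own seed
# do not disturb the caller's stream.
.Random.seed.save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
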