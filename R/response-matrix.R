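#' Synthetic sampling configuration
#'
#' Describes the person side of a simulated assessment: sample size,
#' the latent-ability model (a continuous normal trait, or a discrete
#' mixture of ability locations as assumed by the constrained mixture
#' Rasch model), an RNG seed and a completely-at-random missingness
#' rate.
#'
#' @param n_persons number of test takers (>= 1).
#' @param ability either `ability_continuous()` or `ability_mixture()`.
#' @param seed integer RNG seed.
#' @param missing_rate proportion of cells set missing, in `[0, 1)`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_persons, ability = ability_continuous(),
                             seed = 1L, missing_rate = 0) {
  stopifnot(n_persons >= 1L, missing_rate >= 0, missing_rate < 1)
  structure(list(n_persons = as.integer(n_persons), ability = ability,
                 seed = as.integer(seed), missing_rate = missing_rate),
            class = "synthetic_config")
}

#' @param mean,sd mean and standard deviation of the latent normal
#'   ability distribution (logits).
#' @rdname synthetic_config
#' @export
ability_continuous <- function(mean = 0, sd = 1.3) {
  stopifnot(sd > 0)
  structure(list(model = "continuous", mean = mean, sd = sd),
            class = "ability_model")
}

#' @param props class proportions (must sum to 1 within 1e-12).
#' @param locations class ability locations in logits, strictly
#'   increasing, one per class.
#' @rdname synthetic_config
#' @export
ability_mixture <- function(props, locations) {
  if (length(props) != length(locations))
    stop("mixture props and locations must have the same length")
  if (abs(sum(props) - 1) > 1e-12) stop("mixture props must sum to 1")
  if (length(locations) > 1 && any(diff(locations) <= 0))
    stop("mixture locations must be strictly increasing")
  structure(list(model = "mixture", props = props, locations = locations),
            class = "ability_model")
}

#' Simulate a scored response matrix
#'
#' Draws each person's ability from the configured ability model and
#' each response item-wise from the weighted partial credit category
#' probabilities at that ability. Missing cells are inserted completely
#' at random at the configured rate.
#'
#' @param bank an [item_bank].
#' @param cfg a [synthetic_config].
#' @return A `response_matrix`: an integer N x I matrix of category
#'   codes (`NA` = missing) with attributes `person_id`, `true_theta`
#'   and, for mixture configurations, `true_class` (1 = lowest
#'   location).
#' @export
simulate_responses <- function(bank, cfg) {
  stopifnot(inherits(bank, "item_bank"), inherits(cfg, "synthetic_config"))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(cfg$seed)
  n <- cfg$n_persons
  ab <- cfg$ability
  true_class <- NULL
  if (ab$model == "continuous") {
    theta <- stats::rnorm(n, ab$mean, ab$sd)
  } else {
    true_class <- sample.int(length(ab$props), n, replace = TRUE,
                             prob = ab$props)
    theta <- ab$locations[true_class]
  }
  x <- matrix(NA_integer_, n, nrow(bank),
              dimnames = list(NULL, bank$item_id))
  for (i in seq_len(nrow(bank))) {
    p <- pcm_prob(theta, bank$step_params[[i]], bank$category_weight[i])
    cum <- t(apply(p, 1L, cumsum))
    u <- stats::runif(n)
    x[, i] <- rowSums(u > cum[, -ncol(cum), drop = FALSE])
  }
  if (cfg$missing_rate > 0) {
    drop_cells <- stats::runif(length(x)) < cfg$missing_rate
    x[drop_cells] <- NA_integer_
  }
  response_matrix(x, person_id = sprintf("P%05d", seq_len(n)),
                  true_theta = theta, true_class = true_class)
}

#' Construct a response matrix
#'
#' @param x integer matrix of category codes, persons in rows, items
#'   in columns (column names are item ids); `NA` marks missing.
#' @param person_id optional character vector of person identifiers.
#' @param true_theta,true_class optional simulation truth.
#' @return A `response_matrix`.
#' @export
response_matrix <- function(x, person_id = NULL, true_theta = NULL,
                            true_class = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (any(x < 0L, na.rm = TRUE)) stop("category codes must be >= 0")
  if (is.null(person_id)) person_id <- sprintf("P%05d", seq_len(nrow(x)))
  stopifnot(length(person_id) == nrow(x))
  structure(x, person_id = as.character(person_id),
            true_theta = true_theta, true_class = true_class,
            class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d persons x %d items, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Split a sample into two random halves
#'
#' Partitions the persons of a response matrix into two disjoint random
#' halves without replacement (sizes `ceiling(N/2)` and `floor(N/2)`),
#' as used to check the replicability of a latent class solution.
#'
#' @param rm a `response_matrix` with at least 2 persons.
#' @param seed integer RNG seed.
#' @return A list of two `response_matrix` halves.
#' @export
split_half <- function(rm, seed) {
  stopifnot(inherits(rm, "response_matrix"))
  n <- nrow(rm)
  if (n < 2L) stop("split_half needs at least 2 persons")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  idx1 <- sort(sample.int(n, ceiling(n / 2)))
  idx2 <- setdiff(seq_len(n), idx1)
  list(subset_persons(rm, idx1), subset_persons(rm, idx2))
}

subset_persons <- function(rm, idx) {
  out <- unclass(rm)[idx, , drop = FALSE]
  response_matrix(out,
                  person_id = attr(rm, "person_id")[idx],
                  true_theta = attr(rm, "true_theta")[idx],
                  true_class = attr(rm, "true_class")[idx])
}

#' Read / write response matrices as CSV
#'
#' Persons are rows; the first column holds person ids and the header
#' row the item ids. Missing responses are written as `missing_token`.
#'
#' @param rm a `response_matrix`.
#' @param path file path.
#' @param missing_token string representing a missing response.
#' @return `read_responses` returns a `response_matrix`;
#'   `write_responses` returns `path` invisibly.
#' @export
write_responses <- function(rm, path, missing_token = "NA") {
  df <- as.data.frame(unclass(rm))
  df[] <- lapply(df, function(col) {
    out <- as.character(col); out[is.na(out)] <- missing_token; out
  })
  df <- cbind(person_id = attr(rm, "person_id"), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, missing_token = "NA") {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed response file: ", path)
  if (names(df)[1] != "person_id")
    stop("malformed header: first column must be 'person_id'")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  x <- matrix(NA_integer_, nrow(vals), ncol(vals),
              dimnames = dimnames(vals))
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    miss <- v == missing_token
    num <- suppressWarnings(as.numeric(v[!miss]))
    bad <- is.na(num) | num != round(num) | num < 0
    if (any(bad)) {
      row <- which(!miss)[which(bad)[1]]
      stop(sprintf("unknown or non-integer token '%s' at row %d, column '%s'",
                   v[!miss][which(bad)[1]], row, colnames(vals)[j]))
    }
    x[!miss, j] <- as.integer(num)
  }
  response_matrix(x, person_id = ids)
}
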