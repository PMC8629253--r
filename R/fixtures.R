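#' Published bookmark-vs-cMRM contingency tables
#'
#' The three published 2x2 agreement tables between the bookmark
#' procedure and the constrained mixture Rasch model for the
#' ninth-grade student sample (N = 13,897) and the two adult samples
#' (N = 5,330 and 3,145), shipped as an in-package fixture so the
#' agreement suite can be exercised and reproduced without access to
#' the restricted assessment data.
#'
#' @return Named list of `contingency_2x2` tables: `student`,
#'   `adult1`, `adult2`.
#' @export
published_contingency_tables <- function() {
  path <- system.file("extdata", "agreement_contingency_tables.csv",
                      package = "raschcut", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    contingency_table(df$A[i], df$B[i], df$C[i], df$D[i]))
  names(out) <- df$sample
  out
}
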