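#' Activity label vocabularies
#'
#' The package ships the two six-class vocabularies used by the public
#' smartphone HAR benchmarks. `"uci"` covers walking, walking-upstairs,
#' walking-downstairs, sitting, standing and laying; `"wisdm"` swaps laying
#' for jogging and shortens the stair labels. Class indices are 0-based
#' internally; dataset files that use 1-based codes are converted at the
#' reading boundary.
#'
#' @param vocabulary `"uci"` or `"wisdm"`.
#' @return A tibble with columns `name` (character) and `index` (integer,
#'   0 to 5), one row per activity class.
#' @examples
#' activity_vocabulary("uci")
#' @export
activity_vocabulary <- function(vocabulary = c("uci", "wisdm")) {
  vocabulary <- match.arg(vocabulary)
  names <- switch(vocabulary,
    uci = c("walking", "walking-upstairs", "walking-downstairs",
            "sitting", "standing", "laying"),
    wisdm = c("walking", "jogging", "upstairs", "downstairs",
              "sitting", "standing")
  )
  tibble::tibble(name = names, index = 0:5)
}

#' @keywords internal
#' @noRd
vocab_names <- function(vocabulary) activity_vocabulary(vocabulary)$name

#' Map activity names to 0-based class indices
#' @keywords internal
#' @noRd
label_index <- function(names, vocabulary) {
  vocab <- activity_vocabulary(vocabulary)
  idx <- vocab$index[match(names, vocab$name)]
  if (anyNA(idx)) {
    bad <- unique(names[is.na(idx)])
    stop("activity name(s) outside the '", vocabulary, "' vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}
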