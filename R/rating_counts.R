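#' Rating count tables
#'
#' A `rating_counts` object is the sufficient statistic for all signal
#' detection fitting in this package: a `2 x 2 x K` array of non-negative
#' integer trial counts indexed by stimulus class (`"nonmatch"`, `"match"`),
#' type-1 response (`"nonmatch"`, `"match"`) and rating level (`1..K`).
#' `K` is 2 for the binary pre-rating (bet / memory belief) phase and 5 for
#' the post-decision confidence phase.
#'
#' The "match" class plays the role of the signal (S2) class: a hit is a
#' "match" response to a match trial.
#'
#' @param x either a `2 x 2 x K` numeric array (dimensions stimulus,
#'   response, rating), or a data frame with columns `stimulus`, `response`,
#'   `rating`, `count`.
#' @param K number of rating levels; inferred from `x` when `NULL`.
#' @return a `rating_counts` object.
#' @examples
#' df <- expand.grid(stimulus = c("nonmatch", "match"),
#'                   response = c("nonmatch", "match"), rating = 1:2)
#' df$count <- c(20, 8, 9, 11, 10, 12, 6, 24)
#' rating_counts(df)
#' @export
rating_counts <- function(x, K = NULL) {
  classes <- c("nonmatch", "match")
  if (is.data.frame(x)) {
    req <- c("stimulus", "response", "rating", "count")
    miss <- setdiff(req, names(x))
    if (length(miss) > 0L) {
      stop("rating_counts data frame is missing column(s): ",
           paste(miss, collapse = ", "))
    }
    if (is.null(K)) K <- max(as.integer(x$rating))
    arr <- array(0, dim = c(2L, 2L, K),
                 dimnames = list(stimulus = classes, response = classes,
                                 rating = as.character(seq_len(K))))
    si <- match(as.character(x$stimulus), classes)
    ri <- match(as.character(x$response), classes)
    ki <- as.integer(x$rating)
    if (anyNA(si)) stop("unknown stimulus label; expected 'nonmatch'/'match'")
    if (anyNA(ri)) stop("unknown response label; expected 'nonmatch'/'match'")
    if (any(ki < 1L | ki > K)) stop("rating outside 1..", K)
    for (i in seq_along(si)) {
      arr[si[i], ri[i], ki[i]] <- arr[si[i], ri[i], ki[i]] + x$count[i]
    }
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (!is.null(K) && dim(x)[3] != K) stop("array third dimension != K")
    K <- dim(x)[3]
    if (!all(dim(x)[1:2] == 2L)) stop("first two dimensions must both be 2")
    arr <- x
    dimnames(arr) <- list(stimulus = classes, response = classes,
                          rating = as.character(seq_len(K)))
  } else {
    stop("x must be a 2 x 2 x K array or a stimulus/response/rating/count ",
         "data frame")
  }
  if (K < 2L) stop("K must be >= 2")
  if (any(arr < 0)) stop("counts must be non-negative")
  if (any(abs(arr - round(arr)) > 1e-8)) stop("counts must be integers")
  structure(arr, class = "rating_counts")
}

#' @export
print.rating_counts <- function(x, ...) {
  cat("Rating counts (", sum(x), " trials, K = ", dim(x)[3], " levels)\n",
      sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname rating_counts
#' @param counts a `rating_counts` object.
#' @export
as.data.frame.rating_counts <- function(x, ...) {
  K <- dim(x)[3]
  df <- expand.grid(stimulus = c("nonmatch", "match"),
                    response = c("nonmatch", "match"),
                    rating = seq_len(K), stringsAsFactors = FALSE)
  df$count <- as.vector(unclass(x))
  df
}

#' Read / write rating count tables as flat CSV
#'
#' Serializes a [rating_counts] table to a four-column CSV
#' (`stimulus,response,rating,count`) and back.
#'
#' @param counts a `rating_counts` object.
#' @param path file path.
#' @return `read_rating_counts` returns a `rating_counts` object;
#'   `write_rating_counts` returns `path`, invisibly.
#' @export
write_rating_counts <- function(counts, path) {
  stopifnot(inherits(counts, "rating_counts"))
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rating_counts
#' @export
read_rating_counts <- function(path) {
  rating_counts(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Tabulate rating counts from trial-level data
#'
#' Builds one [rating_counts] table per participant and difficulty condition
#' from a validated trial table (see [read_trials] for the schema). The
#' `phase` argument selects the prospective binary pre-rating (`K = 2`) or
#' the retrospective 5-point post-rating (`K = 5`).
#'
#' @param trials a trial data frame (exclusions should already have been
#'   applied; rows with missing stimulus, response or rating are dropped).
#' @param phase `"pre"` or `"post"`.
#' @return a data frame with columns `participant_id`, `instruction`,
#'   `difficulty` and a list-column `counts` of `rating_counts`.
#' @export
tabulate_rating_counts <- function(trials, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  rating_col <- if (phase == "pre") "pre_rating" else "post_rating"
  K <- if (phase == "pre") 2L else 5L
  keep <- !is.na(trials$stimulus) & !is.na(trials$type1_response) &
    !is.na(trials[[rating_col]])
  trials <- trials[keep, , drop = FALSE]
  key <- interaction(trials$participant_id, trials$difficulty, drop = TRUE)
  groups <- split(trials, key)
  out <- lapply(groups, function(g) {
    arr <- array(0, dim = c(2L, 2L, K))
    si <- ifelse(g$stimulus == "match", 2L, 1L)
    ri <- ifelse(g$type1_response == "match", 2L, 1L)
    ki <- as.integer(g[[rating_col]])
    for (i in seq_along(si)) arr[si[i], ri[i], ki[i]] <-
        arr[si[i], ri[i], ki[i]] + 1
    list(participant_id = g$participant_id[1],
         instruction = g$instruction[1],
         difficulty = g$difficulty[1],
         counts = rating_counts(arr))
  })
  data.frame(
    participant_id = vapply(out, `[[`, character(1), "participant_id"),
    instruction = vapply(out, `[[`, character(1), "instruction"),
    difficulty = vapply(out, `[[`, character(1), "difficulty"),
    counts = I(lapply(out, `[[`, "counts")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
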