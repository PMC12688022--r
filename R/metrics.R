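#' Expert agreement proportion for vignette ratings
#'
#' Ratings compare the high-expertise care algorithm's recommendation with a
#' base algorithm against the expert's own judgment, per care field and
#' clinical vignette, on a 5-point scale: 0 (both algorithms perfectly agree
#' with the expert), 1 (worse than base), 2 (as bad as base), 3 (better than
#' base), 4 (better than base and perfectly agrees). The agreement proportion
#' is the fraction of ratings in \{0, 3, 4\} — cases where the high-expertise
#' recommendation was judged appropriate.
#'
#' @param scores Integer vector of ratings in `0:4` (one field, or pooled).
#' @return A list with `numerator`, `denominator` and `proportion`.
#' @examples
#' agreement_proportion(c(0, 3, 4, 2))
#' @export
agreement_proportion <- function(scores) {
  check_ratings(scores, 0:4)
  num <- sum(scores %in% c(0L, 3L, 4L))
  list(numerator = num, denominator = length(scores),
       proportion = num / length(scores))
}

#' Expert improvement proportion for vignette ratings
#'
#' Among vignettes where the two algorithms did not both perfectly agree with
#' the expert (rating non-zero), the fraction rated better than the base
#' algorithm (ratings 3 or 4). When every rating in the field is 0 there is
#' no disagreement to improve on and the proportion is undefined: `NULL` is
#' returned, and such fields contribute neither numerator nor denominator to
#' pooled summaries.
#'
#' @param scores Integer vector of ratings in `0:4`.
#' @return A list with `numerator`, `denominator`, `proportion`, or `NULL`
#'   when all ratings are 0.
#' @examples
#' improvement_proportion(c(0, 0, 3, 4)) # 2/2
#' improvement_proportion(c(0, 0, 0, 0)) # NULL
#' @export
improvement_proportion <- function(scores) {
  check_ratings(scores, 0:4)
  den <- sum(scores %in% 1:4)
  if (den == 0L) return(NULL)
  num <- sum(scores %in% c(3L, 4L))
  list(numerator = num, denominator = den, proportion = num / den)
}

#' Mean expected healing level
#'
#' The expert's rating of the healing expected if all recommendations of the
#' high-expertise algorithm were applied, on a 4-point scale:
#' 1 worsens, 2 stagnates, 3 improves, 4 much improves.
#'
#' @param ratings Integer vector of ratings in `1:4`.
#' @return Arithmetic mean on the 1-4 scale.
#' @examples
#' expected_healing_mean(c(4, 4, 3, 2)) # 3.25
#' @export
expected_healing_mean <- function(ratings) {
  check_ratings(ratings, 1:4)
  mean(ratings)
}

check_ratings <- function(scores, scale) {
  if (length(scores) == 0) stop("no ratings supplied", call. = FALSE)
  if (anyNA(scores) || !all(scores %in% scale)) {
    stop("ratings must lie in {", paste(range(scale), collapse = "..."), "}",
         call. = FALSE)
  }
  invisible(scores)
}

#' Per-field and pooled vignette metrics
#'
#' Computes agreement and improvement proportions per care field and pooled
#' count-wise (sum of numerators over sum of denominators, so that e.g. nine
#' fields of four vignettes pool to a denominator of 36). Fields whose
#' improvement proportion is `NULL` (all ratings 0) are excluded from the
#' pooled improvement numerator and denominator.
#'
#' @param ratings A data.frame with columns `field`, `vignette`, `score`
#'   (ratings on the 0-4 scale). Typically one evaluation round.
#' @return A list with `per_field` (data.frame: field, agreement and
#'   improvement counts/fractions, improvement `NA` where undefined) and
#'   `pooled` (agreement and improvement numerator/denominator/proportion).
#' @export
vignette_metrics <- function(ratings) {
  stopifnot(all(c("field", "score") %in% names(ratings)))
  fields <- unique(ratings$field)
  per <- lapply(fields, function(f) {
    sc <- ratings$score[ratings$field == f]
    ag <- agreement_proportion(sc)
    im <- improvement_proportion(sc)
    data.frame(field = f,
               agree_num = ag$numerator, agree_den = ag$denominator,
               agreement = ag$proportion,
               improve_num = if (is.null(im)) NA_integer_ else im$numerator,
               improve_den = if (is.null(im)) NA_integer_ else im$denominator,
               improvement = if (is.null(im)) NA_real_ else im$proportion,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  ok <- !is.na(per$improve_den)
  pooled <- list(
    agreement = list(numerator = sum(per$agree_num),
                     denominator = sum(per$agree_den),
                     proportion = sum(per$agree_num) / sum(per$agree_den)),
    improvement = if (any(ok)) {
      list(numerator = sum(per$improve_num[ok]),
           denominator = sum(per$improve_den[ok]),
           proportion = sum(per$improve_num[ok]) / sum(per$improve_den[ok]))
    } else NULL
  )
  list(per_field = per, pooled = pooled)
}

#' Read a vignette-rating CSV
#'
#' Expected columns: `round`, `field`, `vignette`, `score`. The package ships
#' a synthetic reconstruction of the published evaluation rounds
#' (`system.file("extdata", "study1_ratings_synthetic.csv", package =
#' "piheal")`): individual ratings were not published, so each field's ratings
#' are representative values consistent with the published per-field
#' agreement/improvement counts (which the metrics reproduce exactly).
#'
#' @param path CSV path.
#' @return data.frame of ratings.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("round", "field", "vignette", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("rating file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  check_ratings(df$score, 0:4)
  df
}
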