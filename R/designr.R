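#' DESIGN-R 2020 subscale configuration
#'
#' Permissible score sets and the large/small (uppercase/lowercase) partition
#' for the six subscales entering the DESIGN-R 2020 total score. The total is
#' the sum of Exudate (E), Size (S), Inflammation/infection (I), Granulation
#' (G), Necrotic tissue (N) and Pocket (P); Depth (D) is recorded but excluded
#' from the total.
#'
#' Only the Exudate rule (6 is "large" E; 1 and 3 are "small" e; 0 is neither)
#' is fixed by the modelling context; the partitions of the remaining subscales
#' are instrument-derived defaults following the published DESIGN-R 2020
#' uppercase/lowercase convention and can be overridden by supplying a
#' modified table to the coding functions.
#'
#' @return A named list, one element per subscale (`e`, `s`, `i`, `g`, `n`,
#'   `p`), each a list with integer vectors `large`, `small` and `zero`.
#'   The permissible set of a subscale is the union of the three.
#' @examples
#' designr_cutoffs()$e
#' @export
designr_cutoffs <- function() {
  list(
    e = list(large = 6L,               small = c(1L, 3L),             zero = 0L),
    s = list(large = 15L,              small = c(3L, 6L, 8L, 9L, 12L), zero = 0L),
    i = list(large = c(3L, 9L),        small = 1L,                    zero = 0L),
    g = list(large = c(4L, 5L, 6L),    small = c(1L, 3L),             zero = 0L),
    n = list(large = c(3L, 6L),        small = integer(0),            zero = 0L),
    p = list(large = c(6L, 9L, 12L, 24L), small = integer(0),         zero = 0L)
  )
}

.designr_subscales <- c("e", "s", "i", "g", "n", "p")

#' Permissible values of one subscale
#' @param name Subscale id, one of `"e","s","i","g","n","p"`.
#' @param cutoffs A cutoff table, as from [designr_cutoffs()].
#' @return Sorted integer vector of permissible scores.
#' @export
designr_permissible <- function(name, cutoffs = designr_cutoffs()) {
  name <- match.arg(tolower(name), .designr_subscales)
  cs <- cutoffs[[name]]
  sort(unique(c(cs$zero, cs$small, cs$large)))
}

#' A single DESIGN-R 2020 assessment
#'
#' Validates the six scored subscales against their permissible value sets and
#' stores the depth code alongside (depth never enters the total score or the
#' dummy coding).
#'
#' @param depth Depth code (integer; recorded, excluded from the total).
#' @param e,s,i,g,n,p Integer subscale scores.
#' @param cutoffs Cutoff/permissible-value table, see [designr_cutoffs()].
#' @return An object of class `designr_assessment`.
#' @examples
#' a <- designr_assessment(depth = 3, e = 3, s = 8, i = 1, g = 4, n = 3, p = 0)
#' total_score(a)
#' @export
designr_assessment <- function(depth, e, s, i, g, n, p,
                               cutoffs = designr_cutoffs()) {
  vals <- list(e = e, s = s, i = i, g = g, n = n, p = p)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1 || is.na(v)) {
      stop("missing subscale score: ", nm, call. = FALSE)
    }
    if (v != as.integer(v) || !(as.integer(v) %in% designr_permissible(nm, cutoffs))) {
      stop(sprintf("subscale '%s': score %s is not in the permissible set {%s}",
                   nm, format(v),
                   paste(designr_permissible(nm, cutoffs), collapse = ",")),
           call. = FALSE)
    }
    vals[[nm]] <- as.integer(v)
  }
  if (length(depth) != 1 || is.na(depth)) stop("missing subscale score: depth", call. = FALSE)
  structure(c(list(depth = as.integer(depth)), vals),
            class = "designr_assessment")
}

#' @export
print.designr_assessment <- function(x, ...) {
  cat(sprintf("DESIGN-R 2020 assessment: D%d E%d S%d I%d G%d N%d P%d (total %d)\n",
              x$depth, x$e, x$s, x$i, x$g, x$n, x$p, total_score(x)))
  invisible(x)
}

#' DESIGN-R 2020 total severity score
#'
#' Sum of the six scored subscales (E, S, I, G, N, P); depth is excluded.
#' Higher totals indicate a more severe pressure injury.
#'
#' @param a A [designr_assessment()], or a list/data.frame row with fields
#'   `e,s,i,g,n,p`.
#' @return Integer total score.
#' @export
total_score <- function(a) {
  for (nm in .designr_subscales) {
    v <- a[[nm]]
    if (is.null(v) || length(v) == 0 || anyNA(v)) {
      stop("missing subscale score: ", nm, call. = FALSE)
    }
  }
  as.integer(a$e + a$s + a$i + a$g + a$n + a$p)
}

#' Large/small dummy coding of one subscale score
#'
#' Encodes a subscale score as the mutually exclusive pair of indicators
#' (large, small) following the DESIGN-R 2020 uppercase/lowercase
#' classification: e.g. an E score of 6 codes as "large" E `(1, 0)`, an E
#' score of 1 or 3 as "small" e `(0, 1)`, and a score of 0 as neither
#' `(0, 0)`.
#'
#' @param name Subscale id (`"e","s","i","g","n","p"`).
#' @param score Integer score, must lie in the subscale's permissible set.
#' @param cutoffs Cutoff table, see [designr_cutoffs()].
#' @return Named integer vector `c(large = 0/1, small = 0/1)`.
#' @examples
#' binarize_subscale("e", 6) # large
#' binarize_subscale("e", 3) # small
#' binarize_subscale("e", 0) # neither
#' @export
binarize_subscale <- function(name, score, cutoffs = designr_cutoffs()) {
  name <- match.arg(tolower(name), .designr_subscales)
  cs <- cutoffs[[name]]
  if (length(score) != 1 || is.na(score) ||
      !(score %in% designr_permissible(name, cutoffs))) {
    stop(sprintf("subscale '%s': score %s is not in the permissible set {%s}",
                 name, format(score),
                 paste(designr_permissible(name, cutoffs), collapse = ",")),
         call. = FALSE)
  }
  c(large = as.integer(score %in% cs$large),
    small = as.integer(score %in% cs$small))
}

#' Change in total score between two assessments of one pressure injury
#'
#' The modelled quantity: `d = y_ts - y_t`, the signed change in the DESIGN-R
#' 2020 total between an assessment at day `t` and the next at day `t + s`.
#' Negative values indicate healing. No transformation is applied.
#'
#' @param y_t Total score at the earlier assessment.
#' @param y_ts Total score at the later assessment.
#' @return Signed integer change.
#' @examples
#' score_change(19, 28) # +9, a worsening (e.g. infection)
#' score_change(12, 5)  # -7, healing
#' @export
score_change <- function(y_t, y_ts) {
  as.integer(y_ts) - as.integer(y_t)
}
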