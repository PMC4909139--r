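# Stunting classification and the LMS z-score transform.
#
# The primary input path supplies HAZ directly (survey recodes ship
# z-scores); computing HAZ from raw height via an LMS reference is a
# convenience path for users bringing their own growth-standard table.

#' Classify stunting from a height-for-age z-score
#'
#' A child is stunted when height-for-age is more than 2 SD below the
#' growth-standard median, i.e. strictly HAZ < -2.
#'
#' @param haz numeric vector of height-for-age z-scores; must be finite.
#' @return logical vector.
#' @export
#' @examples
#' classify_stunting(c(-2.01, -2, 1.5))  # TRUE FALSE FALSE
classify_stunting <- function(haz) {
  if (any(!is.finite(haz))) stop("haz must be finite; handle missing HAZ upstream")
  haz < -2
}

#' Read an LMS growth reference table
#'
#' Expects columns `sex` ("male"/"female"), `age_months`, `L`, `M`, `S`.
#' Ages must be contiguous within each sex so lookups cannot silently skip
#' a month.
#'
#' @param path path to a CSV file.
#' @return validated data.frame.
#' @export
read_lms_reference <- function(path) {
  stopifnot(file.exists(path))
  ref <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("sex", "age_months", "L", "M", "S")
  missing_cols <- setdiff(needed, names(ref))
  if (length(missing_cols)) stop("LMS reference missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0)) stop("LMS reference requires M > 0 and S > 0")
  for (sx in unique(ref$sex)) {
    ages <- sort(ref$age_months[ref$sex == sx])
    if (length(ages) > 1 && any(diff(ages) != 1L)) {
      stop("LMS reference ages not contiguous for sex ", sx)
    }
  }
  ref
}

#' Height-for-age z-score from measured height via the LMS transform
#'
#' z = ((height/M)^L - 1) / (L * S) for L != 0, and log(height/M)/S when
#' L = 0, using the (sex, age) row of the reference.
#'
#' @param height_cm measured length/height in cm, positive.
#' @param age_months completed age in months.
#' @param sex "male" or "female".
#' @param ref LMS reference table from [read_lms_reference()].
#' @return numeric z-score vector.
#' @export
haz_from_height <- function(height_cm, age_months, sex, ref) {
  n <- max(length(height_cm), length(age_months), length(sex))
  height_cm <- rep_len(height_cm, n)
  age_months <- rep_len(age_months, n)
  sex <- rep_len(sex, n)
  if (any(!is.finite(height_cm) | height_cm <= 0)) stop("height_cm must be positive")
  key <- paste(ref$sex, ref$age_months)
  idx <- match(paste(sex, age_months), key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop(sprintf("no LMS reference row for sex=%s, age_months=%s", sex[miss], age_months[miss]))
  }
  L <- ref$L[idx]; M <- ref$M[idx]; S <- ref$S[idx]
  ifelse(L != 0,
         ((height_cm / M)^L - 1) / (L * S),
         log(height_cm / M) / S)
}
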