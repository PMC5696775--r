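# Segmentation accuracy metrics (Qseg, Sr, Es), fractional vegetation
# cover, and day-course / time-series summaries.

check_mask_pair <- function(S, R) {
  validate_mask(S)
  validate_mask(R)
  if (!identical(dim(S), dim(R))) {
    stop("segmented and reference masks have different dimensions (",
         paste(dim(S), collapse = "x"), " vs ",
         paste(dim(R), collapse = "x"), ")", call. = FALSE)
  }
}

#' Segmentation quality factor Qseg (intersection over union)
#'
#' Pixel-wise agreement between a segmented mask `S` and a reference mask
#' `R` over plant pixels: `|S AND R| / |S OR R|`. 1 is a perfect outcome;
#' symmetric in its arguments.
#'
#' @param S,R Logical plant/background matrices of equal dimensions.
#' @return A number in \[0, 1\].
#' @export
qseg <- function(S, R) {
  check_mask_pair(S, R)
  u <- sum(S | R)
  if (u == 0L) {
    stop("both masks are empty of plant pixels: Qseg is undefined",
         call. = FALSE)
  }
  sum(S & R) / u
}

#' Plant-region consistency Sr
#'
#' As printed, the true-positive rate `|S AND R| / |R|` (so `sr <= 1`).
#' Some reported uses of this metric behave as the plant-pixel ratio
#' `|S| / |R|`, which can exceed 1; that variant is available with
#' `variant = "ratio"`.
#'
#' @inheritParams qseg
#' @param variant `"printed"` (default) for `|S AND R| / |R|`, or
#'   `"ratio"` for `|S| / |R|`.
#' @return A non-negative number (at most 1 for the printed variant).
#' @export
sr <- function(S, R, variant = c("printed", "ratio")) {
  variant <- match.arg(variant)
  check_mask_pair(S, R)
  nR <- sum(R)
  if (nR == 0L) {
    stop("reference mask has no plant pixels: Sr is undefined",
         call. = FALSE)
  }
  if (variant == "printed") sum(S & R) / nR else sum(S) / nR
}

#' Misclassification error factor Es
#'
#' False-positive plant pixels relative to the reference plant count:
#' `|S AND NOT R| / |R|`. 0 is a perfect outcome.
#'
#' @inheritParams qseg
#' @return A non-negative number.
#' @export
es <- function(S, R) {
  check_mask_pair(S, R)
  nR <- sum(R)
  if (nR == 0L) {
    stop("reference mask has no plant pixels: Es is undefined",
         call. = FALSE)
  }
  sum(S & !R) / nR
}

#' Evaluate a segmentation against a reference mask
#'
#' Bundles the three accuracy metrics [qseg()], [sr()] and [es()].
#'
#' @inheritParams qseg
#' @param sr_variant Passed to [sr()] as `variant`.
#' @return An object of class `"segmentation_scores"`: a list with
#'   elements `qseg`, `sr`, `es`.
#' @export
evaluate_masks <- function(S, R, sr_variant = "printed") {
  structure(
    list(qseg = qseg(S, R), sr = sr(S, R, variant = sr_variant),
         es = es(S, R)),
    class = "segmentation_scores")
}

#' @export
print.segmentation_scores <- function(x, ...) {
  cat(sprintf("Segmentation scores: Qseg = %.4f, Sr = %.4f, Es = %.4f\n",
              x$qseg, x$sr, x$es))
  invisible(x)
}

#' Fractional vegetation cover of a mask
#'
#' The ratio of plant pixels to the total pixel count.
#'
#' @param mask A logical plant/background matrix.
#' @return A number in \[0, 1\].
#' @export
fvc <- function(mask) {
  validate_mask(mask)
  if (length(mask) == 0L) {
    stop("mask has no pixels: FVC is undefined", call. = FALSE)
  }
  mean(mask)
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(values) / mean(values)` with the sample (n - 1) standard
#' deviation; the day-course stability statistic for FVC series.
#'
#' @param values At least two numbers with non-zero mean.
#' @return The CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) {
    stop("at least two values are needed for a coefficient of variation",
         call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) {
    stop("mean of values is zero: CV is undefined", call. = FALSE)
  }
  100 * stats::sd(values) / m
}

#' Summarize an FVC time series per method
#'
#' Groups FVC records by segmentation method and reports the mean, sample
#' standard deviation and coefficient of variation of each method's series,
#' ordered by method name. Methods with a single record are excluded with a
#' warning (their SD is undefined).
#'
#' @param records A data frame with columns `method` and `fvc` (extra
#'   columns such as `image_id` and `timestamp` are allowed and ignored).
#' @return A data frame with columns `method`, `n`, `mean`, `sd`,
#'   `cv_percent`.
#' @export
summarize_timeseries <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("method", "fvc") %in% names(records)))
  counts <- table(records$method)
  single <- names(counts)[counts < 2L]
  if (length(single) > 0L) {
    warning("excluding method(s) with a single record: ",
            paste(single, collapse = ", "), call. = FALSE)
    records <- records[!records$method %in% single, , drop = FALSE]
  }
  methods <- sort(unique(records$method))
  out <- do.call(rbind, lapply(methods, function(m) {
    v <- records$fvc[records$method == m]
    data.frame(method = m, n = length(v), mean = mean(v),
               sd = stats::sd(v), cv_percent = cv_percent(v))
  }))
  rownames(out) <- NULL
  out
}
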