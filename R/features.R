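#' Tumor volume from caliper measurements
#'
#' `V = length^2 * width / 2`, with `length` the longest diameter across
#' the tumor and `width` the perpendicular diameter. If `width > length`
#' the inputs are swapped with a warning to enforce the convention.
#'
#' @param length,width Caliper diameters in mm (> 0); vectorized.
#' @return Volume in mm^3.
#' @examples
#' caliper_volume(10, 10)  # 500 mm^3
#' @export
caliper_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) {
    stop_validation("caliper diameters must be positive")
  }
  swap <- width > length
  if (any(swap)) {
    warning("width > length for some tumors; swapping to enforce the ",
            "longest-diameter convention")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * length * width / 2
}

input_set_params <- function(input_set = c("all", "adc", "ktrans")) {
  input_set <- match.arg(input_set)
  switch(input_set,
         all = c("V", "PSA", "ADC", "Ktrans"),
         adc = c("V", "PSA", "ADC"),
         ktrans = c("V", "PSA", "Ktrans"))
}

#' Build the baseline-normalized feature matrix from a cohort
#'
#' For each selected parameter p the day-1 and day-9 values are divided by
#' the animal's own day-0 value, giving the ratios `p(d1)/p(d0)` and
#' `p(d9)/p(d0)`; the constant day-0 self-ratio is excluded as
#' non-informative unless `include_day0 = TRUE`. Four one-hot treatment
#' group columns are appended. The prediction target is the
#' baseline-normalized endpoint `V30/V(d0)`.
#'
#' @param cohort An [simulate_cohort()] cohort (or any data.frame with the
#'   same columns).
#' @param input_set `"all"` (V, PSA, ADC, Ktrans), `"adc"` (V, PSA, ADC)
#'   or `"ktrans"` (V, PSA, Ktrans).
#' @param include_day0 Also emit the day-0 self-ratio columns
#'   (identically 1).
#' @return A data.frame of class `feature_matrix`: feature columns, the
#'   `target` column, and attributes `feature_names` (the column manifest,
#'   in order), `input_set` and `ids`.
#' @examples
#' fm <- build_features(simulate_cohort(seed = 1), "all")
#' length(attr(fm, "feature_names"))  # 12
#' @export
build_features <- function(cohort, input_set = c("all", "adc", "ktrans"),
                           include_day0 = FALSE) {
  input_set <- match.arg(input_set)
  params <- input_set_params(input_set)
  need <- c(paste0(rep(params, each = 3), "_", c("d0", "d1", "d9")), "V_d30")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop_validation("cohort lacks columns: %s", paste(miss, collapse = ", "))
  }
  days <- if (include_day0) c("d0", "d1", "d9") else c("d1", "d9")
  feat <- list()
  for (p in params) {
    d0 <- cohort[[paste0(p, "_d0")]]
    bad <- which(!(d0 > 0))
    if (length(bad)) {
      stop_validation("non-positive day-0 %s for animal(s): %s", p,
                      paste(cohort$id[bad], collapse = ", "))
    }
    for (d in days) {
      feat[[paste0(p, "_", d, "_ratio")]] <- cohort[[paste0(p, "_", d)]] / d0
    }
  }
  grp <- as.factor(cohort$group)
  for (g in levels(grp)) {
    feat[[paste0("group_", gsub("[^A-Za-z0-9]", "_", g))]] <-
      as.numeric(grp == g)
  }
  out <- as.data.frame(feat)
  fn <- names(out)
  out$target <- cohort$V_d30 / cohort$V_d0
  if (anyNA(out)) stop_validation("missing values in the feature matrix")
  structure(out, feature_names = fn, input_set = input_set,
            ids = cohort$id, class = c("feature_matrix", "data.frame"))
}
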