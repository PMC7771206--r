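# Image quantification: epithelial tissue proportion from label masks.
#
# Masks are integer matrices with labels 0 = background, 1 = epithelial,
# 2 = stromal. The proportion is computed over tissue pixels only; any other
# label value is treated as a mis-encoded mask and raised as an error rather
# than silently folded into the background.

MASK_BACKGROUND <- 0L
MASK_EPITHELIAL <- 1L
MASK_STROMAL <- 2L

#' Epithelial tissue proportion of a segmentation mask
#'
#' Computes `Area_epi / (Area_epi + Area_stro)` from a label mask, where the
#' areas are pixel counts of the epithelial (label 1) and stromal (label 2)
#' classes. Background pixels (label 0) are excluded from both numerator and
#' denominator, so the proportion is invariant to padding the mask.
#'
#' @param mask integer matrix with values in `{0, 1, 2}`.
#' @return a single number in `[0, 1]`.
#' @examples
#' m <- matrix(0L, 10, 10)
#' m[1:6, 1] <- 1L; m[7:10, 1] <- 2L
#' epithelial_proportion(m) # 0.6
#' @export
epithelial_proportion <- function(mask) {
  if (!is.matrix(mask) || length(mask) == 0L) {
    stop_invalid("`mask` must be a non-empty matrix")
  }
  vals <- as.integer(mask)
  bad <- setdiff(unique(vals), c(MASK_BACKGROUND, MASK_EPITHELIAL, MASK_STROMAL))
  if (length(bad) > 0L) {
    stop_invalid("mask contains unknown label value(s): %s",
                 paste(bad, collapse = ", "))
  }
  n_epi <- sum(vals == MASK_EPITHELIAL)
  n_str <- sum(vals == MASK_STROMAL)
  if (n_epi + n_str == 0L) {
    stop("mask contains no tissue pixels; proportion undefined", call. = FALSE)
  }
  n_epi / (n_epi + n_str)
}

#' Classify epithelial-high vs epithelial-low
#'
#' Samples with proportion greater than or equal to the cutoff are classified
#' "high", the rest "low". The boundary is inclusive for "high".
#'
#' @param proportion numeric vector of epithelial proportions in `[0, 1]`.
#' @param cutoff classification boundary, default 0.5.
#' @return character vector of `"high"` / `"low"`.
#' @export
classify_group <- function(proportion, cutoff = 0.5) {
  check_scalar_number(cutoff, "cutoff", 0, 1)
  if (!is.numeric(proportion) || anyNA(proportion) ||
      any(proportion < 0 | proportion > 1)) {
    stop_invalid("`proportion` must be numeric in [0, 1] with no NA")
  }
  ifelse(proportion >= cutoff, "high", "low")
}

#' Build a cohort table from sample proportions
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param proportion epithelial proportions in `[0, 1]`.
#' @param cutoff high/low classification boundary.
#' @return data.frame with columns `sample_id`, `proportion`, `group`.
#' @export
make_cohort <- function(sample_id, proportion, cutoff = 0.5) {
  if (length(sample_id) != length(proportion)) {
    stop_invalid("`sample_id` and `proportion` lengths differ")
  }
  if (anyDuplicated(sample_id)) stop_invalid("`sample_id` must be unique")
  data.frame(
    sample_id = as.character(sample_id),
    proportion = as.numeric(proportion),
    group = classify_group(proportion, cutoff),
    stringsAsFactors = FALSE
  )
}

#' Summarize the high/low composition of a cohort
#'
#' @param cohort data.frame with columns `sample_id` and `proportion`.
#' @param cutoff classification boundary, default 0.5.
#' @return list with `n_low`, `n_high`, `low_fraction`.
#' @examples
#' co <- make_cohort(c("a", "b", "c"), c(0.2, 0.5, 0.7))
#' cohort_summary(co) # 1 low, 2 high
#' @export
cohort_summary <- function(cohort, cutoff = 0.5) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop_invalid("`cohort` must be a non-empty data.frame")
  }
  grp <- classify_group(cohort$proportion, cutoff)
  n_low <- sum(grp == "low")
  n_high <- sum(grp == "high")
  list(n_low = n_low, n_high = n_high, low_fraction = n_low / nrow(cohort))
}

#' Quantify a directory of masks into a cohort table
#'
#' Reads every `*.tsv` label mask in `dir` (file stem = sample id), computes
#' the epithelial proportion of each, and assembles a cohort table.
#'
#' @param dir directory containing label-mask TSV files.
#' @param cutoff high/low classification boundary.
#' @return cohort data.frame as from [make_cohort()].
#' @export
quantify_masks <- function(dir, cutoff = 0.5) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop_invalid("no .tsv masks found in %s", dir)
  props <- vapply(files, function(f) epithelial_proportion(read_mask(f)),
                  numeric(1))
  make_cohort(sub("\\.tsv$", "", basename(files)), unname(props), cutoff)
}
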