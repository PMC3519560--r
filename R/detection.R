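#' Count spots above background
#'
#' AbB(g, S): the number of arrays in subset S on which gene g's spot was
#' above background.
#'
#' @param expr a `ck_expr`.
#' @param arrays character vector of array ids (must be a subset of the
#'   design's arrays); defaults to all arrays.
#' @return named integer vector, one count per gene.
#' @export
count_above_background <- function(expr, arrays = expr$design$array_id) {
  stopifnot(inherits(expr, "ck_expr"))
  if (length(arrays) == 0) stop("empty array subset")
  unknown <- setdiff(arrays, expr$design$array_id)
  if (length(unknown) > 0)
    stop("arrays not in design: ", paste(unknown, collapse = ", "))
  counts <- rowSums(expr$mask[, arrays, drop = FALSE])
  stats::setNames(as.integer(counts), rownames(expr$mask))
}

#' Apply the detection filters
#'
#' Computes per-gene AbB counts on the full array set and on the induction
#' and deficiency subsets, and derives the study's detection flags:
#' \describe{
#'   \item{not_expressed}{detected on fewer than `abb_not_expressed` arrays in
#'     total (default 4); excluded from all analyses.}
#'   \item{model_eligible}{at least `abb_model_min` (default 10) total
#'     detections; required for the full-model fit and PCA selection.}
#'   \item{induction_eligible / deficiency_eligible}{detected on at least
#'     `ceiling(abb_subset_fraction * subset size)` arrays of the respective
#'     subset (defaults: 8 of 32 induction arrays, 4 of 16 deficiency
#'     arrays).}
#' }
#'
#' @param expr a `ck_expr`.
#' @param th a `ck_thresholds`.
#' @return a `ck_detection` data frame with columns `gene`, `abb_total`,
#'   `abb_induction`, `abb_deficiency` and the four 0/1-codable logical flags.
#' @export
detection_report <- function(expr, th = thresholds()) {
  stopifnot(inherits(expr, "ck_expr"), inherits(th, "ck_thresholds"))
  ind <- induction_arrays(expr$design)
  def <- deficiency_arrays(expr$design)
  rep <- data.frame(
    gene = rownames(expr$values),
    abb_total = count_above_background(expr),
    abb_induction = count_above_background(expr, ind),
    abb_deficiency = count_above_background(expr, def),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rep$not_expressed <- rep$abb_total < th$abb_not_expressed
  rep$model_eligible <- rep$abb_total >= th$abb_model_min
  rep$induction_eligible <-
    rep$abb_induction >= ceiling(th$abb_subset_fraction * length(ind))
  rep$deficiency_eligible <-
    rep$abb_deficiency >= ceiling(th$abb_subset_fraction * length(def))
  class(rep) <- c("ck_detection", "data.frame")
  rep
}

#' @rdname detection_report
#' @param detection a `ck_detection`.
#' @param path output TSV path; flags are written as 0/1.
#' @export
write_detection_report <- function(detection, path) {
  out <- detection
  for (col in c("not_expressed", "model_eligible",
                "induction_eligible", "deficiency_eligible"))
    out[[col]] <- as.integer(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
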