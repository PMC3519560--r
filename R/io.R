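#' Construct an expression matrix container
#'
#' Holds log2 steady-state intensities (common-reference single-channel
#' estimates) together with the parallel "above background" detection mask.
#' Cells where the mask is `FALSE` are non-quantitative and are treated as
#' missing throughout the analysis; their stored value is `NA`.
#'
#' @param values numeric genes x arrays matrix of log2 intensities, with gene
#'   ids as rownames and array ids as colnames.
#' @param mask logical matrix of the same shape; `TRUE` where the spot was
#'   above background.
#' @param design a `ck_design`; column order of `values` must match
#'   `design$array_id`.
#' @return a `ck_expr` list with elements `values`, `mask`, `design`.
#' @export
expression_matrix <- function(values, mask, design) {
  stopifnot(is.matrix(values), is.matrix(mask),
            identical(dim(values), dim(mask)))
  design <- validate_design(design)
  if (!identical(colnames(values), design$array_id))
    stop("column order of values must match design$array_id")
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ", rownames(values)[duplicated(rownames(values))][1])
  mode(mask) <- "logical"
  dimnames(mask) <- dimnames(values)
  if (any(mask & !is.finite(values)))
    stop("non-finite value at a cell marked above background")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, design = design),
            class = "ck_expr")
}

#' @export
print.ck_expr <- function(x, ...) {
  cat(sprintf("ck_expr: %d genes x %d arrays (%.1f%% above background)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' Read an expression table
#'
#' Reads a tab-delimited gene x array table of log2 intensities. The first
#' column (`gene`) holds probe ids; the remaining column names must be array
#' ids known to `design`. Cells are either finite numbers or the sentinel
#' `NA`, which marks a spot below background (mask `FALSE`). Columns are
#' re-ordered to the design's array order.
#'
#' @param path TSV file path.
#' @param design a `ck_design`.
#' @return a `ck_expr`.
#' @export
read_expression_table <- function(path, design) {
  design <- validate_design(design)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (names(raw)[1] != "gene") stop("first column must be named 'gene'")
  arrays <- names(raw)[-1]
  unknown <- setdiff(arrays, design$array_id)
  if (length(unknown) > 0)
    stop("unknown array_id in expression table: ",
         paste(unknown, collapse = ", "))
  if (length(setdiff(design$array_id, arrays)) > 0)
    stop("expression table is missing arrays: ",
         paste(setdiff(design$array_id, arrays), collapse = ", "))
  genes <- raw$gene
  if (anyDuplicated(genes))
    stop("duplicate gene row: ", genes[duplicated(genes)][1])
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at gene '%s', array '%s': '%s'",
                 genes[bad[1, 1]], arrays[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]))
  dimnames(vals) <- list(genes, arrays)
  vals <- vals[, design$array_id, drop = FALSE]
  expression_matrix(vals, !is.na(vals), design)
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]: below-background cells are written as
#' the sentinel `NA`. Values round-trip at full double precision.
#'
#' @param expr a `ck_expr`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(inherits(expr, "ck_expr"))
  out <- format(expr$values, digits = 17, trim = TRUE, scientific = FALSE)
  out[!expr$mask] <- "NA"
  df <- data.frame(gene = rownames(expr$values), out,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the study design table
#' @param path TSV path with columns `array_id`, `organ`, `condition`,
#'   `biological_replicate`, `technical_replicate`.
#' @return a `ck_design`.
#' @export
read_design_table <- function(path) {
  validate_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_design_table
#' @param design a `ck_design`.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the gene annotation table
#'
#' Annotation columns: `probe_id` (CATMA id), `agi` (AGI locus), `description`,
#' and `localization` — a comma-separated set of single-character subcellular
#' localization codes (uppercase `P` = plastid), `-` when empty.
#'
#' @param path TSV path.
#' @return data frame classed `ck_annotation`.
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  req <- c("probe_id", "agi", "description", "localization")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0)
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id))
    stop("duplicate probe_id in annotation: ",
         ann$probe_id[duplicated(ann$probe_id)][1])
  class(ann) <- c("ck_annotation", "data.frame")
  ann
}

#' @rdname read_annotation_table
#' @param annotation annotation data frame.
#' @export
write_annotation_table <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Section layout of the published-style result tables: one file per
# organ-specificity category, letters a-f.
CK_SECTIONS <- c(a = "root_specific", b = "shoot_specific", c = "differential",
                 d = "similar", e = "uncategorized", f = "not_regulated")

#' Write per-category result tables
#'
#' Splits the analyzed genes into the six organ-specificity sections (a:
#' root-specific, b: shoot-specific, c: differential, d: similar, e:
#' uncategorized, f: not regulated) and writes one TSV per section with
#' columns probe id, AbB, per-organ linear ratios, q-values, AGI and
#' description. Genes called `not_expressed` are not written (they are outside
#' the analyzed set). Sections are sorted by the magnitude of the response:
#' section a by the sum of root ratios (descending), b by the sum of shoot
#' ratios, c and d by the sum of all ratios, e and f by probe id; ties break
#' by probe id ascending.
#'
#' @param calls a `ck_calls` data frame from [classify_induction()] or
#'   [classify_deficiency()].
#' @param ratios a `ck_ratios` data frame from [fold_change_ratios()].
#' @param stats an effect-statistics data frame from [fit_models()].
#' @param detection a `ck_detection` report.
#' @param annotation optional `ck_annotation`; AGI/description left blank when
#'   absent.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix, e.g. `"induction"`.
#' @return named character vector of the six file paths.
#' @export
write_results_tables <- function(calls, ratios, stats, detection,
                                 annotation = NULL, out_dir, prefix) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  absent <- setdiff(calls$gene, ratios$gene)
  if (length(absent) > 0)
    stop("gene present in calls but absent from ratios: ", absent[1])
  rownames(ratios) <- ratios$gene
  rownames(detection) <- detection$gene
  rownames(stats) <- stats$gene
  ratio_cols <- grep("^r_(root|shoot)_", names(ratios), value = TRUE)
  root_cols <- grep("^r_root_", ratio_cols, value = TRUE)
  shoot_cols <- grep("^r_shoot_", ratio_cols, value = TRUE)
  q_cols <- grep("^q_", names(stats), value = TRUE)

  keep <- calls[calls$category != "not_expressed", , drop = FALSE]
  paths <- character(0)
  for (sec in names(CK_SECTIONS)) {
    cat_name <- CK_SECTIONS[[sec]]
    g <- keep$gene[keep$category == cat_name]
    tab <- data.frame(probe_id = g, stringsAsFactors = FALSE)
    tab$abb <- detection[g, "abb_total"]
    for (col in ratio_cols) tab[[col]] <- ratios[g, col]
    for (col in q_cols) tab[[col]] <- stats[g, col]
    tab$agi <- if (!is.null(annotation))
      annotation$agi[match(g, annotation$probe_id)]
    else rep(NA_character_, length(g))
    tab$description <- if (!is.null(annotation))
      annotation$description[match(g, annotation$probe_id)]
    else rep(NA_character_, length(g))
    key <- switch(sec,
      a = -rowSums(tab[, root_cols, drop = FALSE], na.rm = TRUE),
      b = -rowSums(tab[, shoot_cols, drop = FALSE], na.rm = TRUE),
      c = ,
      d = -rowSums(tab[, ratio_cols, drop = FALSE], na.rm = TRUE),
      rep(0, nrow(tab))
    )
    tab <- tab[order(key, tab$probe_id), , drop = FALSE]
    p <- file.path(out_dir, sprintf("%s_%s_%s.tsv", prefix, sec, cat_name))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[sec] <- p
  }
  paths
}
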