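#' Run the full analysis pipeline
#'
#' Executes all stages end to end — detection filtering, the three per-gene
#' model fits (induction, deficiency, full), condition means and fold-change
#' ratios, organ-specificity categorization of both analyses,
#' developmental-shift analysis with the overlap partition and plastid
#' fraction, organ-effect normalization, PCA gene selection, PCA of the 10
#' condition profiles, and support-tree clustering — and writes all result
#' tables plus a machine-readable JSON summary to `out_dir`.
#'
#' Input is either a simulated dataset (`sim` a [simulation_config()]) or
#' real tables (`paths` a list with elements `expression`, `design`, and
#' optionally `annotation`). The run is deterministic given the
#' configuration: the simulation draws from `sim$seed` and the support-tree
#' bootstrap from `seed`. On any stage error the files already written are
#' removed and the error is re-signalled with the stage name.
#'
#' @param out_dir output directory (created if needed).
#' @param sim optional `ck_sim_config`.
#' @param paths optional list of input TSV paths (ignored when `sim` given).
#' @param th a `ck_thresholds`.
#' @param seed integer seed for the support-tree bootstrap.
#' @param n_boot bootstrap resamples for the support tree.
#' @return the summary list, invisibly; also written as `summary.json`.
#' @export
run_pipeline <- function(out_dir, sim = NULL, paths = NULL, th = thresholds(),
                         seed = 1L, n_boot = 100) {
  stopifnot(inherits(th, "ck_thresholds"))
  if (is.null(sim) && is.null(paths))
    stop("either a simulation config or input paths must be given")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }
  stage <- function(name, expr) {
    message(sprintf("[%s] ...", name))
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  inputs <- stage("input", {
    if (!is.null(sim)) {
      ds <- simulate_dataset(sim)
      note(write_design_table(ds$expr$design,
                              file.path(out_dir, "design.tsv")))
      note(write_expression_table(ds$expr,
                                  file.path(out_dir, "expression.tsv")))
      note(write_annotation_table(ds$annotation,
                                  file.path(out_dir, "annotation.tsv")))
      utils::write.table(ds$truth, note(file.path(out_dir, "truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ds
    } else {
      design <- read_design_table(paths$design)
      list(expr = read_expression_table(paths$expression, design),
           annotation = if (!is.null(paths$annotation))
             read_annotation_table(paths$annotation) else NULL)
    }
  })
  expr <- inputs$expr

  detection <- stage("detection", {
    d <- detection_report(expr, th)
    note(write_detection_report(d, file.path(out_dir, "detection.tsv")))
    d
  })

  fits <- stage("models", {
    f <- list(induction = fit_models(expr, "induction", detection),
              deficiency = fit_models(expr, "deficiency", detection),
              full = fit_models(expr, "full", detection))
    for (nm in names(f))
      note(write_stats_table(f[[nm]],
                             file.path(out_dir, paste0("stats_", nm, ".tsv"))))
    f
  })

  ratios <- stage("ratios", {
    means <- condition_means(expr)
    r <- fold_change_ratios(means)
    utils::write.table(means, note(file.path(out_dir, "condition_means.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(r, note(file.path(out_dir, "ratios.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(means = means, ratios = r)
  })

  calls <- stage("categorize", {
    ci <- classify_induction(ratios$ratios, fits$induction, detection, th)
    cd <- classify_deficiency(ratios$ratios, fits$deficiency, detection, th)
    for (p in write_results_tables(ci, ratios$ratios, fits$induction,
                                   detection, inputs$annotation,
                                   out_dir, "induction")) note(p)
    for (p in write_results_tables(cd, ratios$ratios, fits$deficiency,
                                   detection, inputs$annotation,
                                   out_dir, "deficiency")) note(p)
    list(induction = ci, deficiency = cd)
  })

  shift <- stage("shift", {
    tab <- shift_input_table(ratios$ratios, fits$full)
    elig <- detection$gene[detection$induction_eligible &
                           detection$deficiency_eligible &
                           !detection$not_expressed]
    tab <- tab[tab$gene %in% elig, , drop = FALSE]
    sr <- find_shift_genes(tab, th, "root_under_BA1080")
    ss <- find_shift_genes(tab, th, "shoot_under_CKX1")
    ov <- shift_overlap(sr, ss)
    utils::write.table(sr, note(file.path(out_dir, "shift_root.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ss, note(file.path(out_dir, "shift_shoot.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    plastid <- if (!is.null(inputs$annotation))
      localization_fraction(ov$root_up_shoot_down, inputs$annotation, "P")
    else list(count = NA_integer_, fraction = NA_real_)
    list(root = sr, shoot = ss, overlap = ov, plastid = plastid)
  })

  ordination <- stage("normalize_pca", {
    sel <- select_pca_genes(detection, fits$full, th)
    norm <- organ_normalize(ratios$means)
    utils::write.table(norm, note(file.path(out_dir, "normalized_means.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    profiles <- condition_profiles(ratios$means, sel)
    pca <- run_pca(profiles)
    utils::write.table(
      data.frame(sample = rownames(pca$scores), pca$scores),
      note(file.path(out_dir, "pca_scores.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(component = seq_along(pca$eig_fractions),
                 eigenvalue = pca$eigenvalues,
                 fraction = pca$eig_fractions),
      note(file.path(out_dir, "pca_eigenvalues.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    tree <- support_tree(profiles, n_boot = n_boot, seed = seed)
    note(write_support_tree(tree, file.path(out_dir, "support_tree.nwk")))
    list(selected = sel, pca = pca, tree = tree)
  })

  summary <- stage("summary", {
    s <- list(
      n_genes = nrow(expr$values),
      n_arrays = ncol(expr$values),
      thresholds = unclass(th)[!vapply(unclass(th), is.null, logical(1))],
      detection = list(
        not_expressed = sum(detection$not_expressed),
        model_eligible = sum(detection$model_eligible),
        induction_eligible = sum(detection$induction_eligible),
        deficiency_eligible = sum(detection$deficiency_eligible)),
      categories = list(
        induction = as.list(table(calls$induction$category)),
        deficiency = as.list(table(calls$deficiency$category))),
      shift = list(
        root_under_BA1080 = nrow(shift$root),
        shoot_under_CKX1 = nrow(shift$shoot),
        overlap_root_up_shoot_down = length(shift$overlap$root_up_shoot_down),
        overlap_root_down_shoot_up = length(shift$overlap$root_down_shoot_up),
        overlap_total = shift$overlap$total,
        plastid_count_root_up = shift$plastid$count,
        plastid_fraction_root_up = shift$plastid$fraction),
      pca = list(
        n_selected_genes = length(ordination$selected),
        eig_fractions = as.numeric(ordination$pca$eig_fractions)))
    jsonlite::write_json(s, note(file.path(out_dir, "summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    s
  })
  invisible(summary)
}
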