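#' Family-stratified function-category profile
#'
#' For every (family, category, sample) triple, the summed normalized
#' activity of the ORFs of that family whose KO belongs to the category —
#' the data behind family-resolved peptidase / amino-acid metabolism /
#' amino-acid transporter profiles. The full table is always produced;
#' `plot_families` additionally lists the families passing the 0.5%
#' plotting threshold for display use.
#'
#' @param norm Normalized ORF x sample `expr_matrix`.
#' @param ko_map Named character vector orf_id -> KO.
#' @param family_map Named character vector orf_id -> family.
#' @param categories A `function_categories` list.
#' @param design Optional `study_design`; when given, the 0.5% family
#'   filter is evaluated on diet-group means and attached as attribute
#'   `"plot_families"`.
#' @param threshold Plotting threshold on family activity (default 0.005).
#' @return data.frame of class `family_function_profile` with columns
#'   `family`, `category`, `sample`, `activity`. Families or categories
#'   with no annotated ORFs appear as explicit zero rows.
#' @export
build_family_function_profile <- function(norm, ko_map, family_map,
                                          categories, design = NULL,
                                          threshold = 0.005) {
  df <- category_activity(norm, ko_map, categories, family_map = family_map)
  df <- df[, c("family", "category", "sample", "activity")]
  class(df) <- c("family_function_profile", "data.frame")
  if (!is.null(design)) {
    fam_act <- family_activity(norm, family_map)
    attr(df, "plot_families") <-
      filter_families_for_plot(fam_act, design, threshold)
  }
  df
}

#' Family-resolved SCFA production-pathway profile
#'
#' Sums normalized activity over each SCFA pathway's KO set per family and
#' sample, then reports the mean and standard deviation across the samples
#' of each diet group — the numbers behind per-family acetate / propionate
#' / butyrate production bars with SD error bars. The default KO sets keep
#' K01895 in both the acetate and propionate pathways (see
#' [scfa_pathway_config()]).
#'
#' @inheritParams build_family_function_profile
#' @param design A `study_design` covering the samples.
#' @param scfa_config `function_categories` for the three pathways
#'   (default [scfa_pathway_config()]).
#' @return data.frame of class `scfa_pathway_profile`: `family`, `pathway`,
#'   `diet`, `mean_activity`, `sd_activity`.
#' @export
build_scfa_pathway_profile <- function(norm, ko_map, family_map, design,
                                       scfa_config = scfa_pathway_config()) {
  long <- category_activity(norm, ko_map, scfa_config,
                            family_map = family_map)
  diets <- setNames(design$diet, design$sample_id)
  long$diet <- diets[long$sample]
  rows <- list()
  for (f in unique(long$family)) for (pw in names(scfa_config)) {
    sub <- long[long$family == f & long$category == pw, , drop = FALSE]
    agg_m <- tapply(sub$activity, sub$diet, mean)
    agg_s <- tapply(sub$activity, sub$diet, sd)
    rows[[length(rows) + 1L]] <- data.frame(
      family = f, pathway = pw, diet = names(agg_m),
      mean_activity = unname(agg_m), sd_activity = unname(agg_s),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scfa_pathway_profile", "data.frame")
  out
}

#' Family-stratified activity of a single KO
#'
#' The family x sample activity table for one KO of interest (e.g. the
#' glycolysis marker 6-phosphofructokinase), for comparing one enzyme's
#' expression across diets and contributing families. An unknown or
#' undetected KO yields an empty table with a warning.
#'
#' @inheritParams build_family_function_profile
#' @param ko A single KO identifier.
#' @return Family x sample matrix of summed activity (0-row when the KO is
#'   absent).
#' @export
single_ko_report <- function(norm, ko_map, family_map, ko) {
  orfs <- names(ko_map)[ko_map == ko]
  orfs <- intersect(orfs, rownames(norm))
  if (!length(orfs)) {
    warnf("KO %s is not carried by any ORF in the matrix", ko)
    return(matrix(numeric(0), nrow = 0, ncol = ncol(norm),
                  dimnames = list(NULL, colnames(norm))))
  }
  fams <- family_map[orfs]
  fams[is.na(fams)] <- "unclassified"
  rowsum(unclass(norm)[orfs, , drop = FALSE], group = unname(fams),
         reorder = TRUE)
}

#' iPath-style line widths from KO read counts
#'
#' Computes a metabolic-map line width per KO as `log10(1 + c)` where `c`
#' is the KO's raw aligned-nucleotide count summed over the samples of one
#' diet group (per-group aggregation is the default; pass a single sample
#' id for per-sample widths). Zero-count KOs are omitted.
#'
#' @param ko_counts Raw KO x sample count matrix (see [aggregate_by()] on a
#'   raw matrix re-counted at KO level, or aggregate raw ORF counts).
#' @param samples Sample ids of the group to aggregate.
#' @return data.frame `ko`, `count`, `width`, sorted by KO.
#' @export
ipath_width_export <- function(ko_counts, samples = colnames(ko_counts)) {
  missing <- setdiff(samples, colnames(ko_counts))
  if (length(missing))
    stopf("unknown sample(s): %s", paste(missing, collapse = ", "))
  counts <- rowSums(unclass(ko_counts)[, samples, drop = FALSE])
  counts <- counts[counts > 0]
  out <- data.frame(ko = names(counts), count = unname(counts),
                    width = log10(1 + unname(counts)),
                    stringsAsFactors = FALSE)
  out[order(out$ko), , drop = FALSE]
}

#' @rdname ipath_width_export
#' @param widths Result of `ipath_width_export()`.
#' @param path Output selection file: one `"Kxxxxx Wwidth"` row per KO.
#' @export
write_ipath_selection <- function(widths, path) {
  writeLines(sprintf("%s W%g", widths$ko, widths$width), path)
  invisible(path)
}
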