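pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "mtxprof_out",
    alpha = 0.05,
    n_permutations = 999L,
    alignment_format = "tsv",
    category_config = NULL,
    module_catalog = NULL,
    synthetic = list(
      orfs_per_family = 320L,
      n_background = 116L,
      depth = 1e6,
      dispersion = 0.2,
      fold_change = 4,
      read_length = 100L,
      scfa_mice_per_group = 10L,
      replicates = list(NPLF = 3L, NPHF = 4L, HPLF = 4L, HPHF = 4L)))
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML configuration, fills in defaults, and fails hard with a
#' single message listing every violation at once. A configuration either
#' carries a `synthetic:` block (the bundled community generator supplies
#' all inputs) or an `inputs:` block pointing at user files.
#'
#' @param path YAML configuration file.
#' @return list of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path) %||% list()
  def <- pipeline_defaults()
  cfg <- modifyList(def[setdiff(names(def), "synthetic")], raw)
  problems <- character(0)
  if (!is.null(raw$synthetic) && !is.null(raw$inputs))
    problems <- c(problems, "give either `synthetic` or `inputs`, not both")
  if (is.null(raw$synthetic) && is.null(raw$inputs))
    cfg$synthetic <- def$synthetic
  if (!is.null(raw$synthetic) || is.null(raw$inputs))
    cfg$synthetic <- modifyList(def$synthetic, raw$synthetic %||% list())
  # YAML 1.1 only recognizes exponents written with a sign (2.0e+5); be
  # lenient and coerce numeric-looking scalars
  coerce_num <- function(x) {
    if (is.character(x) && length(x) == 1 &&
        grepl("^[0-9.eE+-]+$", x) && !is.na(suppressWarnings(as.numeric(x))))
      as.numeric(x) else x
  }
  for (key in c("alpha", "seed", "n_permutations"))
    cfg[[key]] <- coerce_num(cfg[[key]])
  if (!is.null(cfg$synthetic))
    for (key in c("depth", "dispersion", "fold_change", "orfs_per_family",
                  "n_background", "read_length", "scfa_mice_per_group"))
      cfg$synthetic[[key]] <- coerce_num(cfg$synthetic[[key]])
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    problems <- c(problems, sprintf("`alpha` must lie in (0, 1), got %s",
                                    format(cfg$alpha)))
  if (!is_count(cfg$seed))
    problems <- c(problems, "`seed` must be a non-negative integer")
  if (!is_count(cfg$n_permutations) || cfg$n_permutations < 99)
    problems <- c(problems, "`n_permutations` must be an integer >= 99")
  if (!cfg$alignment_format %in% c("tsv", "sam"))
    problems <- c(problems, "`alignment_format` must be 'tsv' or 'sam'")
  for (key in c("category_config", "module_catalog")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      problems <- c(problems, sprintf("`%s` file not found: %s", key, cfg[[key]]))
  }
  if (!is.null(cfg$inputs)) {
    req <- c("orfs", "alignments", "metadata")
    for (key in req)
      if (is.null(cfg$inputs[[key]]))
        problems <- c(problems, sprintf("`inputs$%s` is required", key))
    for (key in intersect(names(cfg$inputs),
                          c("contigs", "orfs", "hits", "ko_map",
                            "alignments", "metadata", "scfa")))
      if (!is.null(cfg$inputs[[key]]) && !file.exists(cfg$inputs[[key]]))
        problems <- c(problems, sprintf("`inputs$%s` not found: %s",
                                        key, cfg$inputs[[key]]))
    if (!is.null(cfg$inputs$metadata) && file.exists(cfg$inputs$metadata)) {
      md <- read.delim(cfg$inputs$metadata, stringsAsFactors = FALSE)
      dup <- md$sample_id[duplicated(md$sample_id)]
      if (length(dup))
        problems <- c(problems, sprintf("duplicate sample id(s) in metadata: %s",
                                        paste(unique(dup), collapse = ", ")))
    }
  } else {
    syn <- cfg$synthetic
    reps <- unlist(syn$replicates)
    if (!setequal(names(reps), diet_levels()))
      problems <- c(problems,
                    "`synthetic$replicates` must name all four diet groups")
    if (anyDuplicated(names(reps)))
      problems <- c(problems, "duplicate diet groups in `synthetic$replicates`")
    if (!is.numeric(syn$depth) || syn$depth <= 0)
      problems <- c(problems, "`synthetic$depth` must be positive")
    if (!is.numeric(syn$dispersion) || syn$dispersion < 0)
      problems <- c(problems, "`synthetic$dispersion` must be >= 0")
  }
  if (length(problems))
    stopf("invalid pipeline configuration:\n  - %s",
          paste(problems, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  cfg$config_path <- normalizePath(path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

pipeline_stages <- function() {
  c("simulate", "quantify", "annotate", "diff", "strata", "ordinate")
}

read_metadata_tsv <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  md$protein_level <- protein_level_of(md$diet)
  md$fat_level <- fat_level_of(md$diet)
  class(md) <- c("study_design", "data.frame")
  md
}

write_metadata_tsv <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

stage_simulate <- function(cfg, dirs) {
  syn <- cfg$synthetic
  modules <- module_catalog(cfg$module_catalog)
  categories <- function_categories(cfg$category_config)
  truth <- community_truth(
    planted_effects = default_planted_effects(fold = syn$fold_change),
    modules = modules, seed = cfg$seed)
  full <- study_design(replicates = syn$scfa_mice_per_group,
                       seed = cfg$seed + 11L)
  design <- subset_design(full, unlist(syn$replicates))
  gen <- generate_catalog(truth$families, syn$orfs_per_family,
                          default_ko_pool(modules, categories,
                                          n_background = syn$n_background),
                          modules = modules, seed = cfg$seed + 23L)
  expr <- simulate_expression(truth, design, gen$catalog,
                              depth = syn$depth,
                              dispersion = syn$dispersion,
                              seed = cfg$seed + 37L)
  reads <- simulate_alignment_records(expr, gen$catalog,
                                      read_length = syn$read_length,
                                      seed = cfg$seed + 53L)
  panel <- simulate_scfa_panel(truth, full, seed = cfg$seed + 71L)
  inp <- dirs$inputs
  write_contigs_fasta(gen$contigs, file.path(inp, "contigs.fasta"))
  write_orf_gff3(gen$catalog, file.path(inp, "orfs.gff3"),
                 contig_lengths = gen$contig_lengths)
  write.table(gen$hits, file.path(inp, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(orf_id = names(gen$ko_map), ko = unname(gen$ko_map)),
              file.path(inp, "ko_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (cfg$alignment_format == "sam") {
    write_alignments_sam(reads, gen$contig_lengths,
                         file.path(inp, "alignments"))
  } else {
    write_alignments_tsv(reads, file.path(inp, "alignments.tsv"))
  }
  write_metadata_tsv(design, file.path(inp, "metadata.tsv"))
  write_metadata_tsv(full, file.path(inp, "metadata_full_study.tsv"))
  write.table(panel, file.path(inp, "scfa_panel.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_module_catalog(modules, file.path(inp, "modules.tsv"))
  write_truth(truth, file.path(inp, "truth.yaml"))
  mtx_log(sprintf("simulate: %d ORFs, %d samples, %d reads",
                  nrow(gen$catalog), nrow(design), nrow(reads)))
  invisible(NULL)
}

# Resolve the input files of the downstream stages (synthetic runs read
# back the checkpointed simulate outputs, keeping every stage auditable
# from plain files).
pipeline_inputs <- function(cfg, dirs) {
  if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    inp$alignment_format <- inp$alignment_format %||% cfg$alignment_format
    return(inp)
  }
  base <- dirs$inputs
  list(orfs = file.path(base, "orfs.gff3"),
       hits = file.path(base, "hits.tsv"),
       ko_map = file.path(base, "ko_map.tsv"),
       alignments = if (cfg$alignment_format == "sam")
         file.path(base, "alignments") else file.path(base, "alignments.tsv"),
       alignment_format = cfg$alignment_format,
       metadata = file.path(base, "metadata.tsv"),
       scfa = file.path(base, "scfa_panel.tsv"),
       scfa_design = file.path(base, "metadata_full_study.tsv"))
}

stage_quantify <- function(cfg, dirs) {
  inp <- pipeline_inputs(cfg, dirs)
  catalog <- read_orf_gff3(inp$orfs)
  design <- read_metadata_tsv(inp$metadata)
  reads <- if (identical(inp$alignment_format, "sam")) {
    files <- sort(list.files(inp$alignments, pattern = "\\.sam$",
                             full.names = TRUE))
    read_alignments_sam(files)
  } else {
    read_alignments_tsv(inp$alignments)
  }
  raw <- count_aligned_nucleotides(reads, catalog,
                                   samples = design$sample_id)
  norm <- normalize_per_sample(raw)
  write_expression_tsv(raw, file.path(dirs$out, "orf_counts_raw.tsv"))
  write_expression_tsv(norm, file.path(dirs$out, "orf_activity_normalized.tsv"))
  mtx_log(sprintf("quantify: %d reads counted over %d ORFs x %d samples",
                  length(unique(reads$read_id)), nrow(raw), ncol(raw)))
  invisible(NULL)
}

stage_annotate <- function(cfg, dirs) {
  inp <- pipeline_inputs(cfg, dirs)
  catalog <- read_orf_gff3(inp$orfs)
  design <- read_metadata_tsv(inp$metadata)
  norm <- read_expression_tsv(file.path(dirs$out, "orf_activity_normalized.tsv"),
                              "normalized")
  raw <- read_expression_tsv(file.path(dirs$out, "orf_counts_raw.tsv"), "raw")
  fam_map <- if (!is.null(inp$hits)) {
    hits <- read.delim(inp$hits, stringsAsFactors = FALSE)
    assign_family_best_hit(hits, orf_ids = catalog$orf_id)
  } else setNames(catalog$family, catalog$orf_id)
  komap_df <- read.delim(inp$ko_map, stringsAsFactors = FALSE)
  ko_map <- setNames(komap_df$ko, komap_df$orf_id)
  categories <- function_categories(cfg$category_config)
  fam_act <- family_activity(norm, fam_map)
  ko_act <- aggregate_by(norm, ko_map)
  ko_counts <- aggregate_counts(raw, ko_map)
  cat_act <- category_activity(norm, ko_map, categories)
  write.table(data.frame(orf_id = names(fam_map), family = unname(fam_map)),
              file.path(dirs$out, "family_assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_expression_tsv(fam_act, file.path(dirs$out, "family_activity.tsv"))
  write_expression_tsv(ko_act, file.path(dirs$out, "ko_activity.tsv"))
  write_expression_tsv(ko_counts, file.path(dirs$out, "ko_counts_raw.tsv"))
  write.table(data.frame(category = rownames(cat_act), cat_act,
                         check.names = FALSE),
              file.path(dirs$out, "category_activity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  plot_fams <- filter_families_for_plot(fam_act, design)
  writeLines(plot_fams, file.path(dirs$out, "families_above_threshold.txt"))
  mtx_log(sprintf("annotate: %d families detected, %d KOs in universe",
                  nrow(fam_act), sum(rownames(ko_act) != "unassigned")))
  invisible(NULL)
}

stage_diff <- function(cfg, dirs) {
  inp <- pipeline_inputs(cfg, dirs)
  design <- read_metadata_tsv(inp$metadata)
  modules <- module_catalog(cfg$module_catalog %||%
    (if (is.null(cfg$inputs)) file.path(dirs$inputs, "modules.tsv")))
  ko_act <- read_expression_tsv(file.path(dirs$out, "ko_activity.tsv"),
                                "normalized")
  ko_mat <- unclass(ko_act)
  ko_mat <- ko_mat[rownames(ko_mat) != "unassigned", , drop = FALSE]
  enr <- module_enrichment_analysis(
    structure(ko_mat, mode = "normalized",
              class = c("expr_matrix", "matrix", "array")),
    design, modules, alpha = cfg$alpha)
  write.table(enr$ko, file.path(dirs$out, "ko_differential.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(enr$modules, file.path(dirs$out, "module_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  categories <- function_categories(cfg$category_config)
  cat_df <- read.delim(file.path(dirs$out, "category_activity.tsv"),
                       check.names = FALSE, stringsAsFactors = FALSE)
  cat_mat <- as.matrix(cat_df[, -1, drop = FALSE])
  rownames(cat_mat) <- cat_df$category
  groups <- setNames(design$protein_level, design$sample_id)[colnames(cat_mat)]
  wtests <- data.frame(
    category = rownames(cat_mat),
    p_value = vapply(rownames(cat_mat), function(cc)
      wilcoxon_category_test(cat_mat[cc, ], groups), numeric(1)),
    stringsAsFactors = FALSE)
  wtests$significant <- wtests$p_value < cfg$alpha
  write.table(wtests, file.path(dirs$out, "category_wilcoxon.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(inp$scfa) && file.exists(inp$scfa)) {
    panel <- read.delim(inp$scfa, stringsAsFactors = FALSE)
    stats <- scfa_group_test(panel, alpha = cfg$alpha)
    write.table(stats, file.path(dirs$out, "scfa_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    mtx_log("diff: no SCFA panel configured; SCFA statistics skipped")
  }
  mtx_log(sprintf("diff: %d KOs tested, %d modules reported",
                  nrow(enr$ko), nrow(enr$modules %||% data.frame())))
  invisible(NULL)
}

stage_strata <- function(cfg, dirs) {
  inp <- pipeline_inputs(cfg, dirs)
  design <- read_metadata_tsv(inp$metadata)
  norm <- read_expression_tsv(file.path(dirs$out, "orf_activity_normalized.tsv"),
                              "normalized")
  fam_df <- read.delim(file.path(dirs$out, "family_assignments.tsv"),
                       stringsAsFactors = FALSE)
  fam_map <- setNames(fam_df$family, fam_df$orf_id)
  komap_df <- read.delim(inp$ko_map, stringsAsFactors = FALSE)
  ko_map <- setNames(komap_df$ko, komap_df$orf_id)
  categories <- function_categories(cfg$category_config)
  profile <- build_family_function_profile(norm, ko_map, fam_map,
                                           categories, design = design)
  write.table(profile, file.path(dirs$out, "family_function_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  scfa_prof <- build_scfa_pathway_profile(norm, ko_map, fam_map, design)
  write.table(scfa_prof, file.path(dirs$out, "scfa_pathway_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ko_counts <- read_expression_tsv(file.path(dirs$out, "ko_counts_raw.tsv"),
                                   "raw")
  for (d in intersect(diet_levels(), unique(design$diet))) {
    ids <- design$sample_id[design$diet == d]
    widths <- ipath_width_export(ko_counts, samples = ids)
    widths <- widths[widths$ko != "unassigned", , drop = FALSE]
    write_ipath_selection(widths,
                          file.path(dirs$out, sprintf("ipath_%s.txt", d)))
  }
  mtx_log("strata: stratified profiles and iPath selections written")
  invisible(NULL)
}

stage_ordinate <- function(cfg, dirs) {
  inp <- pipeline_inputs(cfg, dirs)
  design <- read_metadata_tsv(inp$metadata)
  ko_act <- read_expression_tsv(file.path(dirs$out, "ko_activity.tsv"),
                                "normalized")
  m <- unclass(ko_act)
  m <- m[rownames(m) != "unassigned", , drop = FALSE]
  lg <- log10_transform(m)
  hc <- pearson_ward_cluster(lg)
  write_linkage_newick(hc, file.path(dirs$out, "clustering.nwk"))
  write.table(linkage_table(hc), file.path(dirs$out, "clustering_merges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  expl <- data.frame(diet = design$diet, weight = design$mouse_weight)
  if (!is.null(inp$scfa) && file.exists(inp$scfa)) {
    panel <- read.delim(inp$scfa, stringsAsFactors = FALSE)
    wide <- tapply(panel$concentration, list(panel$mouse_id, panel$acid), mean)
    present <- intersect(design$sample_id, rownames(wide))
    if (length(present) == nrow(design)) {
      expl <- cbind(expl, as.data.frame(wide[design$sample_id, , drop = FALSE]))
    } else {
      mtx_log("ordinate: SCFA panel does not cover all samples; RDA uses diet and weight only")
    }
  }
  res <- rda_fit(lg, expl)
  perm <- rda_permutation_test(lg, expl,
                               n_permutations = cfg$n_permutations,
                               seed = cfg$seed + 97L)
  write_rda_tsv(res, dirs$out)
  retained <- species_axis_filter(res)
  writeLines(retained, file.path(dirs$out, "rda_features_axis_filtered.txt"))
  write.table(data.frame(statistic = "constrained_fraction",
                         observed = perm$observed,
                         p_value = perm$p_value,
                         n_permutations = cfg$n_permutations),
              file.path(dirs$out, "rda_permutation_test.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mtx_log(sprintf("ordinate: constrained fraction %.3f (permutation p = %.4f)",
                  res$constrained_fraction, perm$p_value))
  invisible(NULL)
}

#' Run the full metatranscriptome analysis pipeline
#'
#' Executes the stages `simulate` (synthetic configurations only) ->
#' `quantify` -> `annotate` -> `diff` -> `strata` -> `ordinate`, each
#' reading its inputs from and writing its outputs to plain-text
#' checkpoints under the configured output directory, so any stage can be
#' re-run from the previous checkpoints with `from_stage`.
#'
#' @param config A `pipeline_config` from [validate_config()], or a path
#'   to a YAML configuration.
#' @param from_stage Stage name to start from (earlier checkpoints must
#'   exist); default runs everything.
#' @param to_stage Last stage to run (defaults to the final stage; set
#'   `from_stage == to_stage` to re-run a single stage).
#' @return Invisibly, a list describing the report bundle: `output_dir`,
#'   `files` (relative paths of all outputs) and `manifest`.
#' @export
run_pipeline <- function(config, from_stage = NULL, to_stage = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dirs <- list(out = cfg$output_dir,
               inputs = file.path(cfg$output_dir, "inputs"))
  dir.create(dirs$inputs, recursive = TRUE, showWarnings = FALSE)
  stages <- pipeline_stages()
  if (is.null(cfg$synthetic) || !is.null(cfg$inputs))
    stages <- setdiff(stages, "simulate")
  for (bound in c(from_stage, to_stage))
    if (!is.null(bound) && !bound %in% stages)
      stopf("unknown stage '%s' (expected one of: %s)", bound,
            paste(stages, collapse = ", "))
  lo <- if (is.null(from_stage)) 1L else match(from_stage, stages)
  hi <- if (is.null(to_stage)) length(stages) else match(to_stage, stages)
  if (lo > hi) stopf("from_stage comes after to_stage")
  stages <- stages[lo:hi]
  runners <- list(simulate = stage_simulate, quantify = stage_quantify,
                  annotate = stage_annotate, diff = stage_diff,
                  strata = stage_strata, ordinate = stage_ordinate)
  for (st in stages) {
    mtx_log("stage: ", st)
    tryCatch(runners[[st]](cfg, dirs),
             error = function(e) stopf("stage '%s' failed: %s", st,
                                       conditionMessage(e)))
  }
  manifest <- list(
    package = "mtxprof",
    version = as.character(utils::packageVersion("mtxprof")),
    seed = cfg$seed,
    alpha = cfg$alpha,
    n_permutations = cfg$n_permutations,
    config_md5 = unname(tools::md5sum(cfg$config_path)),
    stages = stages)
  yaml::write_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  files <- sort(list.files(cfg$output_dir, recursive = TRUE))
  invisible(list(output_dir = cfg$output_dir, files = files,
                 manifest = manifest))
}
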