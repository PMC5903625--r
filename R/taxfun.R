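#' Assign family-level taxonomy by the best protein hit
#'
#' Each ORF receives the taxonomic family of its highest-similarity protein
#' hit. Hits are ordered by descending bit score, then ascending e-value,
#' then lexicographic subject id, which makes the assignment a total order
#' and therefore invariant to the input row order. ORFs listed in `orf_ids`
#' but with no hit are assigned `"unclassified"`.
#'
#' @param hits data.frame with columns `orf_id`, `subject_id`, `bit_score`,
#'   `e_value`, `subject_family`.
#' @param orf_ids Optional full ORF universe; defaults to the ORFs present
#'   in `hits`.
#' @param max_evalue Optional e-value ceiling; hits above it are discarded
#'   before the best-hit rule (default `Inf`: no cutoff).
#' @return Named character vector orf_id -> family.
#' @export
assign_family_best_hit <- function(hits, orf_ids = NULL, max_evalue = Inf) {
  orf_ids <- orf_ids %||% unique(hits$orf_id)
  if (any(hits$e_value < 0)) stopf("e-values must be non-negative")
  hits <- hits[hits$e_value <= max_evalue, , drop = FALSE]
  fam <- setNames(rep("unclassified", length(orf_ids)), orf_ids)
  if (nrow(hits)) {
    ord <- order(hits$orf_id, -hits$bit_score, hits$e_value, hits$subject_id,
                 method = "radix")
    hits <- hits[ord, , drop = FALSE]
    best <- hits[!duplicated(hits$orf_id), , drop = FALSE]
    keep <- best$orf_id %in% orf_ids
    fam[best$orf_id[keep]] <- best$subject_family[keep]
  }
  fam
}

#' Family-level relative activity
#'
#' Sums normalized ORF activity per assigned family; columns keep summing
#' to 1, with unassigned ORFs preserved under `"unclassified"`.
#'
#' @param norm Normalized ORF x sample `expr_matrix`.
#' @param family_map Named character vector orf_id -> family.
#' @return Family x sample `expr_matrix`.
#' @export
family_activity <- function(norm, family_map) {
  fm <- family_map
  fm[is.na(fm)] <- "unclassified"
  aggregate_by(norm, fm)
}

#' Retain families above the plotting abundance threshold
#'
#' A family is retained when its mean relative activity within at least one
#' diet condition exceeds the threshold (default 0.5%). "Condition" means
#' the diet-group mean, not an individual sample.
#'
#' @param family_matrix Family x sample activity matrix.
#' @param design A `study_design` covering the matrix's sample columns.
#' @param threshold Fraction in `[0, 1)`; default `0.005`.
#' @return Character vector of retained family names.
#' @export
filter_families_for_plot <- function(family_matrix, design,
                                     threshold = 0.005) {
  if (threshold < 0 || threshold >= 1)
    stopf("threshold must lie in [0, 1)")
  diets <- setNames(design$diet, design$sample_id)[colnames(family_matrix)]
  keep <- vapply(rownames(family_matrix), function(f) {
    means <- tapply(family_matrix[f, ], diets, mean)
    any(means > threshold)
  }, logical(1))
  rownames(family_matrix)[keep]
}

#' Function-category configuration
#'
#' Maps category names to KO sets. The shipped defaults cover peptidases,
#' amino-acid metabolism, amino-acid transporters, glycolysis marker
#' 6-phosphofructokinase, and the three SCFA production pathways with their
#' literature KO sets: acetate production via acetate kinase, acetyl-CoA
#' synthase and phosphate acetyltransferase (K00925, K00625, K01895,
#' K13788); propionate production via propionate CoA-transferase and
#' acetyl-CoA synthase (K01895, K01026); butyrate production via butyrate
#' kinase, acetoacetate CoA-transferase and phosphate butyryltransferase
#' (K01034, K01035, K01896, K00929, K00634). Note that K01895 is a member
#' of both the acetate and the propionate set; the overlap is deliberate
#' and preserved (see `split_k01895`).
#'
#' The SCFA pathway sets are real KEGG orthology ids. The shipped
#' peptidase / amino-acid metabolism / amino-acid transporter /
#' phosphofructokinase sets are synthetic placeholder ids (K76xxx plus
#' K00850) matched to the bundled community generator; for real data,
#' point `path` at a configuration seeded from KEGG BRITE groupings.
#'
#' @param path Optional TSV config (columns `category`, `kos` with a
#'   comma-separated KO list); defaults to the packaged configuration.
#' @param split_k01895 If `TRUE`, assign K01895 to the acetate pathway only,
#'   removing the acetate/propionate double-counting (default `FALSE`,
#'   keeping the published sets).
#' @return Named list of KO character vectors, class `function_categories`.
#' @export
function_categories <- function(path = NULL, split_k01895 = FALSE) {
  path <- path %||% system.file("extdata", "function_categories.tsv",
                                package = "mtxprof", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  cats <- lapply(strsplit(df$kos, ","), trimws)
  names(cats) <- df$category
  if (any(!lengths(cats)))
    stopf("category KO sets must be non-empty: %s",
          paste(names(cats)[!lengths(cats)], collapse = ", "))
  if (split_k01895 && "propionate" %in% names(cats))
    cats$propionate <- setdiff(cats$propionate, "K01895")
  structure(cats, class = "function_categories")
}

#' The three SCFA production pathway KO sets
#'
#' @inheritParams function_categories
#' @return `function_categories` restricted to acetate/propionate/butyrate.
#' @export
scfa_pathway_config <- function(split_k01895 = FALSE) {
  cats <- function_categories(split_k01895 = split_k01895)
  structure(cats[c("acetate", "propionate", "butyrate")],
            class = "function_categories")
}

#' Function-category relative activity
#'
#' Per category, sums the activity of all ORFs whose KO belongs to the
#' category's KO set; optionally stratified by taxonomic family. Because
#' categories may share KOs (K01895 sits in both the acetate and propionate
#' pathway), category rows are not a partition and may double-count.
#'
#' @param norm Normalized ORF x sample `expr_matrix`.
#' @param ko_map Named character vector orf_id -> KO.
#' @param categories A `function_categories` object (or named list of KO
#'   vectors).
#' @param family_map Optional orf_id -> family map; when given, the result
#'   is a long data.frame stratified by family.
#' @return Category x sample matrix, or a data.frame with columns
#'   `category`, `family`, `sample`, `activity` when `family_map` is given.
#'   Categories with no detected KOs yield zero rows (with a log warning).
#' @export
category_activity <- function(norm, ko_map, categories, family_map = NULL) {
  kos <- ko_map[rownames(norm)]
  undetected <- names(categories)[
    !vapply(categories, function(set) any(kos %in% set), logical(1))]
  if (length(undetected))
    mtx_log("category with no detected KOs (zero activity): ",
            paste(undetected, collapse = ", "))
  if (is.null(family_map)) {
    m <- t(vapply(categories, function(set) {
      colSums(unclass(norm)[which(kos %in% set), , drop = FALSE])
    }, numeric(ncol(norm))))
    dimnames(m) <- list(names(categories), colnames(norm))
    return(m)
  }
  fams <- unname(family_map[rownames(norm)])
  fams[is.na(fams)] <- "unclassified"
  fam_levels <- sort(unique(fams))
  out <- list()
  for (cat in names(categories)) {
    member <- kos %in% categories[[cat]]
    for (f in fam_levels) {
      rows <- which(member & fams == f)
      act <- colSums(unclass(norm)[rows, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        category = cat, family = f, sample = colnames(norm),
        activity = unname(act), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
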