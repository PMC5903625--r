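#' Read / construct a KEGG module catalog
#'
#' A module catalog maps KEGG module ids to their member KO sets. The
#' packaged default mirrors the six diet-responsive modules of the study
#' design (three sugar-metabolism modules favoured under normal-protein
#' diets, three protein-metabolism modules favoured under high-protein
#' diets) with synthetic placeholder member KOs, sized like their KEGG
#' counterparts.
#'
#' @param path TSV with columns `module_id`, `description`, `kos`
#'   (comma-separated). Defaults to the packaged synthetic catalog.
#' @return data.frame of class `module_catalog` with a list-column `kos`.
#' @export
module_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "kegg_modules_synthetic.tsv",
                                package = "mtxprof", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$kos <- lapply(strsplit(df$kos, ","), trimws)
  class(df) <- c("module_catalog", "data.frame")
  df
}

#' @rdname module_catalog
#' @param modules A `module_catalog`.
#' @export
write_module_catalog <- function(modules, path) {
  df <- data.frame(module_id = modules$module_id,
                   description = modules$description,
                   kos = vapply(modules$kos, paste, "", collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

module_kos <- function(modules) {
  setNames(modules$kos, modules$module_id)
}

#' Per-KO two-sample t-tests between diet factor levels
#'
#' Welch (unequal-variance) two-sided t-tests on normalized KO activity,
#' comparing the two levels of a design factor (by default the protein
#' level, NP vs HP). A KO with zero variance and equal means in both groups
#' is reported with `t = 0`, `p = 1` and `degenerate = TRUE`.
#'
#' @param ko_matrix KO x sample matrix of normalized activities.
#' @param design A `study_design` covering the sample columns.
#' @param factor Design column to contrast: `"protein_level"` (default,
#'   levels NP/HP) or `"fat_level"` (LF/HF).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching the raw P < 0.05 convention; use `"BH"`
#'   for Benjamini-Hochberg).
#' @return data.frame with one row per KO: means per level, `t_statistic`,
#'   `p_value`, `p_adjusted`, `direction`, `degenerate`; sorted by p-value.
#' @export
ko_ttest <- function(ko_matrix, design, factor = c("protein_level", "fat_level"),
                     adjust = "none") {
  factor <- match.arg(factor)
  levels <- if (factor == "protein_level") c("NP", "HP") else c("LF", "HF")
  fac <- setNames(design[[factor]], design$sample_id)[colnames(ko_matrix)]
  ia <- which(fac == levels[1]); ib <- which(fac == levels[2])
  if (length(ia) < 2 || length(ib) < 2)
    stopf("need >= 2 samples per %s level", factor)
  m <- unclass(ko_matrix)
  nk <- nrow(m)
  mean_a <- rowMeans(m[, ia, drop = FALSE])
  mean_b <- rowMeans(m[, ib, drop = FALSE])
  t_stat <- numeric(nk); p_val <- numeric(nk); degen <- logical(nk)
  for (i in seq_len(nk)) {
    a <- m[i, ia]; b <- m[i, ib]
    if (var(a) == 0 && var(b) == 0) {
      degen[i] <- TRUE
      if (mean_a[i] == mean_b[i]) {
        t_stat[i] <- 0; p_val[i] <- 1
      } else {
        # separated constants: no variance but unequal means
        t_stat[i] <- sign(mean_a[i] - mean_b[i]) * Inf; p_val[i] <- 0
      }
    } else {
      ht <- t.test(a, b, var.equal = FALSE)
      t_stat[i] <- unname(ht$statistic); p_val[i] <- ht$p.value
    }
  }
  out <- data.frame(ko_id = rownames(m), mean_a = mean_a, mean_b = mean_b,
                    t_statistic = t_stat, p_value = p_val,
                    direction = ifelse(mean_a >= mean_b,
                                       paste0(levels[1], "-higher"),
                                       paste0(levels[2], "-higher")),
                    degenerate = degen, stringsAsFactors = FALSE)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", levels[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", levels[2])
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric KEGG-module enrichment
#'
#' Formalizes the module "likelihood" computation: KOs individually
#' significant for one direction (t-test, P below `alpha`) are taken
#' together and, per module, the probability of observing at least `k`
#' significant members among the module's `n` detected KOs is computed as
#' the upper tail of the hypergeometric distribution over the detected-KO
#' universe. Undetected KOs cannot be "found" and are excluded from both
#' the module size and the universe. Modules with no detected KO are
#' skipped with a log notice.
#'
#' @param significant_kos Character vector of significant KO ids (must be a
#'   subset of `detected_kos`).
#' @param detected_kos Character vector: the universe of KOs with nonzero
#'   activity in at least one sample.
#' @param modules A `module_catalog`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param direction Label copied into the output (e.g. `"NP"` or `"HP"`).
#' @param method `"hypergeometric"` (default) or `"binomial"`, the
#'   binomial approximation with success probability
#'   `|significant| / |detected|`.
#' @return data.frame: `module_id`, `description`, `n_module_kos` (full
#'   module size), `n_detected`, `k_significant`, `p_enrichment`,
#'   `direction`, `significant`; sorted by p. All tested modules are
#'   reported, with the flag marking `p < alpha`.
#' @export
module_enrichment <- function(significant_kos, detected_kos, modules,
                              alpha = 0.05, direction = NA_character_,
                              method = c("hypergeometric", "binomial")) {
  method <- match.arg(method)
  significant_kos <- unique(significant_kos)
  detected_kos <- unique(detected_kos)
  if (!all(significant_kos %in% detected_kos))
    stopf("significant KOs must be a subset of detected KOs")
  N <- length(detected_kos)
  S <- length(significant_kos)
  rows <- lapply(seq_len(nrow(modules)), function(i) {
    kos <- modules$kos[[i]]
    det <- intersect(kos, detected_kos)
    n <- length(det)
    if (n == 0) {
      mtx_log("module ", modules$module_id[i],
              " has no detected KOs; skipped")
      return(NULL)
    }
    k <- length(intersect(det, significant_kos))
    p <- if (method == "hypergeometric") {
      # P(X >= k) drawing n from N with S successes
      phyper(k - 1L, S, N - S, n, lower.tail = FALSE)
    } else {
      stats::pbinom(k - 1L, n, S / N, lower.tail = FALSE)
    }
    data.frame(module_id = modules$module_id[i],
               description = modules$description[i],
               n_module_kos = length(kos), n_detected = n,
               k_significant = k, p_enrichment = p,
               direction = direction, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(out$p_enrichment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full module-enrichment analysis between protein levels
#'
#' Runs [ko_ttest()] on a KO activity matrix, splits the significant KOs by
#' direction, and computes [module_enrichment()] separately for the
#' NP-higher and HP-higher sets, mirroring the two blocks of the enriched-
#' module table.
#'
#' @inheritParams ko_ttest
#' @param modules A `module_catalog`.
#' @param alpha KO-level and module-level significance threshold.
#' @return list with elements `ko` (the KO t-test table) and `modules`
#'   (the combined NP/HP enrichment table).
#' @export
module_enrichment_analysis <- function(ko_matrix, design, modules,
                                       alpha = 0.05, factor = "protein_level") {
  detected <- rownames(ko_matrix)[rowSums(unclass(ko_matrix)) > 0]
  kt <- ko_ttest(ko_matrix[detected, , drop = FALSE], design, factor = factor)
  sig <- kt[kt$p_value < alpha, , drop = FALSE]
  levels <- if (factor == "protein_level") c("NP", "HP") else c("LF", "HF")
  blocks <- lapply(levels, function(lv) {
    module_enrichment(sig$ko_id[sig$direction == paste0(lv, "-higher")],
                      detected, modules, alpha = alpha, direction = lv)
  })
  list(ko = kt, modules = do.call(rbind, blocks))
}

#' Pairwise SCFA group comparisons
#'
#' Two-sample Welch t-tests per acid for each diet pairing. The default
#' pairings contrast protein levels at matched fat content:
#' (NPLF, HPLF) and (NPHF, HPHF).
#'
#' @param panel An `scfa_panel` (long data.frame: `mouse_id`, `diet`,
#'   `acid`, `concentration`).
#' @param pairings list of length-2 character vectors of diet codes.
#' @param alpha Significance level for the star flag (default 0.05).
#' @return data.frame: `acid`, `diet_a`, `diet_b`, group means,
#'   `t_statistic`, `p_value`, `significant`.
#' @export
scfa_group_test <- function(panel,
                            pairings = list(c("NPLF", "HPLF"),
                                            c("NPHF", "HPHF")),
                            alpha = 0.05) {
  rows <- list()
  for (pair in pairings) {
    for (acid in unique(panel$acid)) {
      a <- panel$concentration[panel$diet == pair[1] & panel$acid == acid]
      b <- panel$concentration[panel$diet == pair[2] & panel$acid == acid]
      if (length(a) < 2 || length(b) < 2)
        stopf("fewer than 2 mice in group %s or %s for %s",
              pair[1], pair[2], acid)
      if (var(a) == 0 && var(b) == 0) {
        t_stat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
        p <- if (mean(a) == mean(b)) 1 else 0
      } else {
        ht <- t.test(a, b, var.equal = FALSE)
        t_stat <- unname(ht$statistic); p <- ht$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        acid = acid, diet_a = pair[1], diet_b = pair[2],
        mean_a = mean(a), mean_b = mean(b),
        t_statistic = t_stat, p_value = p, significant = p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test on a function category
#'
#' Two-sided Wilcoxon rank-sum test of per-sample category activity between
#' two groups; exact enumeration is used for group sizes up to 8 (absent
#' ties), the normal approximation otherwise. All values tied yields p = 1.
#'
#' @param values Named numeric vector of per-sample activity.
#' @param groups Factor/character vector (2 levels) aligned with `values`.
#' @return p-value in `[0, 1]`.
#' @export
wilcoxon_category_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  if (length(unique(c(a, b))) == 1L) return(1)
  exact <- max(length(a), length(b)) <= 8 &&
    !anyDuplicated(c(a, b))
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
}
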