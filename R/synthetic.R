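with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Study design for the 2x2 protein/fat diet intervention
#'
#' Builds the sample sheet of a four-diet mouse study: one row per mouse
#' with its diet code, protein level (NP/HP), fat level (LF/HF) and body
#' weight in grams. Weights are drawn around diet-specific means (high-fat
#' diets produce heavier mice).
#'
#' @param replicates Either a single count per diet group (default 4) or a
#'   named vector over `diet_levels()`, e.g. `c(NPLF = 3, NPHF = 4,
#'   HPLF = 4, HPHF = 4)` for the three-mice NPLF metatranscriptome subset.
#' @param seed Integer seed for the weight draws.
#' @param weight_means Named mean weight (g) per diet.
#' @param weight_sd Weight standard deviation (g).
#' @return data.frame of class `study_design` with columns `sample_id`,
#'   `diet`, `protein_level`, `fat_level`, `mouse_weight`.
#' @export
study_design <- function(replicates = 4, seed = 100,
                         weight_means = c(NPLF = 28, NPHF = 34,
                                          HPLF = 27, HPHF = 33),
                         weight_sd = 2) {
  diets <- diet_levels()
  if (length(replicates) == 1L) replicates <- setNames(rep(replicates, 4), diets)
  if (!setequal(names(replicates), diets))
    stopf("replicates must be named by the four diet groups")
  rows <- lapply(diets, function(d) {
    n <- replicates[[d]]
    if (n == 0) return(NULL)
    data.frame(sample_id = sprintf("%s_%d", d, seq_len(n)),
               diet = d,
               protein_level = protein_level_of(d),
               fat_level = fat_level_of(d),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids")
  df$mouse_weight <- with_seed(seed,
    round(rnorm(nrow(df), weight_means[df$diet], weight_sd), 1))
  class(df) <- c("study_design", "data.frame")
  df
}

#' @rdname study_design
#' @param design A `study_design` to subset.
#' @export
subset_design <- function(design, replicates) {
  keep <- unlist(lapply(diet_levels(), function(d) {
    ids <- which(design$diet == d)
    utils::head(ids, replicates[[d]])
  }))
  out <- design[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("study_design", "data.frame")
  out
}

#' Default ground-truth components of the synthetic study
#'
#' `default_family_fractions()` gives the family x diet composition
#' (Erysipelotrichaceae up, Lachnospiraceae down under high protein);
#' `default_planted_effects()` the module fold-changes (sugar modules
#' NP-enriched, protein modules HP-enriched, default fold 4);
#' `default_scfa_effects()` the per-diet acid means (umol/g) and noise SDs
#' with branched acids elevated under high protein.
#'
#' @return A matrix (fractions) or data.frame (effects); see
#'   [community_truth()].
#' @export
default_family_fractions <- function() {
  fam <- c("Lachnospiraceae", "Erysipelotrichaceae", "Clostridiaceae",
           "Ruminococcaceae", "Bacteroidaceae", "Porphyromonadaceae")
  np <- c(0.40, 0.10, 0.15, 0.15, 0.10, 0.10)
  hp <- c(0.25, 0.25, 0.18, 0.10, 0.10, 0.12)
  m <- cbind(NPLF = np, NPHF = np, HPLF = hp, HPHF = hp)
  rownames(m) <- fam
  m
}

#' @rdname default_family_fractions
#' @param fold Fold-change applied to every planted module.
#' @export
default_planted_effects <- function(fold = 4) {
  data.frame(
    module_id = c("M00377", "M00422", "M00196", "M00018", "M00299", "M00236"),
    direction = c(rep("NP-enriched", 3), rep("HP-enriched", 3)),
    fold_change = fold,
    stringsAsFactors = FALSE)
}

#' @rdname default_family_fractions
#' @export
default_scfa_effects <- function() {
  df <- data.frame(
    acid = scfa_acids(),
    NPLF = c(45, 6, 8, 0.20, 0.25, 0.30),
    NPHF = c(40, 5, 7, 0.20, 0.25, 0.30),
    HPLF = c(55, 8, 10, 0.60, 0.60, 0.70),
    HPHF = c(50, 7, 9, 0.50, 0.65, 0.75),
    sd = c(10, 2, 3, 0.15, 0.15, 0.20),
    stringsAsFactors = FALSE)
  df
}

#' Ground truth of a synthetic community study
#'
#' Encodes everything the generator plants and against which recovery is
#' tested: family composition per diet, module-level expression
#' fold-changes between protein levels, and the SCFA concentration means.
#' The defaults express the study's qualitative findings: the
#' *Erysipelotrichaceae* fraction rises (0.10 to 0.25) and
#' *Lachnospiraceae* falls (0.40 to 0.25) under high-protein diets; sugar
#' modules are expressed 4-fold higher under NP and protein modules 4-fold
#' higher under HP; branched-chain acids are elevated under HP.
#'
#' @param family_fractions Family x diet matrix of community fractions;
#'   each diet column must sum to 1 (within 1e-12).
#' @param planted_effects data.frame `module_id`, `direction`
#'   (`"NP-enriched"`/`"HP-enriched"`), `fold_change` (>= 1).
#' @param scfa_effects data.frame `acid`, one mean column per diet
#'   (umol/g), and `sd`.
#' @param modules The `module_catalog` the planted module ids refer to.
#' @param seed Master seed recorded with the truth.
#' @return list of class `community_truth`.
#' @export
community_truth <- function(family_fractions = default_family_fractions(),
                            planted_effects = default_planted_effects(),
                            scfa_effects = default_scfa_effects(),
                            modules = module_catalog(),
                            seed = 1) {
  sums <- colSums(family_fractions)
  if (any(abs(sums - 1) > 1e-12))
    stopf("family fractions must sum to 1 per diet group")
  if (any(family_fractions < 0))
    stopf("family fractions must be non-negative")
  if (any(planted_effects$fold_change < 1))
    stopf("planted fold-changes must be >= 1")
  if (!all(planted_effects$direction %in% c("NP-enriched", "HP-enriched")))
    stopf("planted effect direction must be NP-enriched or HP-enriched")
  unknown <- setdiff(planted_effects$module_id, modules$module_id)
  if (length(unknown))
    stopf("planted module(s) absent from the module catalog: %s",
          paste(unknown, collapse = ", "))
  if (any(unlist(scfa_effects[, diet_levels()]) < 0) ||
      any(scfa_effects$sd < 0))
    stopf("SCFA means and noise SDs must be non-negative")
  structure(list(families = rownames(family_fractions),
                 family_fractions = family_fractions,
                 planted_effects = planted_effects,
                 scfa_effects = scfa_effects,
                 modules = modules,
                 seed = as.integer(seed)),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf("<community_truth> %d families, %d planted module effects, seed %d\n",
              length(x$families), nrow(x$planted_effects), x$seed))
  invisible(x)
}

#' Default KO pool of the synthetic community
#'
#' Union of the module-catalog member KOs, the function-category KOs
#' (including the real SCFA pathway ids), and a block of unplanted
#' background KOs that pads the detected-KO universe to a realistic size.
#'
#' @param modules A `module_catalog`.
#' @param categories A `function_categories` list.
#' @param n_background Number of background KOs (default 116, giving a
#'   200-KO universe with the shipped catalog and categories).
#' @return Sorted character vector of KO ids.
#' @export
default_ko_pool <- function(modules = module_catalog(),
                            categories = function_categories(),
                            n_background = 116) {
  sort(unique(c(unlist(modules$kos), unlist(categories),
                sprintf("K77%03d", seq_len(n_background)))))
}

#' Generate the synthetic ORF catalog, contigs and annotations
#'
#' Builds a family-structured community around a shared gene template:
#' every family carries one ORF for each KO in the pool plus unannotated
#' background ORFs, with template ORF lengths shared across families.
#' Families therefore differ only in their overall activity, so KO-level
#' activity totals are invariant to community-composition shifts — a
#' property the recovery tests rely on. Each ORF sits on its own contig
#' with flanking sequence; contig sequences are uniform random nucleotides
#' (sequence content is never interrogated downstream). The protein hit
#' table gives every ORF a best hit carrying its true family plus lower
#' scoring decoy hits.
#'
#' @param families Family names (character vector), or an integer count
#'   (>= 2) for auto-named families.
#' @param orfs_per_family ORFs per family; must be at least
#'   `length(ko_pool)` so every KO is represented in every family.
#' @param ko_pool KO ids to plant (non-empty).
#' @param modules `module_catalog`; every module KO must be in `ko_pool`.
#' @param seed Integer seed.
#' @param length_range ORF length bounds in nt (lengths are multiples of 3).
#' @param flank Flanking contig sequence on each side of an ORF (nt).
#' @return list: `contigs` (DNAStringSet), `catalog` (`orf_catalog` with
#'   `family` and `ko` columns), `hits` (hit-table data.frame), `ko_map`
#'   (orf_id -> KO), `contig_lengths`.
#' @export
generate_catalog <- function(families, orfs_per_family, ko_pool,
                             modules = module_catalog(), seed = 1,
                             length_range = c(300, 3000), flank = 150) {
  if (is.numeric(families) && length(families) == 1L)
    families <- sprintf("Family%02d", seq_len(families))
  if (length(families) < 2) stopf("need at least 2 families")
  if (!is_count(orfs_per_family) || orfs_per_family < 1)
    stopf("orfs_per_family must be a positive integer")
  ko_pool <- sort(unique(as.character(ko_pool)))
  if (!length(ko_pool)) stopf("ko_pool must be non-empty")
  outside <- setdiff(unlist(modules$kos), ko_pool)
  if (length(outside))
    stopf("module KO(s) outside the ko_pool: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  n_ko <- length(ko_pool)
  if (orfs_per_family < n_ko)
    stopf("orfs_per_family (%d) must be >= length(ko_pool) (%d) so every KO is carried by every family",
          orfs_per_family, n_ko)
  with_seed(seed, {
    lens <- 3L * sample(seq(ceiling(length_range[1] / 3),
                            floor(length_range[2] / 3)),
                        orfs_per_family, replace = TRUE)
    template_ko <- c(ko_pool, rep(NA_character_,  orfs_per_family - n_ko))
    strands <- sample(c("+", "-"), orfs_per_family, replace = TRUE)
    entries <- list(); hit_rows <- list(); seqs <- character(0)
    for (f in families) {
      orf_ids <- sprintf("%s_ORF%04d", f, seq_len(orfs_per_family))
      contig_ids <- sprintf("%s_ctg%04d", f, seq_len(orfs_per_family))
      entries[[f]] <- data.frame(
        orf_id = orf_ids, contig_id = contig_ids,
        start = flank, end = flank + lens, strand = strands,
        family = f, ko = template_ko, stringsAsFactors = FALSE)
      ctg_lens <- lens + 2L * flank
      pool <- paste(sample(c("A", "C", "G", "T"), sum(ctg_lens),
                           replace = TRUE), collapse = "")
      ends <- cumsum(ctg_lens)
      seqs <- c(seqs, setNames(substring(pool, ends - ctg_lens + 1L, ends),
                               contig_ids))
      best_scores <- round(runif(orfs_per_family, 200, 400), 1)
      hit_rows[[f]] <- data.frame(
        orf_id = orf_ids,
        subject_id = sprintf("ref|%s|%04d", f, seq_len(orfs_per_family)),
        bit_score = best_scores,
        e_value = 10^(-best_scores / 10),
        subject_family = f, stringsAsFactors = FALSE)
      # decoy hits from a different family, strictly lower scoring
      decoy_fam <- sample(setdiff(families, f), orfs_per_family,
                          replace = TRUE)
      decoy_scores <- round(best_scores - runif(orfs_per_family, 5, 50), 1)
      hit_rows[[paste0(f, "_decoy")]] <- data.frame(
        orf_id = orf_ids,
        subject_id = sprintf("ref|%s|d%04d", decoy_fam,
                             seq_len(orfs_per_family)),
        bit_score = decoy_scores,
        e_value = 10^(-decoy_scores / 10),
        subject_family = decoy_fam, stringsAsFactors = FALSE)
    }
    catalog <- orf_catalog(do.call(rbind, unname(entries)))
    hits <- do.call(rbind, unname(hit_rows))
    rownames(hits) <- NULL
    list(contigs = Biostrings::DNAStringSet(seqs),
         catalog = catalog,
         hits = hits,
         ko_map = catalog_ko_map(catalog),
         contig_lengths = setNames(nchar(seqs), names(seqs)))
  })
}

orf_fold_factors <- function(catalog, truth, protein_level) {
  phi <- rep(1, nrow(catalog))
  eff <- truth$planted_effects
  favored <- ifelse(eff$direction == "NP-enriched", "NP", "HP")
  kos <- module_kos(truth$modules)
  for (i in seq_len(nrow(eff))) {
    if (favored[i] == protein_level) {
      hit <- catalog$ko %in% kos[[eff$module_id[i]]]
      phi[hit] <- phi[hit] * eff$fold_change[i]
    }
  }
  phi
}

# Expected per-ORF activity proportions for one protein level, applying
# planted module folds budget-preservingly: within each family the
# unannotated background ORFs are scaled down so the family's total
# expected activity is unchanged by the planted folds.
template_shares <- function(catalog, truth, protein_level) {
  phi <- orf_fold_factors(catalog, truth, protein_level)
  l <- catalog$end - catalog$start
  w <- l * phi
  shares <- numeric(nrow(catalog))
  for (f in unique(catalog$family)) {
    idx <- which(catalog$family == f)
    bg <- idx[is.na(catalog$ko[idx])]
    anno <- setdiff(idx, bg)
    L_tot <- sum(l[idx])
    if (length(bg)) {
      beta <- (L_tot - sum(w[anno])) / sum(l[bg])
      if (beta <= 0)
        stopf("family %s lacks background activity to absorb the planted folds; add background ORFs or lower fold_change", f)
      w[bg] <- beta * l[bg]
      shares[idx] <- w[idx] / L_tot
    } else {
      shares[idx] <- w[idx] / sum(w[idx])
    }
  }
  shares
}

#' Expected expression proportions of the synthetic community
#'
#' The noise-free expected per-ORF activity proportion for every sample:
#' `family_fraction(family(o), diet(s)) * within_family_share(o,
#' protein_level(s))`, with planted module folds applied
#' budget-preservingly within families. Columns sum to 1.
#'
#' @param truth A `community_truth`.
#' @param design A `study_design`.
#' @param catalog An annotated `orf_catalog` whose families all occur in
#'   the truth.
#' @return ORF x sample matrix of expected proportions.
#' @export
expected_expression <- function(truth, design, catalog) {
  unknown <- setdiff(unique(catalog$family), truth$families)
  if (length(unknown))
    stopf("catalog families missing from the truth: %s",
          paste(unknown, collapse = ", "))
  shares <- list(NP = template_shares(catalog, truth, "NP"),
                 HP = template_shares(catalog, truth, "HP"))
  m <- vapply(seq_len(nrow(design)), function(j) {
    diet <- design$diet[j]
    frac <- truth$family_fractions[catalog$family, diet]
    frac * shares[[design$protein_level[j]]]
  }, numeric(nrow(catalog)))
  dimnames(m) <- list(catalog$orf_id, design$sample_id)
  m
}

#' Simulate raw expression counts for a synthetic study
#'
#' Draws per-sample ORF nucleotide counts around the expected proportions
#' of [expected_expression()]: an independent multiplicative log-normal
#' factor (log-SD = `dispersion`) perturbs every ORF's expected activity,
#' and the sample's sequencing depth is then allocated across ORFs by a
#' single multinomial draw, producing overdispersed compositional counts
#' whose column sums equal `depth` exactly.
#'
#' @inheritParams expected_expression
#' @param depth Total aligned nucleotides per sample (> 0).
#' @param dispersion Log-normal SD of the per-ORF activity factor (>= 0;
#'   0 gives noise-free multinomial sampling).
#' @param seed Integer seed.
#' @return Raw-mode `expr_matrix` (ORF x sample).
#' @export
simulate_expression <- function(truth, design, catalog, depth = 2e6,
                                dispersion = 0, seed = 1) {
  if (!is.numeric(depth) || depth <= 0) stopf("depth must be positive")
  if (dispersion < 0) stopf("dispersion must be non-negative")
  p <- expected_expression(truth, design, catalog)
  with_seed(seed, {
    counts <- vapply(seq_len(ncol(p)), function(j) {
      pr <- p[, j]
      if (dispersion > 0)
        pr <- pr * rlnorm(length(pr), 0, dispersion)
      rmultinom(1, size = depth, prob = pr)[, 1]
    }, numeric(nrow(p)))
    dimnames(counts) <- dimnames(p)
    expression_matrix(counts, "raw")
  })
}

#' Simulate read alignment records that realize an expression matrix
#'
#' Emits gapless alignment records whose per-ORF aligned-nucleotide totals
#' re-count exactly to the given expression matrix: each ORF/sample cell of
#' `N` nucleotides becomes `N %/% read_length` reads of `read_length` plus
#' one remainder read, all placed uniformly inside the ORF. With
#' `boundary_reads = TRUE` a fraction of reads is shifted to cross ORF
#' boundaries (staying on the contig), in which case only their
#' within-ORF overlap is recovered by counting.
#'
#' @param expr Raw `expr_matrix` (ORF x sample).
#' @param catalog The matching `orf_catalog`.
#' @param read_length Read length in nt; must not exceed the shortest ORF
#'   (and, with boundary reads, the shortest contig).
#' @param seed Integer seed.
#' @param boundary_reads Allow reads crossing ORF boundaries.
#' @param boundary_fraction Fraction of reads shifted when
#'   `boundary_reads` is on.
#' @param contig_lengths Named contig lengths, required to clamp boundary
#'   reads to contig ends.
#' @return An `alignment_records` data.frame.
#' @export
simulate_alignment_records <- function(expr, catalog, read_length = 100,
                                       seed = 1, boundary_reads = FALSE,
                                       boundary_fraction = 0.2,
                                       contig_lengths = NULL) {
  if (read_length > min(catalog$end - catalog$start))
    stopf("read_length exceeds the shortest ORF (%d nt)",
          min(catalog$end - catalog$start))
  idx <- match(rownames(expr), catalog$orf_id)
  if (anyNA(idx)) stopf("expression rows missing from the catalog")
  with_seed(seed, {
    per_sample <- lapply(colnames(expr), function(s) {
      N <- unclass(expr)[, s]
      n_full <- N %/% read_length
      rem <- N %% read_length
      o_full <- rep(seq_along(N), n_full)
      len <- c(rep(read_length, length(o_full)),
               rem[rem > 0])
      orf_i <- idx[c(o_full, which(rem > 0))]
      lo <- catalog$start[orf_i]
      hi <- catalog$end[orf_i] - len
      start <- lo + floor(runif(length(len)) * (hi - lo + 1))
      df <- data.frame(
        read_id = sprintf("%s_r%07d", s, seq_along(len)),
        contig_id = catalog$contig_id[orf_i],
        start = start, end = start + len,
        sample_id = s, stringsAsFactors = FALSE)
      if (boundary_reads && nrow(df)) {
        shift_n <- rbinom(1, nrow(df), boundary_fraction)
        pick <- sample.int(nrow(df), shift_n)
        delta <- sample(c(-1, 1), shift_n, replace = TRUE) *
          sample.int(read_length - 1L, shift_n, replace = TRUE)
        ns <- df$start[pick] + delta
        ns <- pmax(ns, 0L)
        if (!is.null(contig_lengths)) {
          cl <- contig_lengths[df$contig_id[pick]]
          ns <- pmin(ns, cl - (df$end[pick] - df$start[pick]))
        }
        width <- df$end[pick] - df$start[pick]
        df$start[pick] <- ns
        df$end[pick] <- ns + width
      }
      df
    })
    alignment_records(do.call(rbind, per_sample))
  })
}

#' Simulate the caecal SCFA concentration panel
#'
#' One row per mouse and acid, in umol/g caecal content: the diet-specific
#' mean perturbed by Gaussian noise truncated at zero (negative draws are
#' rejected and redrawn).
#'
#' @param truth A `community_truth` (supplies the per-diet acid means and
#'   noise SDs).
#' @param design A `study_design`: one row per mouse.
#' @param seed Integer seed.
#' @return Long data.frame of class `scfa_panel`: `mouse_id`, `diet`,
#'   `acid`, `concentration`.
#' @export
simulate_scfa_panel <- function(truth, design, seed = 1) {
  eff <- truth$scfa_effects
  if (any(eff$sd < 0)) stopf("SCFA noise SD must be non-negative")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(eff)), function(i) {
      mu <- unlist(eff[i, design$diet])
      sdv <- eff$sd[i]
      conc <- rnorm(nrow(design), mu, sdv)
      while (any(conc < 0))
        conc[conc < 0] <- rnorm(sum(conc < 0), mu[conc < 0], sdv)
      data.frame(mouse_id = design$sample_id, diet = design$diet,
                 acid = eff$acid[i], concentration = conc,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("scfa_panel", "data.frame")
    out
  })
}

#' Write / read the ground-truth description
#'
#' Structured YAML holding family fractions, planted effects, SCFA effects
#' and the master seed — everything a recovery test compares against.
#'
#' @param truth A `community_truth`.
#' @param path YAML file path.
#' @export
write_truth <- function(truth, path) {
  ff <- truth$family_fractions
  yaml::write_yaml(list(
    families = truth$families,
    family_fractions = setNames(
      lapply(colnames(ff), function(d) as.list(setNames(ff[, d], rownames(ff)))),
      colnames(ff)),
    planted_effects = lapply(seq_len(nrow(truth$planted_effects)), function(i)
      as.list(truth$planted_effects[i, ])),
    scfa_effects = lapply(seq_len(nrow(truth$scfa_effects)), function(i)
      as.list(truth$scfa_effects[i, ])),
    seed = truth$seed), path)
  invisible(path)
}

#' @rdname write_truth
#' @param modules The `module_catalog` to re-attach (the YAML stores only
#'   planted effects).
#' @export
read_truth <- function(path, modules = module_catalog()) {
  y <- yaml::read_yaml(path)
  ff <- do.call(cbind, lapply(y$family_fractions, function(d)
    unlist(d)[y$families]))
  rownames(ff) <- y$families
  community_truth(
    family_fractions = ff,
    planted_effects = do.call(rbind, lapply(y$planted_effects, as.data.frame)),
    scfa_effects = do.call(rbind, lapply(y$scfa_effects, as.data.frame)),
    modules = modules,
    seed = y$seed)
}
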