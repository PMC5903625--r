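test_that("study designs carry the 2x2 diet structure and weights", {
  d <- study_design(replicates = 4, seed = 1)
  expect_equal(nrow(d), 16L)
  expect_equal(as.vector(table(d$diet)[diet_levels()]), rep(4L, 4))
  expect_setequal(unique(d$protein_level), c("NP", "HP"))
  sub <- subset_design(study_design(replicates = 10, seed = 1),
                       c(NPLF = 3, NPHF = 4, HPLF = 4, HPHF = 4))
  expect_equal(nrow(sub), 15L)
  expect_equal(sum(sub$diet == "NPLF"), 3L)
  # subset keeps the parent's mice (shared ids and weights)
  full <- study_design(replicates = 10, seed = 1)
  expect_true(all(sub$sample_id %in% full$sample_id))
})

test_that("community truth validates fractions, folds and module ids", {
  expect_s3_class(mini_truth(), "community_truth")
  bad_fr <- cbind(NPLF = c(0.6, 0.3), NPHF = c(0.6, 0.3),
                  HPLF = c(0.5, 0.5), HPHF = c(0.5, 0.5))
  rownames(bad_fr) <- c("A", "B")
  expect_error(community_truth(family_fractions = bad_fr,
                               planted_effects = default_planted_effects(),
                               modules = module_catalog()),
               "sum to 1")
  bad_fold <- default_planted_effects()
  bad_fold$fold_change[1] <- 0.5
  expect_error(community_truth(planted_effects = bad_fold), ">= 1")
  ghost <- default_planted_effects()
  ghost$module_id[1] <- "M99999"
  expect_error(community_truth(planted_effects = ghost), "M99999")
})

test_that("catalog generation is deterministic and structurally sound", {
  pool <- c("K00001", "K00002", "K00925")
  mod <- data.frame(module_id = "Mx", description = "d",
                    stringsAsFactors = FALSE)
  mod$kos <- list(c("K00925"))
  class(mod) <- c("module_catalog", "data.frame")
  g1 <- generate_catalog(2, 5, pool, modules = mod, seed = 7)
  g2 <- generate_catalog(2, 5, pool, modules = mod, seed = 7)
  expect_equal(nrow(g1$catalog), 10L)
  expect_identical(g1$catalog, g2$catalog)
  expect_identical(as.character(g1$contigs), as.character(g2$contigs))
  expect_identical(g1$hits, g2$hits)
  # the Fig-4 acetate kinase KO is carried by at least one ORF
  expect_true(any(g1$catalog$ko == "K00925", na.rm = TRUE))
  # every module KO is carried in >= 2 families
  fams_with <- unique(g1$catalog$family[which(g1$catalog$ko == "K00925")])
  expect_gte(length(fams_with), 2L)
  # lengths are in range and multiples of 3
  len <- g1$catalog$end - g1$catalog$start
  expect_true(all(len >= 300 & len <= 3000))
  expect_true(all(len %% 3 == 0))
  # at most one KO per ORF, exactly one family
  expect_false(anyDuplicated(g1$catalog$orf_id) > 0)
  # best hit carries the true family
  fam <- assign_family_best_hit(g1$hits, orf_ids = g1$catalog$orf_id)
  expect_equal(unname(fam[g1$catalog$orf_id]), g1$catalog$family)
})

test_that("catalog generation rejects degenerate inputs", {
  mod <- data.frame(module_id = "Mx", description = "d",
                    stringsAsFactors = FALSE)
  mod$kos <- list("K00001")
  class(mod) <- c("module_catalog", "data.frame")
  expect_error(generate_catalog(2, 0, "K00001", modules = mod),
               "positive integer")
  expect_error(generate_catalog(2, 5, character(0), modules = mod),
               "non-empty")
  expect_error(generate_catalog(1, 5, "K00001", modules = mod),
               "at least 2")
  mod$kos <- list(c("K00001", "K99999"))
  expect_error(generate_catalog(2, 5, "K00001", modules = mod), "K99999")
})

test_that("expected expression is symmetric without effects and columns sum to 1", {
  fr <- cbind(NPLF = 1, NPHF = 1, HPLF = 1, HPHF = 1)
  rownames(fr) <- "FamOnly"
  truth <- community_truth(
    family_fractions = fr,
    planted_effects = default_planted_effects()[0, ],
    modules = module_catalog(), seed = 1)
  catalog <- orf_catalog(data.frame(
    orf_id = c("o1", "o2"), contig_id = c("c1", "c2"),
    start = 0L, end = 600L, strand = "+",
    family = "FamOnly", ko = c("K00001", "K00002"),
    stringsAsFactors = FALSE))
  design <- study_design(replicates = 1, seed = 2)
  p <- expected_expression(truth, design, catalog)
  expect_true(all(abs(p - 0.5) < 1e-12))  # equal length, equal share
  st <- mini_study()
  p2 <- expected_expression(st$truth, st$design, st$gen$catalog)
  expect_equal(unname(colSums(p2)), rep(1, nrow(st$design)), tolerance = 1e-12)
})

test_that("a planted fold of 4 forces an exact 4x normalized module ratio", {
  st <- mini_study(dispersion = 0, fold = 4)
  p <- expected_expression(st$truth, st$design, st$gen$catalog)
  ko_map <- st$gen$ko_map
  np <- st$design$protein_level == "NP"
  for (i in 1:2) {
    mod_kos <- st$truth$modules$kos[[i]]
    rows <- names(ko_map)[ko_map %in% mod_kos]
    share <- colSums(p[rows, ])
    ratio <- mean(share[!np]) / mean(share[np])
    expected <- if (st$truth$planted_effects$direction[i] == "HP-enriched")
      4 else 1 / 4
    expect_equal(ratio, expected, tolerance = 1e-12)
  }
})

test_that("unannotated background absorbs the planted folds budget-preservingly", {
  st <- mini_study(fold = 4)
  p <- expected_expression(st$truth, st$design, st$gen$catalog)
  cat_fam <- st$gen$catalog$family
  # family totals equal the planted community fractions in every sample
  for (j in seq_len(nrow(st$design))) {
    fam_tot <- tapply(p[, j], cat_fam, sum)
    want <- st$truth$family_fractions[names(fam_tot), st$design$diet[j]]
    expect_equal(as.vector(fam_tot), unname(want), tolerance = 1e-12)
  }
  # an absurd fold overwhelms the background and is rejected
  expect_error(mini_study(fold = 500), "background")
})

test_that("simulated counts are reproducible and have exact column sums", {
  st <- mini_study(dispersion = 0.3, depth = 5e4)
  expect_equal(unname(colSums(st$expr)), rep(5e4, nrow(st$design)))
  again <- simulate_expression(st$truth, st$design, st$gen$catalog,
                               depth = 5e4, dispersion = 0.3, seed = 4)
  expect_identical(unclass(st$expr), unclass(again))
})

test_that("empirical mean counts stay near the closed-form expectation", {
  truth <- mini_truth(fold = 1)
  design <- study_design(replicates = c(NPLF = 1, NPHF = 0, HPLF = 0,
                                        HPHF = 0), seed = 3)
  gen <- generate_catalog(truth$families, 40, mini_ko_pool(),
                          modules = mini_modules(), seed = 5)
  p <- expected_expression(truth, design, gen$catalog)[, 1]
  depth <- 1e4
  reps <- 2000
  set.seed(99)
  sums <- numeric(length(p))
  sumsq <- numeric(length(p))
  for (r in seq_len(reps)) {
    pr <- p * rlnorm(length(p), 0, 0.2)
    cts <- rmultinom(1, depth, pr)[, 1]
    sums <- sums + cts
    sumsq <- sumsq + cts^2
  }
  emp_mean <- sums / reps
  emp_se <- sqrt(pmax(sumsq / reps - emp_mean^2, 0) / reps)
  z <- (emp_mean - depth * p) / emp_se
  expect_lt(max(abs(z)), 4.5)
})

test_that("alignment simulation round-trips counts exactly without boundary reads", {
  st <- mini_study(dispersion = 0.2, depth = 2e4)
  reads <- simulate_alignment_records(st$expr, st$gen$catalog,
                                      read_length = 100, seed = 6)
  recount <- count_aligned_nucleotides(reads, st$gen$catalog,
                                       samples = st$design$sample_id)
  expect_equal(unclass(recount), unclass(st$expr), ignore_attr = TRUE)
  # single 100 nt read fully inside an ORF contributes exactly 100
  one <- expression_matrix(
    matrix(100, 1, 1, dimnames = list(st$gen$catalog$orf_id[1], "s1")), "raw")
  r1 <- simulate_alignment_records(one, st$gen$catalog, read_length = 100,
                                   seed = 1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$end - r1$start, 100L)
  expect_gte(r1$start, st$gen$catalog$start[1])
  expect_lte(r1$end, st$gen$catalog$end[1])
})

test_that("boundary reads re-count to the per-base overlap oracle", {
  truth <- mini_truth()
  gen <- generate_catalog(truth$families, 40, mini_ko_pool(),
                          modules = mini_modules(), seed = 8)
  design <- study_design(replicates = c(NPLF = 1, NPHF = 0, HPLF = 0,
                                        HPHF = 0), seed = 3)
  small <- gen$catalog[1:6, ]
  class(small) <- c("orf_catalog", "data.frame")
  expr <- expression_matrix(
    matrix(c(350, 120, 0, 777, 90, 1000), ncol = 1,
           dimnames = list(small$orf_id, "s1")), "raw")
  reads <- simulate_alignment_records(expr, small, read_length = 80,
                                      seed = 10, boundary_reads = TRUE,
                                      boundary_fraction = 0.5,
                                      contig_lengths = gen$contig_lengths)
  got <- count_aligned_nucleotides(reads, small, samples = "s1")
  expect_equal(unclass(got)[, , drop = FALSE],
               brute_force_count(reads, small, "s1"), ignore_attr = TRUE)
})

test_that("SCFA panels honour their noise model and seed", {
  truth <- mini_truth()
  design <- study_design(replicates = 3, seed = 2)
  truth0 <- truth
  truth0$scfa_effects$sd[] <- 0
  p0 <- simulate_scfa_panel(truth0, design, seed = 5)
  for (i in seq_len(nrow(p0))) {
    want <- truth0$scfa_effects[truth0$scfa_effects$acid == p0$acid[i],
                                p0$diet[i]]
    expect_equal(p0$concentration[i], want)
  }
  p1 <- simulate_scfa_panel(truth, design, seed = 5)
  p2 <- simulate_scfa_panel(truth, design, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1$concentration >= 0))
  bad <- truth
  bad$scfa_effects$sd[1] <- -1
  expect_error(simulate_scfa_panel(bad, design, seed = 1), "non-negative")
})

test_that("truth files round-trip through YAML", {
  truth <- mini_truth()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(truth, path)
  back <- read_truth(path, modules = mini_modules())
  expect_equal(back$family_fractions, truth$family_fractions)
  expect_equal(back$planted_effects$module_id, truth$planted_effects$module_id)
  expect_equal(back$planted_effects$fold_change, truth$planted_effects$fold_change)
  expect_equal(back$seed, truth$seed)
})
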