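design_44 <- study_design(replicates = 2, seed = 5)  # 4 NP vs 4 HP samples

ko_mat <- function(values) {
  m <- do.call(rbind, values)
  colnames(m) <- design_44$sample_id
  m
}

test_that("per-KO t-tests flag forced separation and degenerate rows", {
  np <- design_44$protein_level == "NP"
  flat <- setNames(rep(1e-3, 8), design_44$sample_id)
  up <- ifelse(np, 1e-3, 4e-3) + c(1, -1, 2, -2, 1, -1, 2, -2) * 1e-6
  m <- ko_mat(list(flat = flat, up = up))
  rownames(m) <- c("Kflat", "Kup")
  res <- ko_ttest(m, design_44)
  flat_row <- res[res$ko_id == "Kflat", ]
  expect_equal(flat_row$p_value, 1)
  expect_equal(flat_row$t_statistic, 0)
  expect_true(flat_row$degenerate)
  up_row <- res[res$ko_id == "Kup", ]
  expect_lt(up_row$p_value, 0.05)
  expect_equal(up_row$direction, "HP-higher")
})

test_that("t statistics and p-values match the closed-form Welch oracle", {
  set.seed(11)
  np <- design_44$protein_level == "NP"
  for (i in 1:20) {
    vals <- rnorm(8, mean = 1, sd = 0.3)
    m <- ko_mat(list(k = setNames(vals, design_44$sample_id)))
    rownames(m) <- "K1"
    res <- ko_ttest(m, design_44)
    oracle <- welch_oracle(vals[np], vals[!np])
    expect_equal(res$t_statistic, oracle$t, tolerance = 1e-10)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  }
})

test_that("BH adjustment is available behind a flag", {
  set.seed(3)
  m <- matrix(rnorm(80, 1, 0.2), nrow = 10,
              dimnames = list(paste0("K", 1:10), design_44$sample_id))
  res <- ko_ttest(m, design_44, adjust = "BH")
  expect_equal(res$p_adjusted, p.adjust(res$p_value, "BH"))
  raw <- ko_ttest(m, design_44)
  expect_equal(raw$p_adjusted, raw$p_value)
})

two_modules <- function(kos1, kos2 = NULL) {
  df <- data.frame(module_id = c("M1", "M2")[seq_len(1 + !is.null(kos2))],
                   description = "test", stringsAsFactors = FALSE)
  df$kos <- if (is.null(kos2)) list(kos1) else list(kos1, kos2)
  class(df) <- c("module_catalog", "data.frame")
  df
}

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- sprintf("K%02d", 1:12)
  signif <- universe[1:5]
  mod <- two_modules(c(universe[1:3], universe[10]))  # n = 4, k = 3
  res <- module_enrichment(signif, universe, mod)
  expect_equal(res$n_detected, 4L)
  expect_equal(res$k_significant, 3L)
  expect_equal(res$p_enrichment, enumerated_tail(12, 5, 4, 3),
               tolerance = 1e-12)
})

test_that("enrichment boundary cases behave as specified", {
  universe <- sprintf("K%02d", 1:10)
  signif <- universe[1:4]
  # no significant member -> p = 1
  res0 <- module_enrichment(character(0), universe,
                            two_modules(universe[5:7]))
  expect_equal(res0$p_enrichment, 1)
  expect_equal(res0$k_significant, 0L)
  # module exactly the significant set -> minimum attainable p
  resmax <- module_enrichment(signif, universe, two_modules(signif))
  expect_equal(resmax$p_enrichment,
               1 / choose(10, 4), tolerance = 1e-12)
  # module with no detected KO is skipped with a notice
  mod <- two_modules("K99", universe[1:2])
  expect_message(res <- module_enrichment(signif, universe, mod), "skipped")
  expect_equal(res$module_id, "M2")
  # significant set must be inside the universe
  expect_error(module_enrichment("Kxx", universe, two_modules(universe[1:2])),
               "subset")
})

test_that("enrichment p is non-increasing in k at fixed n and universe", {
  universe <- sprintf("K%02d", 1:12)
  mod_kos <- universe[1:4]
  p_at_k <- vapply(0:4, function(k) {
    # |significant| fixed at 5, overlap with the module equal to k
    signif <- c(mod_kos[seq_len(k)],
                setdiff(universe, mod_kos)[seq_len(5 - k)])
    module_enrichment(signif, universe, two_modules(mod_kos))$p_enrichment
  }, numeric(1))
  expect_true(all(diff(p_at_k) <= 1e-12))
})

test_that("a Table-4-shaped row (M00196, n = 4, k = 3, NP) can be emitted", {
  modules <- module_catalog()
  m196 <- modules$kos[[which(modules$module_id == "M00196")]]
  universe <- default_ko_pool()
  signif <- c(m196[1:3], setdiff(universe, m196)[1:6])
  res <- module_enrichment(signif, universe, modules, direction = "NP")
  row <- res[res$module_id == "M00196", ]
  expect_equal(row$n_detected, 4L)
  expect_equal(row$k_significant, 3L)
  expect_equal(row$direction, "NP")
  expect_true(row$significant)
  expect_true(all(c("module_id", "description", "n_module_kos", "n_detected",
                    "k_significant", "p_enrichment", "direction",
                    "significant") %in% names(res)))
})

test_that("the binomial approximation option is coherent with the tail", {
  universe <- sprintf("K%02d", 1:12)
  res <- module_enrichment(universe[1:5], universe,
                           two_modules(universe[c(1:3, 10)]),
                           method = "binomial")
  expect_equal(res$p_enrichment,
               pbinom(2, 4, 5 / 12, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("SCFA group tests compare matched-fat protein contrasts", {
  truth <- mini_truth()
  design <- study_design(replicates = 10, seed = 9)
  panel <- simulate_scfa_panel(truth, design, seed = 2)
  res <- scfa_group_test(panel)
  expect_setequal(unique(res$acid), scfa_acids())
  expect_setequal(unique(paste(res$diet_a, res$diet_b)),
                  c("NPLF HPLF", "NPHF HPHF"))
  # forced separation: iso-butyrate planted much higher under HP
  iso <- res[res$acid == "iso-butyrate" & res$diet_a == "NPHF", ]
  expect_true(iso$significant)
  # oracle agreement
  a <- panel$concentration[panel$diet == "NPLF" & panel$acid == "acetate"]
  b <- panel$concentration[panel$diet == "HPLF" & panel$acid == "acetate"]
  oracle <- welch_oracle(a, b)
  row <- res[res$acid == "acetate" & res$diet_a == "NPLF", ]
  expect_equal(row$t_statistic, oracle$t, tolerance = 1e-10)
  expect_equal(row$p_value, oracle$p, tolerance = 1e-10)
})

test_that("degenerate SCFA comparisons and tiny groups are handled", {
  truth0 <- mini_truth()
  truth0$scfa_effects$sd[] <- 0
  truth0$scfa_effects[, c("HPLF", "HPHF")] <-
    truth0$scfa_effects[, c("NPLF", "NPHF")]
  design <- study_design(replicates = 3, seed = 9)
  panel <- simulate_scfa_panel(truth0, design, seed = 2)
  res <- scfa_group_test(panel)
  expect_true(all(res$p_value == 1))
  one_mouse <- panel[panel$mouse_id != "NPLF_2" & panel$mouse_id != "NPLF_3", ]
  expect_error(scfa_group_test(one_mouse), "fewer than 2")
})

test_that("Wilcoxon category test uses exact enumeration on small groups", {
  # all C(6,3) = 20 rank assignments: the extreme split has two-sided p
  # 2 * (1/20) = 0.1
  expect_equal(wilcoxon_category_test(c(1, 2, 3, 4, 5, 6),
                                      rep(c("a", "b"), each = 3)), 0.1)
  expect_equal(wilcoxon_category_test(rep(2, 6),
                                      rep(c("a", "b"), each = 3)), 1)
  # symmetry under label swap
  set.seed(4)
  v <- rnorm(12)
  g <- rep(c("a", "b"), each = 6)
  g_swapped <- rep(c("b", "a"), each = 6)
  expect_equal(wilcoxon_category_test(v, g), wilcoxon_category_test(v, g_swapped))
})
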