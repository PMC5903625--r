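#' Log10 transform with a scale-aware pseudocount
#'
#' Elementwise `log10(x + pseudocount)`. The default pseudocount is half
#' the smallest nonzero value of the matrix when zeros are present (scale
#' aware, avoiding an arbitrary +1 on fractional data) and 0 otherwise.
#'
#' @param m Non-negative numeric matrix.
#' @param pseudocount Non-negative scalar, or `NULL` for the default rule.
#' @return Matrix of the same shape; attribute `"pseudocount"` records the
#'   value used.
#' @export
log10_transform <- function(m, pseudocount = NULL) {
  if (any(m < 0)) stopf("abundance matrix must be non-negative")
  has_zero <- any(m == 0)
  if (is.null(pseudocount))
    pseudocount <- if (has_zero) min(m[m > 0]) / 2 else 0
  if (pseudocount == 0 && has_zero)
    stopf("zero entries present: a positive pseudocount is required")
  out <- log10(unclass(m) + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Hierarchical clustering of samples by Pearson distance and Ward linkage
#'
#' Sample columns are compared by the correlation distance
#' `d(i, j) = 1 - r(i, j)` and merged by Ward's minimum-variance criterion
#' applied to the squared input dissimilarities (the `ward.D2` convention,
#' so the given non-Euclidean distances are used as-is).
#'
#' @param m Feature x sample matrix (e.g. log10-transformed abundances).
#' @return An object of class `hclust`; leaf labels are the sample names.
#' @export
pearson_ward_cluster <- function(m) {
  if (ncol(m) < 2) stopf("need at least two samples to cluster")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stopf("constant sample column(s): %s",
          paste(colnames(m)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(m))
  hclust(d, method = "ward.D2")
}

#' @rdname pearson_ward_cluster
#' @param hc An `hclust` object.
#' @return `linkage_table()`: data.frame of the merge sequence
#'   (`node_a`, `node_b`, `height`; negative entries are leaves).
#' @export
linkage_table <- function(hc) {
  data.frame(node_a = hc$merge[, 1], node_b = hc$merge[, 2],
             height = hc$height)
}

#' @rdname pearson_ward_cluster
#' @param path Output Newick file (merge heights become branch lengths).
#' @export
write_linkage_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' @importFrom stats as.dist model.matrix
build_explanatory_matrix <- function(explanatory) {
  stopifnot(is.data.frame(explanatory))
  cols <- lapply(names(explanatory), function(nm) {
    v <- explanatory[[nm]]
    if (is.numeric(v)) {
      # standardize continuous covariates
      s <- sd(v)
      x <- matrix(if (s > 0) (v - mean(v)) / s else v - mean(v), ncol = 1)
      colnames(x) <- nm
      x
    } else {
      # nominal variables as one-hot indicators, first level dropped
      f <- as.factor(v)
      x <- model.matrix(~ f)[, -1, drop = FALSE]
      colnames(x) <- paste0(nm, levels(f)[-1])
      x
    }
  })
  do.call(cbind, cols)
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination of a response matrix on explanatory variables:
#' response features are centered, projected onto the column space of the
#' centered explanatory matrix, and the canonical axes are the principal
#' axes of the fitted values. The constrained fraction is the share of
#' total response variance explained by the explanatory variables.
#'
#' Nominal explanatory columns enter as one-hot indicators (first level
#' dropped); continuous covariates are standardized. Collinear columns are
#' dropped with a warning. With at least `n - 1` independent explanatory
#' columns the projection saturates and the constrained fraction is 1.
#'
#' @param response Feature x sample non-negative (or transformed) matrix.
#' @param explanatory data.frame of explanatory variables, one row per
#'   sample in the order of `colnames(response)`.
#' @return list of class `rda_result`: `constrained_fraction`,
#'   `axis_fractions` (per canonical axis, relative to total variance),
#'   `sample_scores`, `feature_scores`, `explanatory_scores`,
#'   `feature_axis_variance`, `feature_total_variance`, `rank`.
#' @export
rda_fit <- function(response, explanatory) {
  n <- ncol(response)
  if (nrow(explanatory) != n)
    stopf("explanatory rows (%d) must match response samples (%d)",
          nrow(explanatory), n)
  X <- build_explanatory_matrix(explanatory)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  rank <- qrx$rank
  if (rank < ncol(Xc)) {
    dropped <- colnames(Xc)[qrx$pivot[(rank + 1):ncol(Xc)]]
    warnf("dropping collinear explanatory column(s): %s",
          paste(dropped, collapse = ", "))
  }
  if (rank >= n - 1)
    warnf("explanatory variables span the sample space; constrained fraction saturates at 1")
  Y <- t(unclass(response))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  total <- sum(Yc^2)
  if (total == 0) stopf("response matrix has no variance")
  fitted <- qr.fitted(qrx, Yc)
  sv <- svd(fitted)
  keep <- which(sv$d^2 / total > 1e-12)
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  axis_fractions <- d^2 / total
  axis_names <- if (length(d)) paste0("RDA", seq_along(d)) else character(0)
  sample_scores <- sweep(U, 2, d, "*")
  dimnames(sample_scores) <- list(colnames(response), axis_names)
  dimnames(V) <- list(rownames(response), axis_names)
  expl_scores <- suppressWarnings(cor(Xc[, qrx$pivot[seq_len(rank)], drop = FALSE],
                                      sample_scores))
  # per-feature variance resolved along each canonical axis
  C <- crossprod(U, Yc)                  # axes x features
  structure(list(
    constrained_fraction = sum(d^2) / total,
    axis_fractions = axis_fractions,
    sample_scores = sample_scores,
    feature_scores = V,
    explanatory_scores = expl_scores,
    feature_axis_variance = C^2,
    feature_total_variance = colSums(Yc^2),
    rank = rank), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("<rda_result> constrained fraction %.3f over %d canonical axes\n",
              x$constrained_fraction, length(x$axis_fractions)))
  cat("axis fractions:",
      paste(sprintf("%.3f", x$axis_fractions), collapse = " "), "\n")
  invisible(x)
}

#' Monte Carlo permutation test for the RDA constrained fraction
#'
#' Rows of the explanatory table are permuted jointly; the p-value is
#' `(1 + #{permuted fraction >= observed}) / (1 + n_permutations)` (the
#' add-one convention, so p can never be zero).
#'
#' @inheritParams rda_fit
#' @param n_permutations Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the permutation stream.
#' @return list: `p_value`, `observed`, `permuted` (vector of permuted
#'   constrained fractions).
#' @export
rda_permutation_test <- function(response, explanatory,
                                 n_permutations = 999, seed = 1) {
  if (n_permutations < 99) stopf("use at least 99 permutations")
  n <- ncol(response)
  X <- build_explanatory_matrix(explanatory)
  Yc <- scale(t(unclass(response)), center = TRUE, scale = FALSE)
  total <- sum(Yc^2)
  frac <- function(Xmat) {
    Xc <- scale(Xmat, center = TRUE, scale = FALSE)
    sum(qr.fitted(qr(Xc), Yc)^2) / total
  }
  observed <- frac(X)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  permuted <- vapply(seq_len(n_permutations), function(i) {
    frac(X[sample.int(n), , drop = FALSE])
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(p_value = (1 + sum(permuted >= observed)) / (1 + n_permutations),
       observed = observed, permuted = permuted)
}

#' Select features resolved on the first two canonical axes
#'
#' Keeps the features (species) whose variance captured by the first two
#' canonical axes is at least `threshold` of their total variance —
#' the rule used to declutter ordination biplots.
#'
#' @param result An `rda_result`.
#' @param threshold Minimum resolved-variance fraction (default 0.5).
#' @return Character vector of retained feature names.
#' @export
species_axis_filter <- function(result, threshold = 0.5) {
  if (length(result$axis_fractions) < 2)
    stopf("need at least two canonical axes")
  captured <- colSums(result$feature_axis_variance[1:2, , drop = FALSE])
  tot <- result$feature_total_variance
  frac <- ifelse(tot > 0, captured / tot, 0)
  names(frac)[frac >= threshold]
}

#' Write RDA scores as a TSV triptych
#'
#' @param result An `rda_result`.
#' @param dir Output directory; writes `rda_samples.tsv`,
#'   `rda_features.tsv`, `rda_variables.tsv` and `rda_summary.tsv`.
#' @export
write_rda_tsv <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(m, f, id) {
    df <- data.frame(id = rownames(m), as.data.frame(unclass(m)),
                     check.names = FALSE)
    names(df)[1] <- id
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(result$sample_scores, "rda_samples.tsv", "sample_id")
  wr(result$feature_scores, "rda_features.tsv", "feature_id")
  wr(result$explanatory_scores, "rda_variables.tsv", "variable")
  write.table(
    data.frame(axis = c("constrained", paste0("RDA", seq_along(result$axis_fractions))),
               fraction = c(result$constrained_fraction, result$axis_fractions)),
    file.path(dir, "rda_summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
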