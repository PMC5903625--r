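# Independent oracles and small fixture builders shared across the suite.
# Every oracle here is written from first principles (per-base loops,
# exhaustive enumeration, closed forms) and never calls the package code
# path it is used to check.

# --- per-base membership counting oracle -----------------------------------

# Counts aligned nucleotides ORF x sample by looping over every aligned
# base of every block and asking which ORFs contain it.
brute_force_count <- function(alignments, catalog, samples = NULL) {
  samples <- samples %||% sort(unique(alignments$sample_id))
  m <- matrix(0, nrow = nrow(catalog), ncol = length(samples),
              dimnames = list(catalog$orf_id, samples))
  for (r in seq_len(nrow(alignments))) {
    s <- alignments$sample_id[r]
    if (!s %in% samples) next
    pos <- seq(alignments$start[r], alignments$end[r] - 1L)
    for (o in which(catalog$contig_id == alignments$contig_id[r])) {
      m[o, s] <- m[o, s] + sum(pos >= catalog$start[o] & pos < catalog$end[o])
    }
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small counting instance: contigs <= 1 kb, <= 20 reads.
random_counting_instance <- function(seed) {
  set.seed(seed)
  n_contig <- sample(1:3, 1)
  contig_ids <- paste0("ctg", seq_len(n_contig))
  contig_len <- sample(200:1000, n_contig, replace = TRUE)
  orfs <- list()
  for (i in seq_len(n_contig)) {
    n_orf <- sample(1:4, 1)
    for (j in seq_len(n_orf)) {
      a <- sample(0:(contig_len[i] - 30L), 1)
      b <- min(contig_len[i], a + sample(30:300, 1))
      orfs[[length(orfs) + 1L]] <- data.frame(
        orf_id = sprintf("ctg%d_orf%d", i, j), contig_id = contig_ids[i],
        start = a, end = b, strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE)
    }
  }
  catalog <- orf_catalog(do.call(rbind, orfs))
  n_read <- sample(0:20, 1)
  reads <- if (n_read > 0) {
    ci <- sample(n_contig, n_read, replace = TRUE)
    len <- sample(20:120, n_read, replace = TRUE)
    len <- pmin(len, contig_len[ci])
    st <- vapply(seq_len(n_read), function(k)
      sample(0:(contig_len[ci[k]] - len[k]), 1), numeric(1))
    alignment_records(data.frame(
      read_id = paste0("r", seq_len(n_read)),
      contig_id = contig_ids[ci], start = st, end = st + len,
      sample_id = sample(c("s1", "s2"), n_read, replace = TRUE),
      stringsAsFactors = FALSE))
  } else {
    alignment_records(data.frame(read_id = character(0),
                                 contig_id = character(0),
                                 start = integer(0), end = integer(0),
                                 sample_id = character(0)))
  }
  list(catalog = catalog, reads = reads)
}

# --- Welch t-test closed form ----------------------------------------------

welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# --- exhaustive hypergeometric tail ----------------------------------------

# P(overlap >= k) when a module of size n is drawn uniformly from a
# universe of size N containing a fixed significant set of size s,
# by enumerating all C(N, n) possible modules.
enumerated_tail <- function(N, s, n, k) {
  draws <- combn(N, n)
  overlap <- colSums(draws <= s)   # significant set = elements 1..s
  mean(overlap >= k)
}

# --- greedy Ward (ward.D2) linkage oracle ----------------------------------

# Recomputes the Ward objective over the current dissimilarity state at
# every step via the Lance-Williams ward.D2 update on squared distances.
ward_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  members <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  merges <- list()
  cur <- d
  diag(cur) <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(cur == min(cur[active, active]), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    ij <- idx[order(idx[, 1], idx[, 2])[1], ]
    i <- ij[1]; j <- ij[2]
    merges[[step]] <- list(members = sort(c(members[[i]], members[[j]])),
                           height = cur[i, j])
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      newd2 <- ((ni + nk) * cur[i, k]^2 + (nj + nk) * cur[j, k]^2 -
                  nk * cur[i, j]^2) / (ni + nj + nk)
      cur[i, k] <- cur[k, i] <- sqrt(newd2)
    }
    sizes[i] <- ni + nj
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    active <- setdiff(active, j)
    cur[j, ] <- cur[, j] <- Inf
  }
  merges
}

hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  members <- list()
  lapply(seq_len(n - 1), function(step) {
    mm <- hc$merge[step, ]
    leaves <- unlist(lapply(mm, function(x)
      if (x < 0) -x else members[[x]]))
    members[[step]] <<- sort(leaves)
    list(members = sort(leaves), height = hc$height[step])
  })
}

# --- small synthetic study shared by several tests -------------------------

mini_modules <- function() {
  df <- data.frame(
    module_id = c("Msugar", "Mprot"),
    description = c("sugar transport (NP favoured)",
                    "amino acid transport (HP favoured)"),
    stringsAsFactors = FALSE)
  df$kos <- list(c("K11001", "K11002", "K11003"),
                 c("K12001", "K12002", "K12003", "K12004"))
  class(df) <- c("module_catalog", "data.frame")
  df
}

mini_truth <- function(fold = 4, seed = 1) {
  fr <- cbind(NPLF = c(0.5, 0.3, 0.2), NPHF = c(0.5, 0.3, 0.2),
              HPLF = c(0.3, 0.5, 0.2), HPHF = c(0.3, 0.5, 0.2))
  rownames(fr) <- c("FamA", "FamB", "FamC")
  planted <- data.frame(
    module_id = c("Msugar", "Mprot"),
    direction = c("NP-enriched", "HP-enriched"),
    fold_change = fold, stringsAsFactors = FALSE)
  community_truth(family_fractions = fr, planted_effects = planted,
                  modules = mini_modules(), seed = seed)
}

mini_ko_pool <- function() {
  c(unlist(mini_modules()$kos), "K00925", "K01895", "K00850",
    sprintf("K13%03d", 1:10))
}

mini_study <- function(seed = 1, dispersion = 0, depth = 1e5,
                       replicates = 2, fold = 4) {
  truth <- mini_truth(fold = fold, seed = seed)
  design <- study_design(replicates = replicates, seed = seed + 1)
  gen <- generate_catalog(truth$families, 40, mini_ko_pool(),
                          modules = mini_modules(), seed = seed + 2)
  expr <- simulate_expression(truth, design, gen$catalog, depth = depth,
                              dispersion = dispersion, seed = seed + 3)
  list(truth = truth, design = design, gen = gen, expr = expr,
       norm = normalize_per_sample(expr))
}

# --- RDA fixtures and direct linear-algebra oracle -------------------------

random_rda_instance <- function(seed, n = 8, p = 5, q = 2) {
  set.seed(seed)
  response <- matrix(rnorm(p * n), nrow = p,
                     dimnames = list(paste0("f", 1:p), paste0("s", 1:n)))
  explanatory <- as.data.frame(matrix(rnorm(n * q), nrow = n,
                                      dimnames = list(NULL, paste0("x", 1:q))))
  list(response = response, explanatory = explanatory)
}

# direct regression + eigendecomposition oracle, coded independently
rda_oracle <- function(response, explanatory) {
  # standardize numeric columns the way the implementation documents
  X <- apply(as.matrix(explanatory), 2, function(v) (v - mean(v)) / sd(v))
  Y <- scale(t(response), center = TRUE, scale = FALSE)
  B <- solve(crossprod(X), crossprod(X, Y))
  F <- X %*% B
  eig <- eigen(crossprod(F), symmetric = TRUE)$values
  eig <- eig[eig > 1e-12 * sum(Y^2)]
  list(constrained = sum(F^2) / sum(Y^2),
       axis_fractions = eig / sum(Y^2))
}

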