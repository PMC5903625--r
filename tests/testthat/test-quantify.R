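make_catalog <- function() {
  orf_catalog(data.frame(
    orf_id = c("orfA", "orfB", "orfC"),
    contig_id = c("ctg1", "ctg1", "ctg2"),
    start = c(100L, 400L, 0L),
    end = c(400L, 700L, 250L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE))
}

test_that("aligned nucleotides are counted by interval overlap", {
  cat3 <- make_catalog()
  reads <- alignment_records(data.frame(
    read_id = c("r1", "r2", "r3"),
    contig_id = c("ctg1", "ctg1", "ctg2"),
    start = c(150L, 360L, 10L),
    end = c(250L, 460L, 110L),
    sample_id = "s1", stringsAsFactors = FALSE))
  m <- count_aligned_nucleotides(reads, cat3)
  # r1 fully inside orfA; r2 spans the orfA/orfB boundary, 40 nt in orfA
  # and 60 nt in orfB; r3 fully inside orfC
  expect_equal(unname(m["orfA", "s1"]), 100 + 40)
  expect_equal(unname(m["orfB", "s1"]), 60)
  expect_equal(unname(m["orfC", "s1"]), 100)
})

test_that("no alignments still yields the full ORF x sample zero matrix", {
  empty <- alignment_records(data.frame(
    read_id = character(0), contig_id = character(0),
    start = integer(0), end = integer(0), sample_id = character(0)))
  m <- count_aligned_nucleotides(empty, make_catalog(),
                                 samples = c("s1", "s2"))
  expect_equal(dim(m), c(3L, 2L))
  expect_true(all(m == 0))
})

test_that("alignments to unknown contigs land in the unassigned bucket", {
  reads <- alignment_records(data.frame(
    read_id = c("r1", "r2"), contig_id = c("ctg1", "ctgX"),
    start = c(150L, 0L), end = c(200L, 80L), sample_id = "s1",
    stringsAsFactors = FALSE))
  expect_message(m <- count_aligned_nucleotides(reads, make_catalog()),
                 "unassigned")
  expect_equal(unname(m["orfA", "s1"]), 50)
  expect_equal(unname(attr(m, "unassigned")["s1"]), 80)
})

test_that("counting matches the per-base membership oracle and is order invariant", {
  for (seed in 1:25) {
    inst <- random_counting_instance(seed)
    got <- count_aligned_nucleotides(inst$reads, inst$catalog,
                                     samples = c("s1", "s2"))
    expect_equal(unclass(got)[, ], brute_force_count(inst$reads, inst$catalog,
                                                     c("s1", "s2")),
                 ignore_attr = TRUE)
    if (nrow(inst$reads) > 1) {
      perm <- inst$reads[sample(nrow(inst$reads)), , drop = FALSE]
      got2 <- count_aligned_nucleotides(alignment_records(perm), inst$catalog,
                                        samples = c("s2", "s1"))
      expect_equal(unclass(got2)[, c("s1", "s2")], unclass(got)[, ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("per-sample normalization scales by the sample total", {
  raw <- expression_matrix(
    matrix(c(300, 700, 0, 500), nrow = 2,
           dimnames = list(c("o1", "o2"), c("s1", "s2"))), "raw")
  norm <- normalize_per_sample(raw)
  expect_equal(unname(unclass(norm)[, "s1"]), c(0.3, 0.7))
  expect_equal(unname(unclass(norm)[, "s2"]), c(0, 1))
  expect_equal(unname(colSums(norm)), c(1, 1), tolerance = 1e-12)
})

test_that("an all-zero sample column is rejected by name", {
  raw <- expression_matrix(
    matrix(c(10, 5, 0, 0), nrow = 2,
           dimnames = list(c("o1", "o2"), c("ok", "empty_sample"))), "raw")
  expect_error(normalize_per_sample(raw), "empty_sample")
})

test_that("aggregation preserves column sums and routes unmapped ORFs to unassigned", {
  set.seed(42)
  vals <- matrix(runif(50 * 3), nrow = 50,
                 dimnames = list(paste0("o", 1:50), paste0("s", 1:3)))
  vals <- sweep(vals, 2, colSums(vals), "/")
  norm <- expression_matrix(vals, "normalized")
  grouping <- setNames(sample(paste0("g", 1:7), 40, replace = TRUE),
                       paste0("o", 1:40))  # last 10 ORFs unmapped
  agg <- aggregate_by(norm, grouping)
  expect_true("unassigned" %in% rownames(agg))
  expect_equal(unname(colSums(agg)), rep(1, 3), tolerance = 1e-12)
  # brute-force per-group summation oracle
  for (g in unique(grouping)) {
    member <- names(grouping)[grouping == g]
    expect_equal(agg[g, ], colSums(vals[member, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  one <- aggregate_by(norm, setNames(rep("all", 50), paste0("o", 1:50)))
  expect_equal(unname(one["all", ]), rep(1, 3), tolerance = 1e-12)
})

test_that("SAM input reproduces the TSV route, honouring CIGAR operations", {
  cat3 <- make_catalog()
  dir <- withr::local_tempdir()
  # 10M2I5M: 15 aligned nt; 5S10M2D8M: two blocks split by the deletion
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:ctg1\tLN:800",
    "@SQ\tSN:ctg2\tLN:250",
    "r1\t0\tctg1\t151\t255\t10M2I5M\t*\t0\t0\t*\t*",
    "r2\t0\tctg2\t11\t255\t5S10M2D8M\t*\t0\t0\t*\t*"),
    file.path(dir, "s1.sam"))
  rec <- read_alignments_sam(file.path(dir, "s1.sam"))
  expect_equal(nrow(rec), 3L)  # r1: 1 block, r2: 2 blocks
  m <- count_aligned_nucleotides(rec, cat3)
  expect_equal(unname(m["orfA", "s1"]), 15)
  expect_equal(unname(m["orfC", "s1"]), 18)

  # round trip through the SAM writer for single-block records
  reads <- alignment_records(data.frame(
    read_id = c("a", "b"), contig_id = c("ctg1", "ctg2"),
    start = c(120L, 5L), end = c(220L, 95L),
    sample_id = c("s1", "s1"), stringsAsFactors = FALSE))
  paths <- write_alignments_sam(reads, c(ctg1 = 800L, ctg2 = 250L),
                                file.path(dir, "sam_out"))
  back <- read_alignments_sam(paths)
  expect_equal(back[order(back$read_id), c("contig_id", "start", "end")],
               reads[order(reads$read_id), c("contig_id", "start", "end")],
               ignore_attr = TRUE)
})

test_that("optional per-kilobase mode divides by ORF length", {
  cat3 <- make_catalog()
  reads <- alignment_records(data.frame(
    read_id = "r1", contig_id = "ctg1", start = 150L, end = 250L,
    sample_id = "s1", stringsAsFactors = FALSE))
  m <- count_aligned_nucleotides(reads, cat3, per_kb = TRUE)
  expect_equal(unname(m["orfA", "s1"]), 100 / 0.3)
})

test_that("GFF3 round trip preserves coordinates and annotations", {
  cat3 <- make_catalog()
  cat3$family <- c("FamA", "FamB", NA)
  cat3$ko <- c("K00001", NA, "K00002")
  path <- withr::local_tempfile(fileext = ".gff3")
  write_orf_gff3(cat3, path)
  back <- read_orf_gff3(path)
  back <- back[match(cat3$orf_id, back$orf_id), ]
  expect_equal(back$start, cat3$start)
  expect_equal(back$end, cat3$end)
  expect_equal(back$family, cat3$family)
  expect_equal(back$ko, cat3$ko)
})
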