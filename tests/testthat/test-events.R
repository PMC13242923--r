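idx <- build_site_index(two_gene_models())

empty_rec <- function() splicecall::event_records(
  splicecall:::empty_junctions(), NULL, idx, "s")

test_that("junctions classify by the annotation status of their two sites", {
  j <- data.frame(
    chrom = "chr1",
    start = c(201L,  # catalog intron of gA
              201L,  # gA donor paired with gA's second acceptor: unpaired
              201L,  # annotated donor joined to an intronic position
              701L), # neither side annotated
    end = c(300L, 500L, 304L, 800L),
    strand = c("+", "+", "+", "."), stringsAsFactors = FALSE)
  expect_equal(classify_junction(j, idx),
               c("Annotated", "Plausible", "Anchored", "Unknown"))
})

test_that("a junction across two genes' annotated sites is Plausible", {
  j <- data.frame(chrom = "chr1", start = 201L, end = 1200L, strand = "+",
                  stringsAsFactors = FALSE)
  expect_equal(classify_junction(j, idx), "Plausible")
})

test_that("read-through splits into NoSplice at annotated, Trivial at novel sites", {
  s <- data.frame(chrom = "chr1", pos = c(201L, 250L, 1200L),
                  side = c("left", "left", "right"), stringsAsFactors = FALSE)
  expect_equal(classify_nosplice(s, idx), c("NoSplice", "Trivial", "NoSplice"))
})

test_that("every junction lands in exactly two site groups", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(3:12, 1L)
    j <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = sample(1000L, n), stringsAsFactors = FALSE)
    j$end <- j$start + sample(50:500, n, replace = TRUE)
    j$strand <- "."
    j$split_reads <- sample(1:50, n, replace = TRUE)
    j <- j[!duplicated(paste(j$chrom, j$start, j$end)), ]
    g <- build_site_groups(j, NULL)
    jid <- paste0("J:", j$chrom, ":", j$start, ":", j$end)
    counts <- table(g$alternative)[jid]
    expect_true(all(counts == 2L))
  }
})

test_that("PSI is the count over the site total, with no-splice competing", {
  j <- data.frame(chrom = "chr1", start = c(201L, 201L), end = c(300L, 500L),
                  strand = "+", split_reads = c(8L, 2L),
                  stringsAsFactors = FALSE)
  g <- compute_psi(build_site_groups(j, NULL))
  donor <- g[g$pos == 201L, ]
  expect_equal(donor$psi[donor$alternative == "J:chr1:201:300"], 0.8)
  expect_equal(donor$psi[donor$alternative == "J:chr1:201:500"], 0.2)

  ns <- data.frame(chrom = "chr1", pos = 201L, side = "left", depth = 2L,
                   stringsAsFactors = FALSE)
  j2 <- j[1L, ]
  g2 <- compute_psi(build_site_groups(j2, ns))
  donor2 <- g2[g2$pos == 201L, ]
  expect_equal(donor2$psi[donor2$alternative == "J:chr1:201:300"], 0.8)
  expect_equal(donor2$psi[startsWith(donor2$alternative, "NS:")], 0.2)
})

test_that("groups with zero total leave PSI undefined", {
  ns <- data.frame(chrom = "chr1", pos = c(201L, 300L), side = c("left", "right"),
                   depth = 0L, stringsAsFactors = FALSE)
  j <- data.frame(chrom = "chr1", start = 201L, end = 300L, strand = "+",
                  split_reads = 0L, stringsAsFactors = FALSE)
  g <- compute_psi(build_site_groups(j, ns))
  expect_true(all(is.na(g$psi)))
})

test_that("PSI sums to one in every group with evidence", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:10, 1L)
    j <- data.frame(chrom = "chr1", start = sample(500L, n),
                    stringsAsFactors = FALSE)
    j$end <- j$start + sample(20:200, n, replace = TRUE)
    j$strand <- "."
    j$split_reads <- sample(0:30, n, replace = TRUE)
    j <- j[!duplicated(paste(j$start, j$end)), ]
    ns <- data.frame(chrom = "chr1", pos = sample(500L, 3L),
                     side = sample(c("left", "right"), 3L, replace = TRUE),
                     depth = sample(0:10, 3L, replace = TRUE),
                     stringsAsFactors = FALSE)
    g <- compute_psi(build_site_groups(j, ns))
    sums <- tapply(g$psi, g$group, sum)
    tots <- tapply(g$total, g$group, max)
    expect_true(all(abs(sums[tots > 0] - 1) < 1e-9))
    expect_true(all(is.na(sums[tots == 0])))
  }
})

test_that("event records carry dual PSI and per-side gene annotation", {
  j <- data.frame(chrom = "chr1", start = 201L, end = 300L, strand = "+",
                  split_reads = 10L, n_sense = 0L, n_antisense = 0L,
                  n_unknown = 10L, shift_applied = 0L, stringsAsFactors = FALSE)
  ns <- data.frame(chrom = "chr1", pos = c(201L, 300L),
                   side = c("left", "right"), depth = c(5L, 0L),
                   stringsAsFactors = FALSE)
  rec <- event_records(j, ns, idx, sample_id = "s1")
  jr <- rec[is.na(rec$side), ]
  expect_equal(jr$class, "Annotated")
  expect_equal(jr$psi_left, 10 / 15)
  expect_equal(jr$psi_right, 1)
  expect_equal(jr$genes_left, "gA")
  expect_equal(jr$nosplice_left, 5L)
  nsr <- rec[!is.na(rec$side) & rec$start == 201L, ]
  expect_equal(nsr$class, "NoSplice")
  expect_equal(nsr$psi_left, 5 / 15)
})

test_that("junctions joining disjoint gene sets become fusion candidates", {
  j <- data.frame(chrom = "chr1", start = c(201L, 201L), end = c(1200L, 300L),
                  strand = "+", split_reads = c(12L, 30L), n_sense = 0L,
                  n_antisense = 0L, n_unknown = 0L, shift_applied = 0L,
                  stringsAsFactors = FALSE)
  rec <- event_records(j, NULL, idx, "s1")
  fus <- call_fusions(rec, idx)
  expect_equal(nrow(fus), 1L)
  expect_equal(fus$genes_a, "gA")
  expect_equal(fus$genes_b, "gB")
  expect_equal(fus$evidence, 12L)
  expect_equal(fus$source, "gap")
})

test_that("chimeric rows pass through with read-count evidence", {
  tsv <- tempfile(fileext = ".tsv")
  write_chimeric_table(data.frame(chrom_a = "chr1", pos_a = 500L,
                                  strand_a = "+", chrom_b = "chr2",
                                  pos_b = 900L, strand_b = "-",
                                  n_reads = 7L), tsv)
  fus <- call_fusions(empty_rec(), idx, chimeric = tsv)
  expect_equal(nrow(fus), 1L)
  expect_equal(fus$evidence, 7L)
  expect_false(fus$same_chrom)
})

test_that("nearby same-chromosome chimeric rows are not fusions; malformed rows warn", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t+\tchr1\t5000\t+\tx\tx\tx\tr1",
               "chr1\t100\t+\tchr2\t5000\t+\tx\tx\tx\tr2",
               "garbage line without tabs"), tsv)
  expect_warning(ch <- read_chimeric(tsv), "malformed")
  fus <- call_fusions(empty_rec(), idx, chimeric = ch)
  expect_equal(nrow(fus), 1L)
  expect_equal(fus$chrom_b, "chr2")
})

test_that("an annotation-only fixture yields only Annotated junctions, and a
           perturbed acceptor flips to Anchored", {
  ref <- make_reference(seed = 9, n_genes = 3, exons_per_gene = 4)
  sim <- simulate_alignments(ref, NULL, depth = 25, seed = 10)
  calls <- call_junctions(sim$sam, ref$gtf, ref$fasta, tier = "none")
  jr <- calls$records[is.na(calls$records$side), ]
  expect_gt(nrow(jr), 0L)
  expect_true(all(jr$class == "Annotated"))
  # no read-through anywhere on a fully spliced fixture
  nsr <- calls$records[!is.na(calls$records$side), ]
  expect_true(all(nsr$split_reads == 0L))

  ridx <- build_site_index(ref$models)
  perturbed <- jr[1L, c("chrom", "start", "end", "strand")]
  perturbed$end <- perturbed$end + 4L
  expect_equal(classify_junction(perturbed, ridx), "Anchored")
})

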