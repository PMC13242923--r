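test_that("reference generation is deterministic and writes valid motifs", {
  d1 <- tempfile("r1"); d2 <- tempfile("r2")
  r1 <- make_reference(seed = 1, n_genes = 3, exons_per_gene = 4,
                       out_dir = d1)
  r2 <- make_reference(seed = 1, n_genes = 3, exons_per_gene = 4,
                       out_dir = d2)
  expect_identical(readLines(r1$fasta), readLines(r2$fasta))
  expect_identical(readLines(r1$gtf), readLines(r2$gtf))
  expect_equal(length(readLines(r1$gtf)), 12L)  # 3 genes x 4 exons

  sq <- r1$genome[[1L]]
  intr <- transcript_introns(r1$models)
  for (i in seq_len(nrow(intr))) {
    m <- paste0(as.character(Biostrings::subseq(sq, intr$start[i],
                                                intr$start[i] + 1L)),
                as.character(Biostrings::subseq(sq, intr$end[i] - 1L,
                                                intr$end[i])))
    expect_true(m == if (intr$strand[i] == "+") "GTAG" else "CTAC")
  }
  expect_error(make_reference(seed = 1, n_genes = 10, chrom_len = 1000L),
               "layout")
})

test_that("planted event fraction follows the class probabilities", {
  # plant over a large synthetic gene set (annotation only, no genome needed)
  ng <- 4000L
  ex <- do.call(rbind, lapply(seq_len(ng), function(g) {
    base <- (g - 1L) * 2000L
    data.frame(chrom = "chrV", start = base + c(1L, 301L, 601L, 901L),
               end = base + c(200L, 500L, 800L, 1100L), strand = "+",
               transcript_id = paste0("t", g), gene_id = paste0("g", g),
               stringsAsFactors = FALSE)
  }))
  ref <- list(exons = as_models(ex))
  truth <- plant_events(ref, seed = 17)
  frac <- mean(truth$event_type != "none")
  p <- 0.625
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / ng))
  # all five event classes drawn, roughly evenly
  tab <- table(truth$event_type)
  expect_setequal(names(tab), c("exon_skip", "multi_exon_skip",
                                "intron_retention", "alt5", "alt3", "none"))
  # alternative-site events never land on the annotated boundary
  alt <- truth[truth$event_type %in% c("alt5", "alt3"), ]
  intr <- transcript_introns(ref$exons)
  ikey <- paste(intr$start, intr$end)
  expect_false(any(paste(alt$start, alt$end) %in% ikey))
})

test_that("probability extremes behave: all-none plants nothing", {
  ref <- make_reference(seed = 2, n_genes = 4)
  truth <- plant_events(ref, seed = 3,
                        event_probs = c(exon_skip = 0, multi_exon_skip = 0,
                                        intron_retention = 0, alt5 = 0,
                                        alt3 = 0, none = 1))
  expect_true(all(truth$event_type == "none"))
})

test_that("simulated SAM is deterministic and its gaps match transcript paths", {
  ref <- make_reference(seed = 4, n_genes = 4, exons_per_gene = 4)
  truth <- plant_events(ref, seed = 5,
                        event_probs = c(exon_skip = .3, multi_exon_skip = .2,
                                        intron_retention = .2, alt5 = .15,
                                        alt3 = .15, none = 0))
  s1 <- simulate_alignments(ref, truth, depth = 20, seed = 6,
                            out_sam = tempfile(fileext = ".sam"))
  s2 <- simulate_alignments(ref, truth, depth = 20, seed = 6,
                            out_sam = tempfile(fileext = ".sam"))
  expect_identical(readLines(s1$sam), readLines(s2$sam))

  # independent CIGAR walk: every emitted gap must be an annotated intron,
  # a planted junction, or a boundary-modified intron of a planted alt event
  lines <- readLines(s1$sam)
  body <- lines[!startsWith(lines, "@")]
  f <- strsplit(body, "\t", fixed = TRUE)
  gaps <- character(0)
  for (r in f) {
    pos <- as.integer(r[4L])
    ops <- regmatches(r[6L], gregexpr("[0-9]+[MIDNSHP=X]", r[6L]))[[1L]]
    at <- pos
    for (op in ops) {
      n <- as.integer(sub(".$", "", op)); o <- sub("^[0-9]+", "", op)
      if (o == "N") gaps <- c(gaps, paste(at, at + n - 1L))
      if (o %in% c("M", "D", "N", "=", "X")) at <- at + n
    }
  }
  intr <- transcript_introns(ref$models)
  legal <- c(paste(intr$start, intr$end),
             paste(truth$start, truth$end))
  # skips remove whole introns+exons: the flanking annotated introns remain;
  # alt events modify one boundary -> their coordinates are in `truth`
  expect_true(all(unique(gaps) %in% legal))

  # all CIGARs consume a reference span that stays inside the chromosome
  ends <- vapply(seq_along(f), function(i) {
    pos <- as.integer(f[[i]][4L])
    ops <- regmatches(f[[i]][6L], gregexpr("[0-9]+[MDN=X]", f[[i]][6L]))[[1L]]
    pos + sum(as.integer(sub(".$", "", ops))) - 1L
  }, integer(1))
  expect_true(all(ends <= Biostrings::width(ref$genome)))
})

test_that("an event with true PSI 1 silences the canonical junction", {
  ref <- make_reference(seed = 7, n_genes = 1, exons_per_gene = 3)
  ge <- as.data.frame(ref$exons)
  truth <- data.frame(gene_id = "g001", event_type = "exon_skip",
                      chrom = "chrS", start = ge$end[1L] + 1L,
                      end = ge$start[3L] - 1L, strand = "+", true_psi = 1,
                      stringsAsFactors = FALSE)
  sim <- simulate_alignments(ref, truth, depth = 50, seed = 8)
  j <- extract_gaps(sim$sam, evidence_config())
  canonical <- transcript_introns(ref$models)
  expect_false(any(paste(j$start, j$end) %in%
                     paste(canonical$start, canonical$end)))
})

test_that("scorer: perfect calls, near-matches and deletions behave arithmetically", {
  ref <- make_reference(seed = 9, n_genes = 8, exons_per_gene = 5)
  truth <- plant_events(ref, seed = 10,
                        event_probs = c(exon_skip = .5, multi_exon_skip = 0,
                                        intron_retention = .5, alt5 = 0,
                                        alt3 = 0, none = 0))
  sim <- simulate_alignments(ref, truth, depth = 50, seed = 11)
  calls <- call_junctions(sim$sam, ref$gtf, ref$fasta, tier = "none")
  sc <- score_calls(calls$records, sim$truth)
  supported <- sim$truth$support >= 10L
  expect_true(all(sc$matches$status[supported] != "miss"))
  det <- sc$matches[sc$matches$status != "miss", ]
  expect_true(all(det$status == "exact"))

  # shifting one called skip by 4 bp turns exact into near
  rec2 <- calls$records
  es <- sim$truth[sim$truth$event_type == "exon_skip" & supported, ][1L, ]
  i <- which(is.na(rec2$side) & rec2$start == es$start & rec2$end == es$end)
  rec2$start[i] <- rec2$start[i] + 4L
  rec2$end[i] <- rec2$end[i] + 4L
  sc2 <- score_calls(rec2, sim$truth)
  m2 <- sc2$matches[sc2$matches$gene_id == es$gene_id, ]
  expect_equal(m2$status, "near")
  expect_equal(m2$delta, 4L)

  # deleting k detected junction events lowers recall by exactly k/N
  es_all <- sim$truth$event_type == "exon_skip" & supported
  k <- min(2L, sum(es_all))
  drop <- sim$truth[which(es_all)[seq_len(k)], ]
  rec3 <- calls$records[!(is.na(calls$records$side) &
                            calls$records$start %in% drop$start &
                            calls$records$end %in% drop$end), ]
  sc3 <- score_calls(rec3, sim$truth)
  n_es <- sum(sim$truth$event_type == "exon_skip")
  r_before <- sc$recall$recall_detected[sc$recall$event_type == "exon_skip"]
  r_after <- sc3$recall$recall_detected[sc3$recall$event_type == "exon_skip"]
  expect_equal(r_before - r_after, k / n_es)

  # scorer is symmetric under permutation of either table
  set.seed(12)
  perm <- score_calls(calls$records[sample(nrow(calls$records)), ],
                      sim$truth[sample(nrow(sim$truth)), ])
  expect_equal(sort(perm$matches$status), sort(sc$matches$status))
  expect_equal(perm$precision$spurious, sc$precision$spurious)
})

test_that("no spurious calls arise on an event-free fixture at tier sensitive", {
  ref <- make_reference(seed = 19, n_genes = 5, exons_per_gene = 4)
  sim <- simulate_alignments(ref, NULL, depth = 40, seed = 20)
  calls <- call_junctions(sim$sam, ref$gtf, ref$fasta, tier = "sensitive")
  expect_equal(nrow(calls$filtered), 0L)
  empty_truth <- data.frame(gene_id = character(0), event_type = character(0),
                            chrom = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            true_psi = numeric(0), stringsAsFactors = FALSE)
  sc <- score_calls(calls$filtered, empty_truth)
  expect_equal(sc$precision$called, 0L)
})
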