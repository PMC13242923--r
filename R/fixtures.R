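# Synthetic fixtures: toy genome + annotation, planted splicing events,
# simulated paired alignments, and truth-based scoring with the <=10 bp
# near-match rule.

#' Generate a toy reference genome and annotation
#'
#' Builds a random-base chromosome carrying `n_genes` multi-exon genes on
#' alternating strands, writes canonical GT-AG (CT-AC on -) motifs at every
#' annotated intron boundary, and emits FASTA + GTF files. Deterministic for
#' a given seed.
#'
#' @param seed Integer seed fixing the random stream.
#' @param n_genes,exons_per_gene,exon_len,intron_len Layout sizes (bases).
#' @param intergenic Spacer between genes (bases).
#' @param chrom Chromosome name.
#' @param chrom_len Optional fixed chromosome length; an error is raised if
#'   the gene layout does not fit.
#' @param out_dir Directory for the FASTA/GTF files (created if needed).
#' @return list of class `splice_fixture_ref`: `genome` (`DNAStringSet`),
#'   `exons` (annotation table), `models`, `fasta`, `gtf`, and the layout
#'   parameters.
#' @export
make_reference <- function(seed, n_genes = 10L, exons_per_gene = 4L,
                           exon_len = 150L, intron_len = 200L,
                           intergenic = 400L, chrom = "chrS",
                           chrom_len = NULL, out_dir = tempfile("ref")) {
  stopifnot(n_genes >= 1L, exons_per_gene >= 1L, exon_len >= 10L,
            intron_len >= 10L)
  gene_len <- exons_per_gene * exon_len + (exons_per_gene - 1L) * intron_len
  need <- n_genes * (gene_len + intergenic) + intergenic
  if (is.null(chrom_len)) chrom_len <- need
  if (chrom_len < need)
    stop("gene layout needs ", need, " bases but chrom_len is ", chrom_len)
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    ex <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
      gstart <- intergenic + (g - 1L) * (gene_len + intergenic) + 1L
      starts <- gstart + (seq_len(exons_per_gene) - 1L) * (exon_len + intron_len)
      data.frame(chrom = chrom, start = starts, end = starts + exon_len - 1L,
                 strand = if (g %% 2L == 1L) "+" else "-",
                 transcript_id = sprintf("t%03d", g),
                 gene_id = sprintf("g%03d", g),
                 gene_name = sprintf("GENE%03d", g), stringsAsFactors = FALSE)
    }))
    class(ex) <- c("transcript_models", "data.frame")
    intr <- transcript_introns(ex)
    for (i in seq_len(nrow(intr))) {
      s <- intr$start[i]; e <- intr$end[i]
      if (intr$strand[i] == "+") {
        bases[c(s, s + 1L, e - 1L, e)] <- c("G", "T", "A", "G")
      } else {
        bases[c(s, s + 1L, e - 1L, e)] <- c("C", "T", "A", "C")
      }
    }
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- chrom
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(out_dir, "genome.fa")
    gtf <- file.path(out_dir, "annotation.gtf")
    Biostrings::writeXStringSet(genome, fasta)
    gtf_lines <- sprintf(
      '%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
      ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
      ex$gene_name)
    writeLines(gtf_lines, gtf)
    structure(list(genome = genome, exons = ex, models = ex, fasta = fasta,
                   gtf = gtf, chrom = chrom, n_genes = n_genes,
                   exons_per_gene = exons_per_gene, exon_len = exon_len,
                   intron_len = intron_len),
              class = "splice_fixture_ref")
  })
}

EVENT_TYPES <- c("exon_skip", "multi_exon_skip", "intron_retention",
                 "alt5", "alt3", "none")

#' Plant splicing events into fixture genes
#'
#' Draws at most one event per gene from the class distribution used
#' throughout the package's benchmarks — exon skipping, multiple-exon
#' skipping, intron retention, alternative 5' and 3' splice sites at 12.5%
#' each and no event at 37.5% — together with a true PSI drawn from
#' `psi_range`. Alternative-site events shift one annotated boundary into
#' the intron by an offset drawn from `alt_offset_range`, so the shifted
#' boundary never lands on the original one. Genes too short for a drawn
#' event type are re-drawn among feasible types (logged via `message`).
#'
#' @param ref A [make_reference()] fixture.
#' @param seed Integer seed.
#' @param event_probs Named probabilities over
#'   `exon_skip, multi_exon_skip, intron_retention, alt5, alt3, none`;
#'   must sum to 1.
#' @param psi_range True-PSI range (uniform draw).
#' @param alt_offset_range Boundary-offset range for alt5/alt3 (bases).
#' @return data.frame of truth events: `gene_id`, `event_type`, `chrom`,
#'   `start`, `end` (event junction, or retained intron for retention),
#'   `strand`, `true_psi`.
#' @export
plant_events <- function(ref, seed,
                         event_probs = c(exon_skip = 0.125,
                                         multi_exon_skip = 0.125,
                                         intron_retention = 0.125,
                                         alt5 = 0.125, alt3 = 0.125,
                                         none = 0.375),
                         psi_range = c(0.2, 0.8),
                         alt_offset_range = c(4L, 20L)) {
  stopifnot(all(names(event_probs) %in% EVENT_TYPES),
            abs(sum(event_probs) - 1) < 1e-9)
  ex <- as.data.frame(ref$exons)
  with_seed(seed, {
    rows <- lapply(unique(ex$gene_id), function(g) {
      ge <- ex[ex$gene_id == g, , drop = FALSE]
      ge <- ge[order(ge$start), , drop = FALSE]
      n <- nrow(ge)
      type <- sample(names(event_probs), 1L, prob = event_probs)
      feasible <- function(t) switch(
        t, exon_skip = n >= 3L, multi_exon_skip = n >= 4L,
        intron_retention = n >= 2L, alt5 = n >= 2L, alt3 = n >= 2L,
        none = TRUE)
      if (!feasible(type)) {
        ok <- names(event_probs)[vapply(names(event_probs), feasible,
                                        logical(1))]
        message("gene ", g, " too short for ", type, "; redrawing")
        type <- sample(ok, 1L, prob = event_probs[ok])
      }
      psi <- stats::runif(1L, psi_range[1L], psi_range[2L])
      strand <- ge$strand[1L]
      coords <- switch(
        type,
        none = c(NA_integer_, NA_integer_),
        exon_skip = {
          i <- if (n == 3L) 2L else sample(2:(n - 1L), 1L)
          c(ge$end[i - 1L] + 1L, ge$start[i + 1L] - 1L)
        },
        multi_exon_skip = {
          k <- if (n == 4L) 2L else sample(2:(n - 2L), 1L)  # run length
          i <- if (n - k == 2L) 2L else sample(2:(n - k), 1L)  # first skipped
          c(ge$end[i - 1L] + 1L, ge$start[i + k] - 1L)
        },
        intron_retention = {
          j <- if (n == 2L) 1L else sample(seq_len(n - 1L), 1L)
          c(ge$end[j] + 1L, ge$start[j + 1L] - 1L)
        },
        alt5 = ,
        alt3 = {
          j <- if (n == 2L) 1L else sample(seq_len(n - 1L), 1L)
          s0 <- ge$end[j] + 1L; e0 <- ge$start[j + 1L] - 1L
          d <- sample(seq.int(alt_offset_range[1L], alt_offset_range[2L]), 1L)
          donor_left <- (strand == "+") == (type == "alt5")
          if (donor_left) c(s0 + d, e0) else c(s0, e0 - d)
        })
      data.frame(gene_id = g, event_type = type, chrom = ge$chrom[1L],
                 start = coords[1L], end = coords[2L], strand = strand,
                 true_psi = if (type == "none") NA_real_ else psi,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Plant readthrough gene-fusion junctions
#'
#' Picks `n` gene pairs (upstream, downstream on the same chromosome) and
#' joins an annotated donor site of the first to an annotated acceptor site
#' of the second, giving a junction with disjoint gene sets.
#'
#' @param ref A [make_reference()] fixture.
#' @param seed Integer seed.
#' @param n Number of fusion junctions.
#' @param n_reads Split reads to emit per fusion.
#' @return Truth rows with `event_type = "fusion"` (columns as
#'   [plant_events()], plus `n_reads`).
#' @export
plant_fusions <- function(ref, seed, n = 1L, n_reads = 20L) {
  ex <- as.data.frame(ref$exons)
  genes <- unique(ex$gene_id)
  if (length(genes) < 2L) stop("need at least two genes to plant a fusion")
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      pair <- sort(sample(seq_along(genes), 2L))
      ga <- ex[ex$gene_id == genes[pair[1L]], , drop = FALSE]
      gb <- ex[ex$gene_id == genes[pair[2L]], , drop = FALSE]
      s <- ga$end[nrow(ga) - 1L] + 1L   # donor: start of A's last intron
      e <- gb$start[2L] - 1L            # acceptor: end of B's first intron
      data.frame(gene_id = paste(genes[pair[1L]], genes[pair[2L]], sep = "-"),
                 event_type = "fusion", chrom = ga$chrom[1L], start = s,
                 end = e, strand = ".", true_psi = 1, n_reads = n_reads,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Apply a splice junction (s,e) to an exon chain: trim the flanking exons to
# the junction and drop exons inside it. Covers skips and alt-site events.
apply_junction <- function(blocks, s, e) {
  left <- blocks[blocks$start < s, , drop = FALSE]
  right <- blocks[blocks$end > e, , drop = FALSE]
  if (nrow(left) == 0L || nrow(right) == 0L)
    stop("junction does not fit inside the gene")
  left$end[nrow(left)] <- s - 1L
  right$start[1L] <- e + 1L
  rbind(left, right)
}

# Merge the blocks flanking a retained intron (s,e) into one.
apply_retention <- function(blocks, s, e) {
  i <- which(blocks$end == s - 1L)
  j <- which(blocks$start == e + 1L)
  if (length(i) != 1L || length(j) != 1L || j != i + 1L)
    stop("retained intron does not match the exon chain")
  blocks$end[i] <- blocks$end[j]
  blocks[-j, , drop = FALSE]
}

# Map a transcript-coordinate interval onto genomic blocks -> CIGAR + pos.
tx_to_cigar <- function(blocks, tx_start, tx_end) {
  w <- blocks$end - blocks$start + 1L
  cum <- cumsum(w)
  first <- which(tx_start <= cum)[1L]
  last <- which(tx_end <= cum)[1L]
  prev <- c(0L, cum)[seq_len(nrow(blocks))]
  segs <- lapply(first:last, function(b) {
    gs <- blocks$start[b] + max(tx_start - prev[b] - 1L, 0L)
    ge <- blocks$start[b] + min(tx_end - prev[b], w[b]) - 1L
    c(gs, ge)
  })
  gs <- as.integer(vapply(segs, `[`, numeric(1), 1L))
  ge <- as.integer(vapply(segs, `[`, numeric(1), 2L))
  ops <- sprintf("%dM", ge - gs + 1L)
  if (length(gs) > 1L) {
    gaps <- sprintf("%dN", gs[-1L] - ge[-length(ge)] - 1L)
    cig <- paste0(paste0(ops[-length(ops)], gaps, collapse = ""),
                  ops[length(ops)])
  } else cig <- ops
  list(pos = gs[1L], cigar = cig, segs_start = gs, segs_end = ge)
}

#' Simulate paired spliced alignments over a fixture
#'
#' Emits coordinate-sorted SAM records for every gene: canonical-isoform and
#' event-isoform fragments mixed at each gene's true PSI, with spliced reads
#' carrying N over introns, retention reads carrying M through the retained
#' intron, and fusion truths emitted as single-end split reads across the
#' fusion junction. The returned truth table gains a `support` column
#' counting, per event, the emitted reads that directly evidence it (reads
#' containing the event gap, or covering a read-through probe base for
#' retention).
#'
#' @param ref A [make_reference()] fixture.
#' @param truth Truth table from [plant_events()] (optionally rbind-ed with
#'   [plant_fusions()] rows); `NULL` simulates annotation-only data.
#' @param depth Target per-gene coverage (x).
#' @param read_len,frag_len Read and fragment lengths (bases).
#' @param seed Integer seed.
#' @param strandedness Protocol used to set mate orientation flags.
#' @param nosplice_offset Probe offset used when counting retention support.
#' @param sample_id Read-name prefix.
#' @param out_sam Output SAM path.
#' @return list: `sam` (path), `truth` (with `support`), `n_records`.
#' @export
simulate_alignments <- function(ref, truth = NULL, depth = 60L,
                                read_len = 100L, frag_len = 250L, seed = 1L,
                                strandedness = c("unstranded", "forward",
                                                 "reverse"),
                                nosplice_offset = 3L, sample_id = "S1",
                                out_sam = tempfile(fileext = ".sam")) {
  strandedness <- match.arg(strandedness)
  ex <- as.data.frame(ref$exons)
  if (is.null(truth))
    truth <- data.frame(gene_id = character(0), event_type = character(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        true_psi = numeric(0), stringsAsFactors = FALSE)
  truth$support <- rep(0L, nrow(truth))
  recs <- new.env(parent = emptyenv()); recs$lines <- vector("list", 2048L)
  recs$n <- 0L
  push <- function(v) {
    if (recs$n + length(v) > length(recs$lines))
      length(recs$lines) <- 2L * (recs$n + length(v))
    recs$lines[recs$n + seq_along(v)] <- v
    recs$n <- recs$n + length(v)
  }
  with_seed(seed, {
    for (g in unique(ex$gene_id)) {
      ge <- ex[ex$gene_id == g, c("start", "end"), drop = FALSE]
      ge <- ge[order(ge$start), , drop = FALSE]
      strand <- ex$strand[ex$gene_id == g][1L]
      chrom <- ex$chrom[ex$gene_id == g][1L]
      ti <- which(truth$gene_id == g &
                    !truth$event_type %in% c("none", "fusion"))
      ev <- if (length(ti) == 1L) truth[ti, ] else NULL
      blocks_e <- NULL
      if (!is.null(ev)) {
        blocks_e <- if (ev$event_type == "intron_retention")
          apply_retention(ge, ev$start, ev$end)
        else apply_junction(ge, ev$start, ev$end)
      }
      txlen_c <- sum(ge$end - ge$start + 1L)
      n_frag <- max(1L, as.integer(round(depth * txlen_c / (2 * read_len))))
      # isoform choice weighted by fragment start positions so that the
      # planted PSI is realized as the junction-evidence fraction at the
      # shared site (unweighted per-fragment draws would bias PSI when the
      # two isoforms differ in length)
      p_event <- 0
      if (!is.null(ev)) {
        txlen_e <- sum(blocks_e$end - blocks_e$start + 1L)
        ns_c <- txlen_c - min(frag_len, txlen_c) + 1L
        ns_e <- txlen_e - min(frag_len, txlen_e) + 1L
        p_event <- ev$true_psi * ns_e /
          (ev$true_psi * ns_e + (1 - ev$true_psi) * ns_c)
      }
      use_event <- stats::runif(n_frag) < p_event
      support <- 0L
      for (f in seq_len(n_frag)) {
        blocks <- if (use_event[f]) blocks_e else ge
        txlen <- sum(blocks$end - blocks$start + 1L)
        fl <- min(frag_len, txlen)
        rl <- min(read_len, fl)
        st <- sample.int(txlen - fl + 1L, 1L)
        r1 <- tx_to_cigar(blocks, st, st + rl - 1L)
        r2 <- tx_to_cigar(blocks, st + fl - rl, st + fl - 1L)
        r1fwd <- switch(strandedness,
                        unstranded = stats::runif(1L) < 0.5,
                        forward = strand == "+",
                        reverse = strand == "-")
        fl1 <- if (r1fwd) c(99L, 147L) else c(83L, 163L)
        qn <- sprintf("%s_%s_f%06d", sample_id, g, f)
        tl <- max(r1$segs_end[length(r1$segs_end)], r2$segs_end[length(r2$segs_end)]) -
          min(r1$pos, r2$pos) + 1L
        push(c(
          sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*", qn, fl1[1L],
                  chrom, r1$pos, r1$cigar, r2$pos, tl),
          sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*", qn, fl1[2L],
                  chrom, r2$pos, r2$cigar, r1$pos, -tl)))
        if (!is.null(ev)) {
          support <- support + count_support(ev, r1, nosplice_offset) +
            count_support(ev, r2, nosplice_offset)
        }
      }
      if (!is.null(ev)) truth$support[ti] <- support
    }
    fi <- which(truth$event_type == "fusion")
    for (i in fi) {
      tr <- truth[i, ]
      nr <- if (!is.null(tr$n_reads)) tr$n_reads else 20L
      anchor <- max(20L, read_len %/% 2L)
      for (k in seq_len(nr)) {
        a <- anchor + sample.int(20L, 1L) - 10L
        pos <- tr$start - a
        cig <- sprintf("%dM%dN%dM", a, tr$end - tr$start + 1L, read_len - a)
        qn <- sprintf("%s_fus%02d_r%04d", sample_id, i, k)
        push(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*", qn, tr$chrom,
                     pos, cig))
      }
      truth$support[i] <- nr
    }
  })
  body <- unlist(recs$lines[seq_len(recs$n)], use.names = FALSE)
  pos <- as.integer(vapply(strsplit(body, "\t", fixed = TRUE), `[`,
                           character(1), 4L))
  chr <- vapply(strsplit(body, "\t", fixed = TRUE), `[`, character(1), 3L)
  body <- body[order(chr, pos)]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome),
                      Biostrings::width(ref$genome)))
  writeLines(c(header, body), out_sam)
  list(sam = out_sam, truth = truth, n_records = length(body))
}

# Does one simulated read evidence its gene's event?
count_support <- function(ev, read, offset) {
  if (ev$event_type == "intron_retention") {
    probes <- c(ev$start + offset - 1L, ev$end - offset + 1L)
    covered <- any(probes >= read$segs_start[1L] &
                     probes <= read$segs_end[length(read$segs_end)] &
                     vapply(probes, function(p)
                       any(p >= read$segs_start & p <= read$segs_end),
                       logical(1)))
    as.integer(covered)
  } else {
    n <- length(read$segs_start)
    if (n < 2L) return(0L)
    hit <- any(read$segs_end[-n] == ev$start - 1L &
                 read$segs_start[-1L] == ev$end + 1L)
    as.integer(hit)
  }
}

#' Write a STAR-dialect chimeric junction table
#'
#' One row per supporting read, columns 1-6 holding the two breakpoints.
#'
#' @param pairs data.frame with `chrom_a`, `pos_a`, `strand_a`, `chrom_b`,
#'   `pos_b`, `strand_b`, `n_reads`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_chimeric_table <- function(pairs, path) {
  lines <- unlist(lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    sprintf("%s\t%d\t%s\t%s\t%d\t%s\t0\t0\t0\tchim%02d_r%04d\t%d\t100M\t%d\t100M",
            p$chrom_a, p$pos_a, p$strand_a, p$chrom_b, p$pos_b, p$strand_b,
            i, seq_len(p$n_reads), p$pos_a, p$pos_b)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Score caller output against fixture truth
#'
#' Junction-type truths (skips, alternative sites, fusions) match junction
#' rows: exact when both intron ends agree, near when every end is within
#' `tolerance` (default 10 bp). Retention truths match read-through rows of
#' class `NoSplice` at either flanking site. Reportable called rows matched
#' by no truth are spurious. The scorer is symmetric under permutation of
#' either list.
#'
#' @param records Event table (typically the unfiltered or tier-filtered
#'   output).
#' @param truth Truth table from the fixture generator.
#' @param tolerance Near-match tolerance in bases.
#' @return list: `matches` (truth rows + `status` in
#'   exact/near/miss, `delta`), `recall` (per event type), `precision`
#'   (overall), `spurious` (unmatched reportable rows).
#' @export
score_calls <- function(records, truth, tolerance = 10L) {
  truth <- truth[truth$event_type != "none", , drop = FALSE]
  jr <- records[is.na(records$side), , drop = FALSE]
  nsr <- records[!is.na(records$side) & records$class == "NoSplice", ,
                 drop = FALSE]
  status <- character(nrow(truth)); delta <- rep(NA_integer_, nrow(truth))
  j_matched <- rep(FALSE, nrow(jr)); ns_matched <- rep(FALSE, nrow(nsr))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (tr$event_type == "intron_retention") {
      cand <- which(nsr$chrom == tr$chrom)
      d <- ifelse(nsr$side[cand] == "left", abs(nsr$start[cand] - tr$start),
                  abs(nsr$start[cand] - tr$end))
      hit <- cand[d <= tolerance]
      ns_matched[hit] <- TRUE
      delta[i] <- if (length(d)) suppressWarnings(min(d)) else NA_integer_
    } else {
      cand <- which(jr$chrom == tr$chrom)
      d <- pmax(abs(jr$start[cand] - tr$start), abs(jr$end[cand] - tr$end))
      hit <- cand[d <= tolerance]
      j_matched[hit] <- TRUE
      delta[i] <- if (length(d)) suppressWarnings(min(d)) else NA_integer_
      # read-through at a boundary displaced by the event is a consequence
      # of the truth, not a spurious call: absorb nearby no-splice rows
      nd <- which(nsr$chrom == tr$chrom &
                    (abs(nsr$start - tr$start) <= tolerance |
                       abs(nsr$start - tr$end) <= tolerance))
      ns_matched[nd] <- TRUE
    }
    status[i] <- if (is.na(delta[i]) || delta[i] > tolerance) "miss"
      else if (delta[i] == 0L) "exact" else "near"
  }
  matches <- cbind(truth, status = status, delta = delta)
  recall <- do.call(rbind, lapply(split(matches, matches$event_type),
                                  function(m) data.frame(
    event_type = m$event_type[1L], n = nrow(m),
    exact = sum(m$status == "exact"), near = sum(m$status == "near"),
    recall_exact = mean(m$status == "exact"),
    recall_detected = mean(m$status != "miss"),
    stringsAsFactors = FALSE)))
  rownames(recall) <- NULL
  reportable <- c("Plausible", "Anchored", "Unknown")
  spur_j <- jr[!j_matched & jr$class %in% reportable, , drop = FALSE]
  spur_ns <- nsr[!ns_matched & nsr$split_reads > 0L, , drop = FALSE]
  spurious <- rbind(spur_j, spur_ns)
  n_called <- sum(jr$class %in% reportable) + sum(nsr$split_reads > 0L)
  n_matched <- n_called - nrow(spurious)
  precision <- data.frame(called = n_called, matched = n_matched,
                          spurious = nrow(spurious),
                          precision = if (n_called > 0L) n_matched / n_called
                            else NA_real_)
  list(matches = matches, recall = recall, precision = precision,
       spurious = spurious)
}
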