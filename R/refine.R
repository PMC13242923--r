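# Placement-ambiguity detection and shifting of novel junctions toward
# annotated splice sites.
#
# Ambiguity is defined purely on the reference sequence, as for indel
# left-alignment: sliding the gap by k leaves the implied aligned sequence
# (left flank + right flank concatenation) unchanged, so all reads of a
# junction shift together.

#' Shift equivalence range of a junction
#'
#' Computes how far a gap (intron) can slide left/right while the implied
#' aligned sequence is unchanged: `max_right` is the largest k with
#' `genome[s .. s+k-1] == genome[e+1 .. e+k]` for intron (s, e); `max_left`
#' is symmetric. Direct base comparison, stopping at the first mismatch, a
#' chromosome edge, or `max_shift`.
#'
#' @param genome Genome (path or `DNAStringSet`).
#' @param chrom,start,end Junction intron interval (1-based inclusive).
#' @param max_shift Scan cap, guarding against pathological repeats.
#' @return list with integers `max_left`, `max_right`.
#' @export
shift_range <- function(genome, chrom, start, end, max_shift = 100L) {
  genome <- load_genome(genome)
  sq <- genome_seq(genome, chrom)
  L <- length(sq)
  if (start < 1L || end > L || start > end)
    stop("junction ", chrom, ":", start, "-", end, " outside genome bounds")
  s <- as.character(sq)
  base <- function(i) substr(s, i, i)
  max_right <- 0L
  while (max_right < max_shift) {
    k <- max_right + 1L
    if (end + k > L) break
    if (base(start + k - 1L) != base(end + k)) break
    max_right <- k
  }
  max_left <- 0L
  while (max_left < max_shift) {
    k <- max_left + 1L
    if (start - k < 1L) break
    if (base(start - k) != base(end - k + 1L)) break
    max_left <- k
  }
  list(max_left = max_left, max_right = max_right)
}

# Canonical splice motif test on the junction's strand; with unknown strand
# both GT-AG and CT-AC count as canonical.
canonical_motif <- function(genome_chr_seq, start, end, strand) {
  if (end - start + 1L < 4L || start < 1L || end > length(genome_chr_seq))
    return(FALSE)
  m <- paste0(as.character(Biostrings::subseq(genome_chr_seq, start, start + 1L)),
              as.character(Biostrings::subseq(genome_chr_seq, end - 1L, end)))
  if (strand == "+") m == "GTAG"
  else if (strand == "-") m == "CTAC"
  else m %in% c("GTAG", "CTAC")
}

#' Realign one junction within its shift-equivalence range
#'
#' Among all sequence-equivalent placements, chooses the one maximizing, in
#' order: (a) the number of its two sites present in the splice-site index,
#' (b) membership of the full junction in the annotated catalog, (c) a
#' canonical GT-AG intron motif, (d) the smallest absolute shift, (e) the
#' leftmost placement. A junction whose two sites are already annotated is
#' returned unchanged.
#'
#' @param junction list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome Genome (path or `DNAStringSet`).
#' @param index A [build_site_index()] object.
#' @param max_shift Scan cap passed to [shift_range()].
#' @return The junction with possibly shifted `start`/`end` and the applied
#'   shift recorded in `shift_applied`.
#' @export
realign_junction <- function(junction, genome, index, max_shift = 100L) {
  genome <- load_genome(genome)
  j <- as.list(junction)
  j$shift_applied <- 0L
  hit0 <- site_annotated(index, j$chrom, j$start, "left", j$strand) +
    site_annotated(index, j$chrom, j$end, "right", j$strand)
  if (hit0 == 2L) return(j)
  rng <- shift_range(genome, j$chrom, j$start, j$end, max_shift)
  ks <- seq.int(-rng$max_left, rng$max_right)
  if (length(ks) == 1L) return(j)
  sq <- genome_seq(genome, j$chrom)
  score <- vapply(ks, function(k) {
    s <- j$start + k; e <- j$end + k
    a <- site_annotated(index, j$chrom, s, "left", j$strand) +
      site_annotated(index, j$chrom, e, "right", j$strand)
    b <- junction_in_catalog(index, j$chrom, s, e, j$strand)
    cc <- canonical_motif(sq, s, e, j$strand)
    c(a, as.integer(b), as.integer(cc), -abs(k), -k)
  }, numeric(5))
  best <- ks[order(-score[1L, ], -score[2L, ], -score[3L, ],
                   -score[4L, ], -score[5L, ])][1L]
  j$start <- j$start + best
  j$end <- j$end + best
  j$shift_applied <- as.integer(best)
  j
}

#' Realign a junction table and merge colliding keys
#'
#' Applies [realign_junction()] to every row; when shifting makes two
#' junction keys collide their evidence counts are summed (the recorded
#' shift is that of the best-supported component). Strands left unknown are
#' re-tested against the canonical motif at the final placement.
#'
#' @param junctions Junction table as produced by [extract_gaps()].
#' @inheritParams realign_junction
#' @return A junction table of the same shape, position-sorted.
#' @export
realign_junctions <- function(junctions, genome, index, max_shift = 100L) {
  if (nrow(junctions) == 0L) return(junctions)
  genome <- load_genome(genome)
  shifted <- junctions
  for (i in seq_len(nrow(junctions))) {
    r <- realign_junction(junctions[i, , drop = FALSE], genome, index,
                          max_shift)
    shifted$start[i] <- r$start
    shifted$end[i] <- r$end
    shifted$shift_applied[i] <- r$shift_applied
  }
  key <- paste(junction_key(shifted$chrom, shifted$start, shifted$end),
               shifted$strand, sep = ":")
  if (anyDuplicated(key)) {
    agg <- function(v, f) as.vector(tapply(v, key, f))
    ord <- !duplicated(key)
    main <- vapply(split(seq_len(nrow(shifted)), key), function(ii)
      ii[which.max(shifted$split_reads[ii])], integer(1))
    merged <- shifted[ord, , drop = FALSE]
    ukey <- key[ord]
    sums <- function(col) as.integer(
      tapply(shifted[[col]], key, sum)[ukey])
    merged$split_reads <- sums("split_reads")
    merged$n_sense <- sums("n_sense")
    merged$n_antisense <- sums("n_antisense")
    merged$n_unknown <- sums("n_unknown")
    merged$shift_applied <- shifted$shift_applied[main[ukey]]
    shifted <- merged
  }
  dot <- shifted$strand == "."
  if (any(dot)) shifted$strand[dot] <- rescue_strand(shifted[dot, , drop = FALSE],
                                                     genome)
  shifted <- shifted[order(shifted$chrom, shifted$start, shifted$end), ,
                     drop = FALSE]
  rownames(shifted) <- NULL
  shifted
}
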