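# Evidence collection: split-read junction observations and site-adjacent
# depth (the no-splice alternative) from deduplicated alignments.

#' Evidence-collection configuration
#'
#' @param strandedness Library protocol: `"unstranded"`, `"forward"` (FR:
#'   read 1 carries the transcript orientation) or `"reverse"` (RF).
#' @param min_mapq Minimum mapping quality; records below are skipped.
#' @param min_anchor Minimum reference-aligned bases flanking a gap on each
#'   side for the gap to be counted as a junction observation.
#' @param count_secondary Count secondary alignments (default drop).
#' @param nosplice_offset Probe offset for read-through depth: the k-th base
#'   inside the putative intron is interrogated (default 3, i.e. 3 bases
#'   inside the intron).
#' @param count_fragments When `TRUE`, the two mates of a pair observing the
#'   same gap count once (per-fragment counting); default counts reads.
#' @return A list of class `evidence_config`.
#' @export
evidence_config <- function(strandedness = c("unstranded", "forward", "reverse"),
                            min_mapq = 0L, min_anchor = 5L,
                            count_secondary = FALSE, nosplice_offset = 3L,
                            count_fragments = FALSE) {
  strandedness <- match.arg(strandedness)
  stopifnot(min_anchor >= 1L, nosplice_offset >= 1L, min_mapq >= 0L)
  structure(list(strandedness = strandedness, min_mapq = as.integer(min_mapq),
                 min_anchor = as.integer(min_anchor),
                 count_secondary = isTRUE(count_secondary),
                 nosplice_offset = as.integer(nosplice_offset),
                 count_fragments = isTRUE(count_fragments)),
            class = "evidence_config")
}

#' Read alignments from SAM or BAM
#'
#' SAM text input is converted with the bundled htslib; unmapped records are
#' never returned. The result keeps the fields the caller needs (flag, mapq,
#' read name).
#'
#' @param path SAM or BAM file path, or an existing `GAlignments` object
#'   (returned unchanged).
#' @return A [GenomicAlignments::GAlignments] with metadata columns `flag`,
#'   `mapq` and `qname`.
#' @export
read_alignments <- function(path) {
  if (is(path, "GAlignments")) return(path)
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = c("flag", "mapq", "qname"))
  GenomicAlignments::readGAlignments(bam, param = param)
}

# Apply record-level retention rules shared by gap extraction and depth
# measurement: mapq, duplicate and (optionally) secondary flags.
retain_records <- function(aln, config) {
  flag <- S4Vectors::mcols(aln)$flag
  mapq <- S4Vectors::mcols(aln)$mapq
  keep <- bitwAnd(flag, 1024L) == 0L           # duplicate-flagged: defensive skip
  if (!config$count_secondary) keep <- keep & bitwAnd(flag, 256L) == 0L
  mq_ok <- is.na(mapq) | mapq >= config$min_mapq
  aln[keep & mq_ok]
}

#' Infer read orientation relative to the + strand template
#'
#' Deterministic truth table over the paired / first-in-pair / reverse flag
#' bits. `"sense"` means the record implies a transcript on the + strand,
#' `"antisense"` the - strand; unstranded protocols always give `"unknown"`.
#' Unpaired reads are treated as first-in-pair.
#'
#' @param flags Integer vector of SAM flags.
#' @param config An [evidence_config()].
#' @return Character vector in `{"sense","antisense","unknown"}`.
#' @export
infer_orientation <- function(flags, config) {
  if (config$strandedness == "unstranded")
    return(rep("unknown", length(flags)))
  paired <- bitwAnd(flags, 1L) > 0L
  rev <- bitwAnd(flags, 16L) > 0L
  second <- bitwAnd(flags, 128L) > 0L
  r1 <- !paired | !second
  # forward (FR): read1 aligned forward reads the transcript strand
  sense <- xor(r1, rev)
  if (config$strandedness == "reverse") sense <- !sense
  ifelse(sense, "sense", "antisense")
}

#' Extract junction observations from gapped alignments
#'
#' Every N CIGAR operation of a retained record contributes one observation
#' to the junction keyed by (chrom, first skipped base, last skipped base).
#' Gaps flanked by fewer than `min_anchor` reference-aligned bases on either
#' side are not counted. Junction strand is assigned by majority read-pair
#' orientation when the protocol is stranded, and rescued from the canonical
#' GT-AG / CT-AC intron motif when unknown and a genome is supplied.
#'
#' @param aln SAM/BAM path or `GAlignments` (see [read_alignments()]).
#' @param config An [evidence_config()].
#' @param genome Optional genome (path or `DNAStringSet`) for motif-based
#'   strand rescue.
#' @return data.frame with columns `chrom`, `start`, `end` (intron, 1-based
#'   inclusive), `strand`, `split_reads`, `n_sense`, `n_antisense`,
#'   `n_unknown`, `shift_applied` (0 at this stage), sorted by position.
#' @export
extract_gaps <- function(aln, config = evidence_config(), genome = NULL) {
  aln <- retain_records(read_alignments(aln), config)
  if (!is.null(genome)) {
    genome <- load_genome(genome)
    unknown <- setdiff(unique(as.character(GenomicAlignments::seqnames(aln))),
                       names(genome))
    if (length(unknown))
      stop("unknown reference name(s) in alignments: ",
           paste(unknown, collapse = ", "))
  }
  if (length(aln) == 0L) return(empty_junctions())
  # Reference blocks per read, split at N only (D stays inside a block), so
  # consecutive blocks are separated exactly by the splice gaps.
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(aln), pos = GenomicRanges::start(aln),
    ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  nb <- S4Vectors::elementNROWS(blocks)
  has_gap <- nb > 1L
  if (!any(has_gap)) return(empty_junctions())
  aln <- aln[has_gap]; blocks <- blocks[has_gap]; nb <- nb[has_gap]
  ubl <- unlist(blocks, use.names = FALSE)
  read_of <- rep(seq_along(blocks), nb)
  first_of_read <- c(TRUE, read_of[-1L] != read_of[-length(read_of)])
  # gap g sits between block i-1 and block i (i not first of its read)
  gi <- which(!first_of_read)
  gap_start <- IRanges::end(ubl)[gi - 1L] + 1L
  gap_end <- IRanges::start(ubl)[gi] - 1L
  anchor_l <- IRanges::width(ubl)[gi - 1L]
  anchor_r <- IRanges::width(ubl)[gi]
  read_idx <- read_of[gi]
  ok <- anchor_l >= config$min_anchor & anchor_r >= config$min_anchor
  if (!any(ok)) return(empty_junctions())
  gap_start <- gap_start[ok]; gap_end <- gap_end[ok]; read_idx <- read_idx[ok]
  chrom <- as.character(GenomicAlignments::seqnames(aln))[read_idx]
  orient <- infer_orientation(S4Vectors::mcols(aln)$flag, config)[read_idx]
  obs <- data.frame(chrom = chrom, start = gap_start, end = gap_end,
                    orient = orient, stringsAsFactors = FALSE)
  if (config$count_fragments) {
    qn <- S4Vectors::mcols(aln)$qname[read_idx]
    obs <- obs[!duplicated(paste(qn, chrom, gap_start, gap_end)), ,
               drop = FALSE]
  }
  key <- junction_key(obs$chrom, obs$start, obs$end)
  tab <- obs[!duplicated(key), c("chrom", "start", "end"), drop = FALSE]
  ktab <- key[!duplicated(key)]
  cnt <- function(o) as.integer(table(factor(key[obs$orient == o],
                                             levels = ktab)))
  tab$split_reads <- as.integer(table(factor(key, levels = ktab)))
  tab$n_sense <- cnt("sense")
  tab$n_antisense <- cnt("antisense")
  tab$n_unknown <- cnt("unknown")
  tab$strand <- ifelse(tab$n_sense > tab$n_antisense, "+",
                       ifelse(tab$n_antisense > tab$n_sense, "-", "."))
  if (!is.null(genome))
    tab$strand <- rescue_strand(tab, genome)
  tab$shift_applied <- 0L
  tab <- tab[order(tab$chrom, tab$start, tab$end),
             c("chrom", "start", "end", "strand", "split_reads", "n_sense",
               "n_antisense", "n_unknown", "shift_applied")]
  rownames(tab) <- NULL
  tab
}

# GT-AG (=> +) / CT-AC (=> -) intron-motif strand rescue for '.' junctions.
rescue_strand <- function(tab, genome) {
  strand <- tab$strand
  for (i in which(strand == ".")) {
    sq <- genome_seq(genome, tab$chrom[i])
    if (tab$start[i] < 1L || tab$end[i] + 0L > length(sq)) next
    if (tab$end[i] - tab$start[i] + 1L < 4L) next
    m <- paste0(as.character(Biostrings::subseq(sq, tab$start[i], tab$start[i] + 1L)),
                as.character(Biostrings::subseq(sq, tab$end[i] - 1L, tab$end[i])))
    if (m == "GTAG") strand[i] <- "+"
    else if (m == "CTAC") strand[i] <- "-"
  }
  strand
}

#' Measure read-through depth inside putative introns
#'
#' For each splice site, counts retained reads whose alignment covers the
#' probe base — the `nosplice_offset`-th base inside the putative intron
#' (site position + offset - 1 for a left site, - offset + 1 for a right
#' site) — with a reference-consuming match state (M/=/X). Reads spliced (N)
#' or deleted (D) over the probe base do not count. This is the no-splice
#' alternative used in PSI denominators.
#'
#' @param aln SAM/BAM path or `GAlignments`.
#' @param sites data.frame with columns `chrom`, `pos`, `side`
#'   (`"left"`/`"right"`), one row per site.
#' @param config An [evidence_config()].
#' @return The `sites` table with added columns `probe` and `depth`.
#' @export
measure_depth_inside <- function(aln, sites, config = evidence_config()) {
  stopifnot(all(c("chrom", "pos", "side") %in% names(sites)))
  sites <- as.data.frame(sites)
  off <- config$nosplice_offset
  sites$probe <- ifelse(sites$side == "left", sites$pos + off - 1L,
                        sites$pos - off + 1L)
  sites$depth <- 0L
  if (nrow(sites) == 0L) return(sites)
  oob <- sites$probe < 1L
  if (any(oob))
    warning(sum(oob), " probe base(s) fall outside chromosome bounds; ",
            "depth reported as 0")
  aln <- retain_records(read_alignments(aln), config)
  if (length(aln) == 0L) return(sites)
  cov <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(aln), pos = GenomicRanges::start(aln),
    ops = c("M", "=", "X"), reduce.ranges = TRUE)
  n <- S4Vectors::elementNROWS(cov)
  covgr <- GenomicRanges::GRanges(
    rep(as.character(GenomicAlignments::seqnames(aln)), n),
    unlist(cov, use.names = FALSE))
  inb <- !oob
  probes <- GenomicRanges::GRanges(
    sites$chrom[inb], IRanges::IRanges(sites$probe[inb], width = 1L))
  suppressWarnings(
    sites$depth[inb] <- GenomicRanges::countOverlaps(probes, covgr))
  sites
}
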