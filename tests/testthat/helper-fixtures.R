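# Shared helpers: tiny SAM/GTF writers and independent oracles used to
# cross-check the package's own parsing.

write_sam <- function(records, sqs = c(chr1 = 5000L),
                      path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sqs), sqs))
  writeLines(c(header, records), path)
  path
}

sam_rec <- function(qname = "r1", flag = 0L, chrom = "chr1", pos = 1L,
                    mapq = 60L, cigar = "100M", rnext = "*", pnext = 0L,
                    tlen = 0L) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*",
          qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen)
}

write_gtf <- function(ex, path = tempfile(fileext = ".gtf")) {
  gn <- if (is.null(ex$gene_name)) ""
    else sprintf(' gene_name "%s";', ex$gene_name)
  writeLines(sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    gn), path)
  path
}

# exon table -> transcript_models object without going through a file
as_models <- function(ex) {
  if (is.null(ex$gene_name)) ex$gene_name <- ex$gene_id
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  class(ex) <- c("transcript_models", "data.frame")
  ex
}

# two-gene annotation used across classification tests:
#   gA (+): exons 101-200, 301-400, 501-600 -> introns 201-300, 401-500
#   gB (+): exons 1001-1100, 1201-1300      -> intron 1101-1200
two_gene_models <- function() {
  as_models(data.frame(
    chrom = "chr1",
    start = c(101L, 301L, 501L, 1001L, 1201L),
    end = c(200L, 400L, 600L, 1100L, 1300L),
    strand = "+",
    transcript_id = c("tA", "tA", "tA", "tB", "tB"),
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    stringsAsFactors = FALSE))
}

# independent N-operation counter over raw SAM text (conservation oracle)
count_n_ops <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  cigars <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 6L)
  sum(vapply(cigars, function(cg)
    length(gregexpr("[0-9]+N", cg)[[1L]][gregexpr("[0-9]+N", cg)[[1L]] > 0]),
    numeric(1)))
}

# brute-force shift-equivalence oracle: slide the gap k bases and compare
# the concatenated flanking sequence strings
bf_shift_range <- function(seqchar, s, e, max_shift = 100L) {
  L <- nchar(seqchar)
  spliced <- function(s2, e2)
    paste0(substr(seqchar, 1L, s2 - 1L), substr(seqchar, e2 + 1L, L))
  ref <- spliced(s, e)
  mr <- 0L
  for (k in seq_len(max_shift)) {
    if (e + k > L || spliced(s + k, e + k) != ref) break
    mr <- k
  }
  ml <- 0L
  for (k in seq_len(max_shift)) {
    if (s - k < 1L || spliced(s - k, e - k) != ref) break
    ml <- k
  }
  list(max_left = ml, max_right = mr)
}

random_genome <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# annotated-site hits of a junction's two ends (any strand)
site_hits <- function(idx, chrom, s, e)
  c(splicecall:::site_annotated(idx, chrom, s, "left", "."),
    splicecall:::site_annotated(idx, chrom, e, "right", "."))

as_dnass <- function(seqchar, chrom = "chr1") {
  g <- Biostrings::DNAStringSet(seqchar)
  names(g) <- chrom
  g
}
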