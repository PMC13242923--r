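# Annotation parsing: transcript models, splice-site index, junction catalog.
#
# Coordinate convention: junctions are stored as 1-based inclusive intron
# intervals (first intronic base, last intronic base), the same convention as
# STAR's SJ.out.tab. The "left" site of a junction is its first intronic base,
# the "right" site its last; which one is the donor depends on the strand.

#' Load transcript models from a GTF annotation
#'
#' Parses `exon` features of a GTF/GFF2 file (gzip-transparent) into a
#' per-transcript exon table. Non-exon features are ignored. `gene_name`
#' falls back to `gene_id` when absent.
#'
#' @param path Path to a GTF file, or a `GRanges` of exon features carrying
#'   `gene_id` and `transcript_id` metadata columns.
#' @return A data.frame of class `transcript_models` with columns `chrom`,
#'   `start`, `end`, `strand`, `transcript_id`, `gene_id`, `gene_name`,
#'   exons sorted by start within transcript.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\ttoy\texon", c("101\t200", "301\t400"),
#'   "\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";"), gtf)
#' models <- load_annotation(gtf)
#' transcript_introns(models)
#' @export
load_annotation <- function(path) {
  if (is(path, "GRanges")) {
    gr <- path
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "gtf"),
      error = function(e) {
        diagnose_gtf(path)       # raises a line-naming error when it can
        stop("malformed annotation: ", conditionMessage(e))
      })
  }
  gr <- gr[as.character(gr$type) == "exon"]
  if (length(gr) == 0L)
    stop("annotation contains no exon features")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id))
    stop("exon features must carry gene_id and transcript_id attributes")
  gene_name <- if (!is.null(md$gene_name)) as.character(md$gene_name) else NA_character_
  gene_name <- ifelse(is.na(gene_name), as.character(md$gene_id), gene_name)
  ex <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    gene_name = gene_name,
    stringsAsFactors = FALSE)
  ex <- ex[order(ex$transcript_id, ex$start, ex$end), , drop = FALSE]
  rownames(ex) <- NULL
  validate_models(ex)
  class(ex) <- c("transcript_models", "data.frame")
  ex
}

# Best-effort scan of a raw GTF to name the first malformed line.
diagnose_gtf <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character(0))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) next
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (!is.na(s) && !is.na(e) && e < s)
      stop("malformed annotation at line ", i, ": end (", e,
           ") < start (", s, ")")
  }
  invisible(NULL)
}

validate_models <- function(ex) {
  bad <- ex$end < ex$start
  if (any(bad))
    stop("malformed annotation: exon with end < start (",
         ex$chrom[bad][1L], ":", ex$start[bad][1L], "-", ex$end[bad][1L], ")")
  by_tx <- split(seq_len(nrow(ex)), ex$transcript_id)
  for (idx in by_tx) {
    if (length(unique(ex$chrom[idx])) > 1L)
      stop("transcript '", ex$transcript_id[idx][1L],
           "' spans multiple chromosomes")
    if (length(unique(ex$strand[idx])) > 1L)
      stop("transcript '", ex$transcript_id[idx][1L],
           "' mixes strands")
    if (length(idx) > 1L) {
      s <- ex$start[idx]; e <- ex$end[idx]
      if (any(s[-1L] <= e[-length(e)]))
        stop("transcript '", ex$transcript_id[idx][1L],
             "' has overlapping or abutting exons (introns must have length >= 1)")
    }
  }
  invisible(ex)
}

#' Intron intervals of each transcript
#'
#' @param models A `transcript_models` table from [load_annotation()].
#' @return data.frame with one row per intron: `chrom`, `start`, `end`
#'   (1-based inclusive intron interval), `strand`, `transcript_id`,
#'   `gene_id`.
#' @export
transcript_introns <- function(models) {
  ex <- as.data.frame(models)
  out <- lapply(split(ex, ex$transcript_id), function(t) {
    n <- nrow(t)
    if (n < 2L) return(NULL)
    data.frame(chrom = t$chrom[-n], start = t$end[-n] + 1L,
               end = t$start[-1L] - 1L, strand = t$strand[-n],
               transcript_id = t$transcript_id[-n], gene_id = t$gene_id[-n],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      transcript_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the splice-site index and annotated-junction catalog
#'
#' Every annotated intron (s, e) contributes one left site (its first base s)
#' and one right site (its last base e) to the index, and the junction
#' (chrom, s, e, strand) to the catalog. Duplicates across transcripts
#' collapse; each site maps to the set of gene_ids whose transcripts use it.
#'
#' @param models A `transcript_models` table.
#' @return An object of class `splice_site_index` with elements `sites`
#'   (data.frame chrom/pos/side/strand), `catalog` (data.frame
#'   chrom/start/end/strand) and internal lookup tables.
#' @export
build_site_index <- function(models) {
  intr <- transcript_introns(models)
  sites <- rbind(
    data.frame(chrom = intr$chrom, pos = intr$start, side = "left",
               strand = intr$strand, gene_id = intr$gene_id,
               stringsAsFactors = FALSE),
    data.frame(chrom = intr$chrom, pos = intr$end, side = "right",
               strand = intr$strand, gene_id = intr$gene_id,
               stringsAsFactors = FALSE))
  site_tab <- unique(sites[c("chrom", "pos", "side", "strand")])
  rownames(site_tab) <- NULL
  cat_tab <- unique(data.frame(chrom = intr$chrom, start = intr$start,
                               end = intr$end, strand = intr$strand,
                               stringsAsFactors = FALSE))
  rownames(cat_tab) <- NULL
  gkey <- site_key(sites$chrom, sites$pos, sites$side)
  genes <- lapply(split(sites$gene_id, gkey), function(g) sort(unique(g)))
  idx <- list(
    sites = site_tab,
    catalog = cat_tab,
    site_keys = paste(site_key(site_tab$chrom, site_tab$pos, site_tab$side),
                      site_tab$strand, sep = ":"),
    catalog_keys = paste(junction_key(cat_tab$chrom, cat_tab$start, cat_tab$end),
                         cat_tab$strand, sep = ":"),
    genes_by_site = genes)
  class(idx) <- "splice_site_index"
  idx
}

#' @export
print.splice_site_index <- function(x, ...) {
  cat("splice_site_index:", nrow(x$sites), "sites,",
      nrow(x$catalog), "annotated junctions\n")
  invisible(x)
}

# Vectorized membership of (chrom,pos,side) in the index; a junction with
# unknown strand ('.') matches sites on either strand.
site_annotated <- function(index, chrom, pos, side, strand = ".") {
  strand <- rep_len(strand, length(chrom))
  base <- site_key(chrom, pos, side)
  stranded <- paste(base, strand, sep = ":")
  hit <- stranded %in% index$site_keys
  dot <- strand == "."
  if (any(dot)) {
    hit[dot] <- paste(base[dot], "+", sep = ":") %in% index$site_keys |
      paste(base[dot], "-", sep = ":") %in% index$site_keys
  }
  hit
}

junction_in_catalog <- function(index, chrom, start, end, strand = ".") {
  strand <- rep_len(strand, length(chrom))
  base <- junction_key(chrom, start, end)
  hit <- paste(base, strand, sep = ":") %in% index$catalog_keys
  dot <- strand == "."
  if (any(dot)) {
    hit[dot] <- paste(base[dot], "+", sep = ":") %in% index$catalog_keys |
      paste(base[dot], "-", sep = ":") %in% index$catalog_keys
  }
  hit
}

# Gene ids annotated at a site (any strand), empty character if none.
site_genes <- function(index, chrom, pos, side) {
  g <- index$genes_by_site[[site_key(chrom, pos, side)]]
  if (is.null(g)) character(0) else g
}
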