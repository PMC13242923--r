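# Internal helpers shared across modules.

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

site_key <- function(chrom, pos, side) paste(chrom, pos, side, sep = ":")

junction_key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")

collapse_genes <- function(x) {
  if (length(x) == 0L) return("")
  paste(sort(unique(x)), collapse = ",")
}

split_genes <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1L]]
}

#' Load a reference genome as a DNAStringSet
#'
#' Accepts a FASTA path (gzip-transparent) or an existing
#' [Biostrings::DNAStringSet] and returns a `DNAStringSet` named by sequence.
#'
#' @param x FASTA file path or `DNAStringSet`.
#' @return A `DNAStringSet` keyed by chromosome name.
#' @export
load_genome <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    g <- Biostrings::readDNAStringSet(x)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  stop("genome must be a FASTA path or a DNAStringSet")
}

genome_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in the genome")
  genome[[chrom]]
}

# Empty junction table with the canonical column set.
empty_junctions <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), split_reads = integer(0),
             n_sense = integer(0), n_antisense = integer(0),
             n_unknown = integer(0), shift_applied = integer(0),
             stringsAsFactors = FALSE)
}
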