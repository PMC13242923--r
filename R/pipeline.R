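# End-to-end caller: alignments + annotation + genome -> classified,
# PSI-annotated junction tables, fusion candidates and tier filtering.

#' Call splicing events from aligned reads
#'
#' Runs the full analysis: junction evidence extraction from gapped
#' alignments, realignment of novel junctions toward annotated splice sites,
#' read-through depth measurement at every annotated and discovered splice
#' site, classification, dual-PSI computation, fusion candidate calling and
#' tier filtering.
#'
#' @param alignments SAM/BAM path(s) or a `GAlignments` object (deduplicated
#'   upstream; duplicate-flagged records are skipped defensively).
#' @param annotation GTF path or `transcript_models`.
#' @param genome FASTA path or `DNAStringSet`.
#' @param chimeric Optional STAR-style chimeric junction table (path or
#'   data.frame) for inter-chromosomal fusion evidence.
#' @param config An [evidence_config()].
#' @param tier Filter tier name or [filter_tier()] object.
#' @param sample_id Sample label.
#' @param out_prefix When given, filtered/unfiltered TSVs are written via
#'   [write_tables()].
#' @param max_shift Realignment scan cap (bases).
#' @param fusion_max_dist Same-chromosome chimeric distance threshold.
#' @param verbose Log per-stage counters to stderr.
#' @return list of class `splice_calls`: `records` (unfiltered event table),
#'   `filtered`, `fusions`, `junctions` (refined junction table), `groups`
#'   (PSI site groups), `counters`.
#' @examples
#' ref <- make_reference(seed = 1, n_genes = 2)
#' sim <- simulate_alignments(ref, truth = NULL, depth = 20, seed = 1)
#' calls <- call_junctions(sim$sam, ref$gtf, ref$fasta, tier = "sensitive")
#' head(calls$records)
#' @export
call_junctions <- function(alignments, annotation, genome, chimeric = NULL,
                           config = evidence_config(), tier = "sensitive",
                           sample_id = "sample", out_prefix = NULL,
                           max_shift = 100L, fusion_max_dist = 1e6,
                           verbose = FALSE) {
  log_ <- function(...) if (verbose) message("[splicecall] ", ...)
  models <- if (inherits(annotation, "transcript_models")) annotation
    else load_annotation(annotation)
  index <- build_site_index(models)
  genome <- load_genome(genome)
  log_("annotation: ", nrow(index$sites), " sites, ", nrow(index$catalog),
       " annotated junctions")
  aln <- if (is.character(alignments) && length(alignments) > 1L) {
    do.call(c, lapply(alignments, read_alignments))
  } else read_alignments(alignments)
  log_("alignments: ", length(aln), " records")
  junctions <- extract_gaps(aln, config, genome = genome)
  log_("evidence: ", nrow(junctions), " distinct junctions, ",
       sum(junctions$split_reads), " observations")
  junctions <- realign_junctions(junctions, genome, index, max_shift)
  n_shifted <- sum(junctions$shift_applied != 0L)
  log_("refine: ", n_shifted, " junction(s) shifted")
  sites <- unique(rbind(
    index$sites[c("chrom", "pos", "side")],
    data.frame(chrom = junctions$chrom, pos = junctions$start, side = "left",
               stringsAsFactors = FALSE),
    data.frame(chrom = junctions$chrom, pos = junctions$end, side = "right",
               stringsAsFactors = FALSE)))
  nosplice <- measure_depth_inside(aln, sites, config)
  log_("no-splice: ", sum(nosplice$depth > 0L), " site(s) with read-through")
  records <- event_records(junctions, nosplice, index, sample_id)
  groups <- compute_psi(build_site_groups(junctions, nosplice))
  fusions <- call_fusions(records, index, chimeric, fusion_max_dist)
  log_("events: ", nrow(records), " records, ", nrow(fusions),
       " fusion candidate(s)")
  filtered <- apply_filter(records, tier)
  log_("filter '", filter_tier(tier)$name, "': ", nrow(filtered),
       " record(s) kept")
  if (!is.null(out_prefix)) write_tables(filtered, records, out_prefix)
  structure(list(records = records, filtered = filtered, fusions = fusions,
                 junctions = junctions, groups = groups,
                 counters = c(alignments = length(aln),
                              junctions = nrow(junctions),
                              shifted = n_shifted,
                              records = nrow(records),
                              filtered = nrow(filtered),
                              fusions = nrow(fusions))),
            class = "splice_calls")
}

#' @export
print.splice_calls <- function(x, ...) {
  cat("splice_calls:", x$counters[["junctions"]], "junctions,",
      x$counters[["records"]], "records (", x$counters[["filtered"]],
      "filtered ),", x$counters[["fusions"]], "fusion candidate(s)\n")
  invisible(x)
}
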