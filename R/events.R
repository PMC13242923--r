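# Junction classification, per-site alternative groups, PSI computation and
# fusion candidate calling.
#
# Classes:
#   Annotated — both sites annotated and at least one transcript holds the
#               junction; Plausible — both sites annotated but no transcript
#               pairs them; Anchored — exactly one site annotated;
#               Unknown — neither site annotated.
#   NoSplice  — read-through (absence of splice) at an annotated site;
#   Trivial   — read-through at a de novo site (inside an annotated intron
#               or exon).

JUNCTION_CLASSES <- c("Annotated", "Plausible", "Anchored", "Unknown")
NOSPLICE_CLASSES <- c("NoSplice", "Trivial")

#' Classify junctions by splice-site annotation status
#'
#' @param junctions data.frame with `chrom`, `start`, `end`, `strand`.
#' @param index A [build_site_index()] object.
#' @return Character vector: `Annotated`, `Plausible`, `Anchored` or
#'   `Unknown` per row.
#' @export
classify_junction <- function(junctions, index) {
  if (nrow(junctions) == 0L) return(character(0))
  l <- site_annotated(index, junctions$chrom, junctions$start, "left",
                      junctions$strand)
  r <- site_annotated(index, junctions$chrom, junctions$end, "right",
                      junctions$strand)
  incat <- junction_in_catalog(index, junctions$chrom, junctions$start,
                               junctions$end, junctions$strand)
  ifelse(l & r & incat, "Annotated",
         ifelse(l & r, "Plausible",
                ifelse(l | r, "Anchored", "Unknown")))
}

#' Classify no-splice (read-through) observations
#'
#' @param sites data.frame with `chrom`, `pos`, `side`.
#' @param index A [build_site_index()] object.
#' @return `"NoSplice"` for annotated sites, `"Trivial"` otherwise.
#' @export
classify_nosplice <- function(sites, index) {
  if (nrow(sites) == 0L) return(character(0))
  ifelse(site_annotated(index, sites$chrom, sites$pos, sites$side, "."),
         "NoSplice", "Trivial")
}

#' Assemble per-site alternative groups
#'
#' Every splice site used by at least one junction, or with measured
#' no-splice depth, yields one group listing the competing alternatives at
#' that site: each junction using the site plus at most one no-splice
#' alternative. PSI denominators are the group totals.
#'
#' @param junctions Refined junction table ([realign_junctions()]).
#' @param nosplice Depth table from [measure_depth_inside()] (columns
#'   `chrom`, `pos`, `side`, `depth`); may be `NULL`.
#' @return data.frame in long form: `group` (site key), `chrom`, `pos`,
#'   `side`, `alternative` (junction or no-splice identifier), `count`,
#'   `total` (group sum).
#' @export
build_site_groups <- function(junctions, nosplice = NULL) {
  rows <- list()
  if (nrow(junctions) > 0L) {
    jid <- paste0("J:", junction_key(junctions$chrom, junctions$start,
                                     junctions$end))
    rows$left <- data.frame(
      chrom = junctions$chrom, pos = junctions$start, side = "left",
      alternative = jid, count = junctions$split_reads,
      stringsAsFactors = FALSE)
    rows$right <- data.frame(
      chrom = junctions$chrom, pos = junctions$end, side = "right",
      alternative = jid, count = junctions$split_reads,
      stringsAsFactors = FALSE)
  }
  if (!is.null(nosplice) && nrow(nosplice) > 0L) {
    rows$ns <- data.frame(
      chrom = nosplice$chrom, pos = nosplice$pos, side = nosplice$side,
      alternative = paste0("NS:", site_key(nosplice$chrom, nosplice$pos,
                                           nosplice$side)),
      count = nosplice$depth, stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, unname(rows))
  if (is.null(g))
    return(data.frame(group = character(0), chrom = character(0),
                      pos = integer(0), side = character(0),
                      alternative = character(0), count = integer(0),
                      total = integer(0), stringsAsFactors = FALSE))
  g$group <- site_key(g$chrom, g$pos, g$side)
  # keep no-splice-only groups just when they carry depth; junction-touched
  # sites keep their (possibly zero-depth) no-splice alternative
  touched <- unique(g$group[startsWith(g$alternative, "J:")])
  keep <- g$group %in% touched | g$count > 0L
  g <- g[keep, , drop = FALSE]
  g <- g[!duplicated(paste(g$group, g$alternative)), , drop = FALSE]
  tot <- tapply(g$count, g$group, sum)
  g$total <- as.integer(tot[g$group])
  g <- g[order(g$chrom, g$pos, g$side, g$alternative),
         c("group", "chrom", "pos", "side", "alternative", "count", "total")]
  rownames(g) <- NULL
  g
}

#' Compute PSI within site groups
#'
#' PSI of an alternative is its count over the group total; undefined (NA)
#' when the total is zero. The no-splice alternative enters the denominator.
#'
#' @param groups Output of [build_site_groups()].
#' @return `groups` with an added `psi` column.
#' @export
compute_psi <- function(groups) {
  groups$psi <- ifelse(groups$total > 0L, groups$count / groups$total,
                       NA_real_)
  groups
}

# psi of a specific alternative at a specific site; NA when absent/undefined
psi_lookup <- function(groups, chrom, pos, side, alternative) {
  key <- paste(site_key(groups$chrom, groups$pos, groups$side),
               groups$alternative)
  m <- match(paste(site_key(chrom, pos, side), alternative), key)
  groups$psi[m]
}

#' Build the classified, PSI-annotated event table
#'
#' One row per junction (with its two PSI values and flanking no-splice
#' depths) and one row per informative no-splice observation. Zero-depth
#' no-splice rows are kept only at sites touched by junction evidence;
#' untouched zero-information sites are suppressed.
#'
#' @param junctions Refined junction table.
#' @param nosplice Depth table from [measure_depth_inside()].
#' @param index A [build_site_index()] object.
#' @param sample_id Sample label written into the table.
#' @return data.frame of event records: `sample`, `chrom`, `start`, `end`,
#'   `side` (NA for junctions, `"left"`/`"right"` for no-splice rows),
#'   `strand`, `class`, `split_reads`, `nosplice_left`, `nosplice_right`,
#'   `psi_left`, `psi_right`, `genes_left`, `genes_right`, `shift_applied`.
#' @export
event_records <- function(junctions, nosplice, index, sample_id = "sample") {
  groups <- compute_psi(build_site_groups(junctions, nosplice))
  ns_depth <- function(chrom, pos, side) {
    if (is.null(nosplice) || nrow(nosplice) == 0L)
      return(rep(0L, length(chrom)))
    m <- match(site_key(chrom, pos, side),
               site_key(nosplice$chrom, nosplice$pos, nosplice$side))
    d <- nosplice$depth[m]
    ifelse(is.na(d), 0L, d)
  }
  genes_at <- function(chrom, pos, side) {
    side <- rep_len(side, length(chrom))
    vapply(seq_along(chrom), function(i)
      collapse_genes(site_genes(index, chrom[i], pos[i], side[i])),
      character(1))
  }
  recs <- list()
  if (nrow(junctions) > 0L) {
    jid <- paste0("J:", junction_key(junctions$chrom, junctions$start,
                                     junctions$end))
    recs$junc <- data.frame(
      sample = sample_id, chrom = junctions$chrom, start = junctions$start,
      end = junctions$end, side = NA_character_, strand = junctions$strand,
      class = classify_junction(junctions, index),
      split_reads = junctions$split_reads,
      nosplice_left = ns_depth(junctions$chrom, junctions$start, "left"),
      nosplice_right = ns_depth(junctions$chrom, junctions$end, "right"),
      psi_left = psi_lookup(groups, junctions$chrom, junctions$start, "left",
                            jid),
      psi_right = psi_lookup(groups, junctions$chrom, junctions$end, "right",
                             jid),
      genes_left = genes_at(junctions$chrom, junctions$start, "left"),
      genes_right = genes_at(junctions$chrom, junctions$end, "right"),
      shift_applied = junctions$shift_applied, stringsAsFactors = FALSE)
  }
  if (!is.null(nosplice) && nrow(nosplice) > 0L) {
    ns <- nosplice
    keep <- site_key(ns$chrom, ns$pos, ns$side) %in% groups$group
    ns <- ns[keep, , drop = FALSE]
    if (nrow(ns) > 0L) {
      nid <- paste0("NS:", site_key(ns$chrom, ns$pos, ns$side))
      psi <- psi_lookup(groups, ns$chrom, ns$pos, ns$side, nid)
      left <- ns$side == "left"
      recs$ns <- data.frame(
        sample = sample_id, chrom = ns$chrom, start = ns$pos, end = ns$pos,
        side = ns$side, strand = ".",
        class = classify_nosplice(ns, index), split_reads = ns$depth,
        nosplice_left = ifelse(left, ns$depth, 0L),
        nosplice_right = ifelse(left, 0L, ns$depth),
        psi_left = ifelse(left, psi, NA_real_),
        psi_right = ifelse(left, NA_real_, psi),
        genes_left = ifelse(left, genes_at(ns$chrom, ns$pos, ns$side), ""),
        genes_right = ifelse(left, "", genes_at(ns$chrom, ns$pos, ns$side)),
        shift_applied = 0L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, unname(recs))
  if (is.null(out)) out <- empty_records()
  out <- out[order(out$chrom, out$start, out$end, !is.na(out$side)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  data.frame(sample = character(0), chrom = character(0), start = integer(0),
             end = integer(0), side = character(0), strand = character(0),
             class = character(0), split_reads = integer(0),
             nosplice_left = integer(0), nosplice_right = integer(0),
             psi_left = numeric(0), psi_right = numeric(0),
             genes_left = character(0), genes_right = character(0),
             shift_applied = integer(0), stringsAsFactors = FALSE)
}

#' Read a STAR-style chimeric junction table
#'
#' Parses the per-read `Chimeric.out.junction` column dialect (chromosome,
#' breakpoint and strand for the two segments in columns 1-6). Header and
#' comment lines are skipped; malformed rows are dropped with a warning.
#'
#' @param path TSV path.
#' @return data.frame `chrom_a`, `pos_a`, `strand_a`, `chrom_b`, `pos_b`,
#'   `strand_b`, one row per supporting read.
#' @export
read_chimeric <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "chr_donorA")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f)
    length(f) >= 6L && !is.na(suppressWarnings(as.integer(f[2L]))) &&
      !is.na(suppressWarnings(as.integer(f[5L]))), logical(1))
  if (any(!ok))
    warning(sum(!ok), " malformed chimeric row(s) skipped")
  fields <- fields[ok]
  if (length(fields) == 0L)
    return(data.frame(chrom_a = character(0), pos_a = integer(0),
                      strand_a = character(0), chrom_b = character(0),
                      pos_b = integer(0), strand_b = character(0),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, fields)
  data.frame(chrom_a = m[, 1L], pos_a = as.integer(m[, 2L]),
             strand_a = m[, 3L], chrom_b = m[, 4L],
             pos_b = as.integer(m[, 5L]), strand_b = m[, 6L],
             stringsAsFactors = FALSE)
}

#' Call gene-fusion candidates
#'
#' A candidate is emitted when (a) a junction's two sites are annotated in
#' disjoint, non-empty gene sets (gap evidence), or (b) a chimeric read
#' joins two loci on different chromosomes, incompatible strands, or farther
#' apart than `max_intra_dist` (chimeric evidence, aggregated per breakpoint
#' pair).
#'
#' @param records Event table from [event_records()] (junction rows used).
#' @param index A [build_site_index()] object.
#' @param chimeric Optional chimeric table path or data.frame
#'   (see [read_chimeric()]).
#' @param max_intra_dist Same-chromosome distance above which a chimeric
#'   pair is considered a fusion candidate (default 1 Mb).
#' @return data.frame of candidates: `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `genes_a`, `genes_b`, `evidence`, `source`, `same_chrom`.
#' @export
call_fusions <- function(records, index, chimeric = NULL,
                         max_intra_dist = 1e6) {
  out <- list()
  jr <- records[is.na(records$side), , drop = FALSE]
  if (nrow(jr) > 0L) {
    ga <- lapply(jr$genes_left, split_genes)
    gb <- lapply(jr$genes_right, split_genes)
    is_fusion <- mapply(function(a, b)
      length(a) > 0L && length(b) > 0L && length(intersect(a, b)) == 0L,
      ga, gb)
    if (any(is_fusion)) {
      f <- jr[is_fusion, , drop = FALSE]
      out$gap <- data.frame(
        chrom_a = f$chrom, pos_a = f$start, chrom_b = f$chrom, pos_b = f$end,
        genes_a = f$genes_left, genes_b = f$genes_right,
        evidence = f$split_reads, source = "gap",
        same_chrom = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(chimeric)) {
    ch <- if (is.character(chimeric)) read_chimeric(chimeric) else chimeric
    if (nrow(ch) > 0L) {
      key <- paste(ch$chrom_a, ch$pos_a, ch$strand_a,
                   ch$chrom_b, ch$pos_b, ch$strand_b)
      agg <- ch[!duplicated(key), , drop = FALSE]
      agg$evidence <- as.integer(table(key)[key[!duplicated(key)]])
      sel <- agg$chrom_a != agg$chrom_b | agg$strand_a != agg$strand_b |
        abs(agg$pos_a - agg$pos_b) > max_intra_dist
      agg <- agg[sel, , drop = FALSE]
      if (nrow(agg) > 0L) {
        genes_near <- function(chrom, pos)
          vapply(seq_along(chrom), function(i)
            collapse_genes(c(site_genes(index, chrom[i], pos[i], "left"),
                             site_genes(index, chrom[i], pos[i], "right"))),
            character(1))
        out$chim <- data.frame(
          chrom_a = agg$chrom_a, pos_a = agg$pos_a, chrom_b = agg$chrom_b,
          pos_b = agg$pos_b, genes_a = genes_near(agg$chrom_a, agg$pos_a),
          genes_b = genes_near(agg$chrom_b, agg$pos_b),
          evidence = agg$evidence, source = "chimeric",
          same_chrom = agg$chrom_a == agg$chrom_b, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, unname(out))
  if (is.null(res))
    res <- data.frame(chrom_a = character(0), pos_a = integer(0),
                      chrom_b = character(0), pos_b = integer(0),
                      genes_a = character(0), genes_b = character(0),
                      evidence = integer(0), source = character(0),
                      same_chrom = logical(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
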