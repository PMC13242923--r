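# Tiered stringency filtering and output tables.

DEFAULT_CLASSES <- c("Plausible", "Anchored", "Unknown", "NoSplice")

#' Filter stringency tiers
#'
#' Four tiers of increasing stringency. Threshold defaults are this
#' package's own calibration and can be overridden per call or through a
#' YAML config (see [read_filter_config()]): a record survives when its
#' class is reportable, its split-read support reaches `min_reads` and its
#' larger PSI reaches `min_psi`. `Annotated` and `Trivial` records are kept
#' only in the unfiltered table.
#'
#' @param name One of `"none"`, `"sensitive"`, `"intermediate"`,
#'   `"stringent"`, or a tier object (returned unchanged).
#' @param min_reads,min_psi,classes_reported Optional overrides.
#' @return list of class `filter_tier`.
#' @export
filter_tier <- function(name, min_reads = NULL, min_psi = NULL,
                        classes_reported = NULL) {
  if (is.list(name) && inherits(name, "filter_tier")) return(name)
  defaults <- list(
    none = list(min_reads = 0L, min_psi = 0),
    sensitive = list(min_reads = 5L, min_psi = 0.01),
    intermediate = list(min_reads = 10L, min_psi = 0.05),
    stringent = list(min_reads = 20L, min_psi = 0.10))
  if (!is.character(name) || length(name) != 1L || !name %in% names(defaults))
    stop("unknown filter tier '", paste(name, collapse = ","),
         "'; valid tiers: ", paste(names(defaults), collapse = ", "))
  d <- defaults[[name]]
  structure(list(name = name,
                 min_reads = as.integer(min_reads %||% d$min_reads),
                 min_psi = as.numeric(min_psi %||% d$min_psi),
                 classes_reported = classes_reported %||% DEFAULT_CLASSES),
            class = "filter_tier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read tier overrides from a YAML config
#'
#' The file may define any of the tier names with `min_reads`, `min_psi`
#' and/or `classes_reported` entries.
#'
#' @param path YAML file path.
#' @param name Tier to build.
#' @return A [filter_tier()] object.
#' @export
read_filter_config <- function(path, name) {
  cfg <- yaml::read_yaml(path)
  ov <- cfg[[name]] %||% list()
  filter_tier(name, min_reads = ov$min_reads, min_psi = ov$min_psi,
              classes_reported = ov$classes_reported)
}

#' Apply a stringency tier to an event table
#'
#' Keeps records whose class is reportable, with `split_reads >= min_reads`
#' and `max(psi_left, psi_right) >= min_psi` (an undefined PSI counts as
#' absent). Pure and idempotent; output ordered by (chrom, start, end).
#'
#' @param records Event table from [event_records()].
#' @param tier Tier name or [filter_tier()] object.
#' @return The surviving records.
#' @export
apply_filter <- function(records, tier) {
  tier <- filter_tier(tier)
  if (nrow(records) == 0L) return(records)
  psi <- pmax(ifelse(is.na(records$psi_left), -Inf, records$psi_left),
              ifelse(is.na(records$psi_right), -Inf, records$psi_right))
  keep <- records$class %in% tier$classes_reported &
    records$split_reads >= tier$min_reads &
    (tier$min_psi <= 0 | psi >= tier$min_psi)
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write filtered and unfiltered junction tables
#'
#' Two UTF-8 TSVs with a stable column set; undefined PSI written as `'.'`.
#'
#' @param filtered,unfiltered Event tables.
#' @param out_prefix Output path prefix; writes
#'   `<prefix>.filtered.tsv` and `<prefix>.unfiltered.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_tables <- function(filtered, unfiltered, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir))
    stop("cannot write tables: directory '", dir, "' does not exist")
  paths <- c(filtered = paste0(out_prefix, ".filtered.tsv"),
             unfiltered = paste0(out_prefix, ".unfiltered.tsv"))
  fmt <- function(x) {
    x$psi_left <- ifelse(is.na(x$psi_left), ".", format(x$psi_left, digits = 15L,
                                                        trim = TRUE, scientific = FALSE))
    x$psi_right <- ifelse(is.na(x$psi_right), ".", format(x$psi_right, digits = 15L,
                                                          trim = TRUE, scientific = FALSE))
    x$side <- ifelse(is.na(x$side), ".", x$side)
    x
  }
  utils::write.table(fmt(filtered), paths[["filtered"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(fmt(unfiltered), paths[["unfiltered"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Read back a junction table written by [write_tables()]
#'
#' @param path TSV path.
#' @return Event table identical to the one written.
#' @export
read_junction_table <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = c(psi_left = "character",
                                        psi_right = "character",
                                        side = "character",
                                        genes_left = "character",
                                        genes_right = "character",
                                        sample = "character",
                                        chrom = "character",
                                        strand = "character"),
                         na.strings = NULL)
  x$psi_left <- suppressWarnings(as.numeric(ifelse(x$psi_left == ".", NA,
                                                   x$psi_left)))
  x$psi_right <- suppressWarnings(as.numeric(ifelse(x$psi_right == ".", NA,
                                                    x$psi_right)))
  x$side <- ifelse(x$side == ".", NA_character_, x$side)
  x
}

#' Per-gene junction summary
#'
#' For a gene with at least one filtered record in the sample, returns the
#' exon structure, the filtered junctions touching the gene, and a plot of
#' junction arcs scaled by split-read support and labeled with PSI. Genes
#' without filtered records yield `NULL` (not an error).
#'
#' @param filtered Filtered event table.
#' @param models A `transcript_models` table.
#' @param gene_id Gene to summarise.
#' @param sample_id Optional sample restriction.
#' @return `NULL`, or a list of class `gene_report` with `gene_id`, `exons`,
#'   `records` and `plot` (a ggplot object).
#' @export
gene_report <- function(filtered, models, gene_id, sample_id = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, !is.na(gene_id))
  ex <- as.data.frame(models)
  ex <- ex[ex$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("gene '", gene_id, "' not in annotation")
  recs <- filtered
  if (!is.null(sample_id)) recs <- recs[recs$sample == sample_id, , drop = FALSE]
  span <- range(c(ex$start, ex$end))
  pad <- 0.1 * diff(span)
  hit <- recs$chrom == ex$chrom[1L] &
    recs$start <= span[2L] + pad & recs$end >= span[1L] - pad
  gene_hit <- grepl(paste0("(^|,)", gene_id, "($|,)"), recs$genes_left) |
    grepl(paste0("(^|,)", gene_id, "($|,)"), recs$genes_right)
  recs <- recs[hit | gene_hit, , drop = FALSE]
  if (nrow(recs) == 0L) return(NULL)
  jr <- recs[is.na(recs$side), , drop = FALSE]
  arcs <- if (nrow(jr) > 0L) data.frame(
    x = (jr$start + jr$end) / 2, xmin = jr$start - 1L, xmax = jr$end + 1L,
    height = 1 + log10(pmax(jr$split_reads, 1L)),
    label = sprintf("%s PSI=%.2f/%.2f", jr$class,
                    ifelse(is.na(jr$psi_left), NA, jr$psi_left),
                    ifelse(is.na(jr$psi_right), NA, jr$psi_right)),
    stringsAsFactors = FALSE) else NULL
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = ex,
                       ggplot2::aes(xmin = start, xmax = end,
                                    ymin = -0.25, ymax = 0.25),
                       fill = "grey40") +
    ggplot2::labs(title = paste0(ex$gene_name[1L], " (", gene_id, ")"),
                  x = ex$chrom[1L], y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(arcs)) {
    arc_pts <- do.call(rbind, lapply(seq_len(nrow(arcs)), function(i) {
      t <- seq(0, pi, length.out = 50L)
      data.frame(id = i,
                 x = arcs$xmin[i] + (arcs$xmax[i] - arcs$xmin[i]) * (1 - cos(t)) / 2,
                 y = arcs$height[i] * sin(t))
    }))
    p <- p +
      ggplot2::geom_path(data = arc_pts,
                         ggplot2::aes(x = x, y = y,
                                      group = id),
                         colour = "steelblue") +
      ggplot2::geom_text(data = arcs,
                         ggplot2::aes(x = x, y = height + 0.2,
                                      label = label), size = 2.8)
  }
  structure(list(gene_id = gene_id, exons = ex, records = recs, plot = p),
            class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  cat("gene_report for", x$gene_id, "-", nrow(x$records),
      "filtered record(s)\n")
  invisible(x)
}
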