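#' Load a BED-like mitochondrial gene annotation
#'
#' Reads a tab-separated annotation with columns \code{chrom},
#' \code{start} (0-based), \code{end} (half-open), \code{gene},
#' \code{category} (\code{mRNA}/\code{rRNA}/\code{tRNA}) and
#' \code{strand}, converting to 1-based inclusive CDS bounds on load.
#' An optional companion table flags CDS intervals shared by two genes
#' where footprint assignment is ambiguous.
#'
#' @param path Annotation TSV (BED-like, 0-based half-open on disk).
#' @param overlaps_path Optional TSV with columns \code{gene_a},
#'   \code{gene_b}, \code{start}, \code{end} (1-based inclusive).
#' @return An object of class \code{mt_annotation}: list with \code{genes}
#'   (data frame: gene, category, strand, cds_start, cds_end) and
#'   \code{overlaps} (data frame, possibly empty).
#' @export
read_mt_annotation <- function(path, overlaps_path = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene", "category", "strand")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  genes <- data.frame(gene = df$gene, category = df$category,
                      strand = df$strand,
                      cds_start = df$start + 1L,   # 0-based -> 1-based
                      cds_end = df$end,
                      stringsAsFactors = FALSE)
  if (any(genes$cds_start > genes$cds_end))
    stop("annotation interval with start > end: ",
         genes$gene[genes$cds_start > genes$cds_end][1L])
  overlaps <- if (!is.null(overlaps_path)) {
    ov <- utils::read.delim(overlaps_path, comment.char = "#",
                            stringsAsFactors = FALSE)
    stopifnot(all(c("gene_a", "gene_b", "start", "end") %in% names(ov)))
    ov
  } else data.frame(gene_a = character(0), gene_b = character(0),
                    start = integer(0), end = integer(0))
  structure(list(genes = genes, overlaps = overlaps),
            class = "mt_annotation")
}

#' Packaged annotation of the 13 human mt-mRNAs
#'
#' CDS intervals of the 13 mitochondrially encoded mRNAs on rCRS
#' (NC_012920) coordinates, with the two ambiguous overlap intervals
#' (ATP8/ATP6 and ND4L/ND4) flagged for exclusion.
#'
#' @return An \code{mt_annotation}; see \code{\link{read_mt_annotation}}.
#' @export
mt_mrna_annotation <- function() {
  read_mt_annotation(
    system.file("extdata", "mt_mrna_annotation.tsv", package = "mtOmeScan",
                mustWork = TRUE),
    system.file("extdata", "mt_mrna_overlaps.tsv", package = "mtOmeScan",
                mustWork = TRUE))
}

assign_gene <- function(pos, strand, genes) {
  # gene index whose CDS contains pos on the matching strand; 0 = none,
  # -1 = more than one (ambiguous)
  hit <- which(genes$strand == strand &
                 genes$cds_start <= pos & pos <= genes$cds_end)
  if (length(hit) == 1L) hit else if (length(hit) == 0L) 0L else -1L
}

#' Filter mitoribosome footprints by position
#'
#' Drops footprints whose 5' end lies (i) within the first
#' \code{start_window} CDS nucleotides (ribosomes paused at initiation),
#' (ii) within the final \code{stop_window} CDS nucleotides (termination),
#' (iii) inside an annotated two-gene overlap interval (ambiguous
#' assignment; excluded from both genes), or (iv) on no annotated gene.
#' Offsets are transcript-sense: for a minus-strand gene the first CDS
#' nucleotide is \code{cds_end}.
#'
#' @param reads Data frame with columns \code{five_prime_pos},
#'   \code{length}, \code{strand} (\code{"+"}/\code{"-"}).
#' @param annotation An \code{mt_annotation}.
#' @param start_window,stop_window Exclusion window sizes in nt
#'   (defaults 15 and 45).
#' @return List with \code{kept} (the surviving reads plus a \code{gene}
#'   column) and \code{drops} (named counts per rule:
#'   \code{start_window}, \code{stop_window}, \code{overlap},
#'   \code{intergenic}).
#' @export
filter_footprints <- function(reads, annotation, start_window = 15L,
                              stop_window = 45L) {
  stopifnot(inherits(annotation, "mt_annotation"),
            all(c("five_prime_pos", "length", "strand") %in% names(reads)))
  genes <- annotation$genes
  ov <- annotation$overlaps
  n <- nrow(reads)
  gene <- character(n)
  rule <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    pos <- reads$five_prime_pos[k]
    in_overlap <- nrow(ov) &&
      any(ov$start <= pos & pos <= ov$end)
    if (in_overlap) { rule[k] <- "overlap"; next }
    gi <- assign_gene(pos, reads$strand[k], genes)
    if (gi == 0L) { rule[k] <- "intergenic"; next }
    if (gi == -1L) { rule[k] <- "overlap"; next }
    g <- genes[gi, ]
    offset <- if (g$strand == "+") pos - g$cds_start else g$cds_end - pos
    from_stop <- if (g$strand == "+") g$cds_end - pos else pos - g$cds_start
    if (offset <= start_window - 1L) { rule[k] <- "start_window"; next }
    if (from_stop <= stop_window - 1L) { rule[k] <- "stop_window"; next }
    gene[k] <- g$gene
  }
  kept <- reads[is.na(rule), , drop = FALSE]
  kept$gene <- gene[is.na(rule)]
  drops <- c(start_window = sum(rule == "start_window", na.rm = TRUE),
             stop_window = sum(rule == "stop_window", na.rm = TRUE),
             overlap = sum(rule == "overlap", na.rm = TRUE),
             intergenic = sum(rule == "intergenic", na.rm = TRUE))
  list(kept = kept, drops = drops)
}

#' Reads-per-million normalisation
#'
#' Footprint and RNA counts are normalised to the number of positive-sense
#' reads mapping to nuclear-encoded mRNA in the same library (supplied by
#' the caller; computing it is upstream of this package).
#'
#' @param count Read count (vector allowed).
#' @param nuclear_mrna_reads Positive normaliser count.
#' @return \code{count / nuclear_mrna_reads * 1e6}.
#' @export
rpm_normalize <- function(count, nuclear_mrna_reads) {
  if (length(nuclear_mrna_reads) != 1L || is.na(nuclear_mrna_reads) ||
      nuclear_mrna_reads <= 0)
    stop("'nuclear_mrna_reads' must be a single positive count")
  count / nuclear_mrna_reads * 1e6
}

#' Translation efficiency
#'
#' @param ribo_rpm,rna_rpm Footprint and RNA-seq RPM for the same gene.
#' @return \code{ribo_rpm / rna_rpm}, or \code{NA} where
#'   \code{rna_rpm} is not positive.
#' @export
translation_efficiency <- function(ribo_rpm, rna_rpm) {
  te <- ribo_rpm / rna_rpm
  te[is.na(rna_rpm) | rna_rpm <= 0] <- NA_real_
  te
}

#' Per-gene expression table from filtered footprints
#'
#' @param kept Filtered reads (output \code{kept} of
#'   \code{\link{filter_footprints}}).
#' @param annotation An \code{mt_annotation}; all mRNA genes appear in the
#'   output (zero counts included).
#' @param nuclear_mrna_reads Library normaliser for RPM.
#' @param rna_rpm Optional named vector of matched RNA-seq RPM per gene,
#'   for translation efficiency.
#' @return Data frame with columns \code{gene}, \code{ribo_count},
#'   \code{ribo_rpm}, \code{rna_rpm}, \code{te}.
#' @export
expression_table <- function(kept, annotation, nuclear_mrna_reads,
                             rna_rpm = NULL) {
  genes <- annotation$genes$gene[annotation$genes$category == "mRNA"]
  counts <- table(factor(kept$gene, levels = genes))
  out <- data.frame(gene = genes,
                    ribo_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$ribo_rpm <- rpm_normalize(out$ribo_count, nuclear_mrna_reads)
  out$rna_rpm <- if (is.null(rna_rpm)) NA_real_ else
    unname(rna_rpm[out$gene])
  out$te <- translation_efficiency(out$ribo_rpm, out$rna_rpm)
  out
}

#' Knock-out vs parental footprint occupancy
#'
#' Per-gene occupancy is the knock-out footprint RPM as a percentage of
#' the parental RPM; the summary reports mean, sample SD, minimum, median
#' and maximum over genes with positive parental RPM (others are excluded
#' and listed).
#'
#' @param ko,parental Expression tables (see \code{\link{expression_table}})
#'   sharing a gene universe.
#' @return An object of class \code{occupancy_summary}: list with
#'   \code{per_gene} (data frame: gene, occupancy percent),
#'   \code{excluded} (genes with no parental signal) and \code{summary}
#'   (named vector: mean, sd, min, median, max, in percent).
#' @export
occupancy <- function(ko, parental) {
  shared <- intersect(ko$gene, parental$gene)
  if (!length(shared)) stop("no shared genes between tables")
  ko <- ko[match(shared, ko$gene), ]
  parental <- parental[match(shared, parental$gene), ]
  ok <- parental$ribo_rpm > 0
  per_gene <- data.frame(
    gene = shared[ok],
    occupancy = 100 * ko$ribo_rpm[ok] / parental$ribo_rpm[ok],
    stringsAsFactors = FALSE)
  if (!nrow(per_gene)) stop("no gene with positive parental RPM")
  s <- c(mean = mean(per_gene$occupancy),
         sd = stats::sd(per_gene$occupancy),
         min = min(per_gene$occupancy),
         median = stats::median(per_gene$occupancy),
         max = max(per_gene$occupancy))
  structure(list(per_gene = per_gene, excluded = shared[!ok], summary = s),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<occupancy_summary> %d genes: mean %.1f%% +/- %.1f%% (min %.1f%%, median %.1f%%, max %.1f%%)\n",
    nrow(x$per_gene), s["mean"], s["sd"], s["min"], s["median"], s["max"]))
  if (length(x$excluded))
    cat("  excluded (no parental signal):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
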