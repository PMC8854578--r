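#' Reference index for a single sequence
#'
#' Describes the coordinate system all per-position profiles live in:
#' 1-based inclusive positions on one reference sequence (for the human
#' mitochondrial genome this matches mtDNA numbering, so U3039 of the 16S
#' mt-rRNA is position 3039).
#'
#' @param name Reference sequence name (e.g. \code{"chrM"}).
#' @param length_nt Reference length in nucleotides; must be positive.
#' @param circular Logical; whether the molecule is circular. Circular
#'   references are treated as linear for counting and origin-spanning
#'   records are skipped (see \code{\link{count_read_ends}}).
#' @return An object of class \code{reference_index}.
#' @export
reference_index <- function(name, length_nt, circular = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  length_nt <- as.integer(length_nt)
  if (is.na(length_nt) || length_nt <= 0L)
    stop("'length_nt' must be a positive integer")
  structure(
    list(name = name, length_nt = length_nt, circular = isTRUE(circular)),
    class = "reference_index"
  )
}

#' Library metadata
#'
#' Identifies one sequencing library: its sample, genotype, assay type,
#' dNTP condition (meaningful only for the RT-stop assay, where parallel
#' low and high dNTP reverse transcriptions of the same RNA pool are
#' sequenced) and biological replicate number.
#'
#' @param sample_id Character scalar.
#' @param genotype One of \code{"parental"}, \code{"MRM1_KO"},
#'   \code{"MRM2_KO"}, \code{"MRM3_KO"}, \code{"other"}.
#' @param assay One of \code{"cleavage"}, \code{"rtstop"}, \code{"riboseq"},
#'   \code{"rnaseq"}.
#' @param dntp \code{"low"} or \code{"high"} for RT-stop libraries,
#'   \code{"not_applicable"} otherwise (enforced).
#' @param replicate Positive integer replicate index.
#' @return An object of class \code{library_meta}.
#' @export
library_meta <- function(sample_id,
                         genotype = c("parental", "MRM1_KO", "MRM2_KO",
                                      "MRM3_KO", "other"),
                         assay = c("cleavage", "rtstop", "riboseq", "rnaseq"),
                         dntp = c("not_applicable", "low", "high"),
                         replicate = 1L) {
  genotype <- match.arg(genotype)
  assay <- match.arg(assay)
  dntp <- match.arg(dntp)
  replicate <- as.integer(replicate)
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            !is.na(replicate), replicate >= 1L)
  if ((assay == "rtstop") != (dntp %in% c("low", "high")))
    stop("'dntp' must be \"low\" or \"high\" iff assay is \"rtstop\" ",
         "(sample ", sample_id, ")")
  structure(
    list(sample_id = sample_id, genotype = genotype, assay = assay,
         dntp = dntp, replicate = replicate),
    class = "library_meta"
  )
}

#' Per-position end-count profile
#'
#' The shared substrate of both methylation-scoring assays: per-position
#' coverage together with counts of read 5' starts and 3' ends, in
#' transcript-sense coordinates (for a minus-strand profile, position 1 is
#' the reference 3' terminus).
#'
#' The arrays are linked by the coverage identity
#' \code{C[1] == S[1]} and \code{C[j] == C[j-1] + S[j] - E[j-1]} for
#' \code{j >= 2}, which the constructor enforces.
#'
#' @param reference A \code{\link{reference_index}}.
#' @param strand \code{"plus"} or \code{"minus"}.
#' @param coverage,starts5,ends3 Integer vectors of length
#'   \code{reference$length_nt}. If \code{coverage} is \code{NULL} it is
#'   derived from \code{starts5} and \code{ends3}.
#' @param meta A \code{\link{library_meta}}.
#' @return An object of class \code{end_count_profile}.
#' @export
end_count_profile <- function(reference, strand = c("plus", "minus"),
                              starts5, ends3, coverage = NULL, meta) {
  strand <- match.arg(strand)
  stopifnot(inherits(reference, "reference_index"),
            inherits(meta, "library_meta"))
  L <- reference$length_nt
  starts5 <- as.numeric(starts5)
  ends3 <- as.numeric(ends3)
  if (length(starts5) != L || length(ends3) != L)
    stop("start/end arrays must have length ", L)
  if (any(starts5 < 0) || any(ends3 < 0))
    stop("counts must be non-negative")
  if (is.null(coverage)) {
    coverage <- cumsum(starts5) - c(0, cumsum(ends3)[-L])
  } else {
    coverage <- as.numeric(coverage)
    if (length(coverage) != L) stop("coverage must have length ", L)
  }
  prof <- structure(
    list(reference = reference, strand = strand, coverage = coverage,
         starts5 = starts5, ends3 = ends3, meta = meta),
    class = "end_count_profile"
  )
  validate_profile(prof)
  prof
}

#' Validate the coverage identity of a profile
#'
#' @param profile An \code{end_count_profile}.
#' @return Invisibly \code{TRUE}; stops with the first offending position
#'   otherwise.
#' @export
validate_profile <- function(profile) {
  stopifnot(inherits(profile, "end_count_profile"))
  L <- profile$reference$length_nt
  S <- profile$starts5; E <- profile$ends3; C <- profile$coverage
  if (sum(S) != sum(E))
    stop("total read starts (", sum(S), ") != total read ends (", sum(E), ")")
  expected <- cumsum(S) - c(0, cumsum(E)[-L])
  bad <- which(abs(C - expected) > 1e-9)
  if (length(bad))
    stop("coverage identity violated first at position ", bad[1L],
         " (coverage ", C[bad[1L]], ", expected ", expected[bad[1L]], ")")
  if (any(C < 0))
    stop("negative coverage at position ", which(C < 0)[1L])
  invisible(TRUE)
}

#' @export
print.end_count_profile <- function(x, ...) {
  cat("<end_count_profile> ", x$meta$sample_id, " (", x$meta$assay,
      if (x$meta$dntp != "not_applicable") paste0("/", x$meta$dntp),
      ", rep ", x$meta$replicate, ")\n", sep = "")
  cat("  reference: ", x$reference$name, " (", x$reference$length_nt,
      " nt), strand ", x$strand, "\n", sep = "")
  cat("  reads: ", sum(x$starts5), ", total coverage: ",
      sum(x$coverage), "\n", sep = "")
  invisible(x)
}

#' Count read 5' starts and 3' ends per position
#'
#' Tallies, for one strand of one reference, the number of reads starting
#' and ending at each position plus per-position coverage. Only records on
#' the requested strand contribute (libraries are strand-specific;
#' antisense records are dropped and counted). Start/end refer to the
#' reference-consuming aligned span, so soft-clipped bases are excluded.
#' Minus-strand profiles are reported in transcript-sense coordinates.
#'
#' @param alignments A data frame with columns \code{start}, \code{end}
#'   (1-based inclusive reference span) and \code{strand} (\code{"+"} or
#'   \code{"-"}). Use \code{\link{profile_from_bam}} to obtain one from a
#'   BAM/SAM file.
#' @param reference A \code{\link{reference_index}}.
#' @param strand Which transcript-sense strand to profile.
#' @param meta A \code{\link{library_meta}}.
#' @return An \code{end_count_profile}. The number of antisense records
#'   dropped and of skipped origin-spanning records are attached as
#'   attributes \code{"dropped_antisense"} and \code{"skipped_spanning"}.
#' @export
count_read_ends <- function(alignments, reference,
                            strand = c("plus", "minus"), meta) {
  strand <- match.arg(strand)
  stopifnot(is.data.frame(alignments),
            all(c("start", "end", "strand") %in% names(alignments)),
            inherits(reference, "reference_index"))
  L <- reference$length_nt
  want <- if (strand == "plus") "+" else "-"
  keep <- alignments$strand == want
  n_anti <- sum(!keep)
  al <- alignments[keep, , drop = FALSE]

  n_span <- 0L
  if (nrow(al)) {
    if (any(al$end < al$start))
      stop("alignment with end < start at row ", which(al$end < al$start)[1L])
    oob <- al$start < 1L | al$end > L
    if (any(oob)) {
      if (reference$circular) {
        n_span <- sum(oob)
        warning(n_span, " origin-spanning record(s) skipped on circular ",
                "reference '", reference$name, "'")
        al <- al[!oob, , drop = FALSE]
      } else {
        i <- which(oob)[1L]
        stop("alignment [", al$start[i], ", ", al$end[i],
             "] outside reference bounds [1, ", L, "]")
      }
    }
  }

  s <- al$start; e <- al$end
  if (strand == "minus") {        # transcript-sense coordinates
    s2 <- L - e + 1L
    e2 <- L - al$start + 1L
    s <- s2; e <- e2
  }
  starts5 <- tabulate(s, nbins = L)
  ends3 <- tabulate(e, nbins = L)
  prof <- end_count_profile(reference, strand, starts5, ends3, meta = meta)
  attr(prof, "dropped_antisense") <- n_anti
  attr(prof, "skipped_spanning") <- n_span
  prof
}

#' Build an end-count profile from a BAM or SAM file
#'
#' Reads primary alignments with \pkg{GenomicAlignments} (the aligned span
#' excludes soft clips by construction) and delegates to
#' \code{\link{count_read_ends}}. SAM input is converted on the fly.
#'
#' @param path Path to a BAM or SAM file.
#' @param reference A \code{\link{reference_index}}; records on other
#'   references are ignored.
#' @param strand,meta Passed to \code{\link{count_read_ends}}.
#' @param min_mapq Minimum mapping quality; defaults to 0 (permissive:
#'   fragmentation assays expect coincident ends and no duplicate removal).
#' @return An \code{end_count_profile}.
#' @export
profile_from_bam <- function(path, reference, strand = c("plus", "minus"),
                             meta, min_mapq = 0L) {
  strand <- match.arg(strand)
  if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
      !requireNamespace("Rsamtools", quietly = TRUE))
    stop("profile_from_bam requires the Rsamtools and GenomicAlignments packages")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isUnmappedQuery = FALSE),
      mapqFilter = as.integer(min_mapq)))
  ga <- ga[as.character(GenomicAlignments::seqnames(ga)) == reference$name]
  al <- data.frame(
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    stringsAsFactors = FALSE
  )
  count_read_ends(al, reference, strand, meta)
}

#' Write an end-count profile as a TSV table
#'
#' Emits a commented header line (package version, sample, strand) followed
#' by columns \code{position}, \code{coverage}, \code{starts5}, \code{ends3}.
#'
#' @param profile An \code{end_count_profile}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_profile_table <- function(profile, path) {
  stopifnot(inherits(profile, "end_count_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("mtOmeScan"))
  cat(sprintf("# mtOmeScan %s profile sample=%s reference=%s length=%d strand=%s\n",
              ver, profile$meta$sample_id, profile$reference$name,
              profile$reference$length_nt, profile$strand), file = con)
  df <- data.frame(position = seq_len(profile$reference$length_nt),
                   coverage = profile$coverage,
                   starts5 = profile$starts5,
                   ends3 = profile$ends3)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an end-count profile from a TSV table
#'
#' Inverse of \code{\link{write_profile_table}}: requires a header with
#' columns \code{position}, \code{coverage}, \code{starts5}, \code{ends3}
#' and contiguous 1-based positions.
#'
#' @param path Input TSV path; lines beginning \code{#} are ignored.
#' @param reference A \code{\link{reference_index}} (length must match the
#'   table), or \code{NULL} to infer a reference from the table length.
#' @param strand,meta Profile annotation (not stored in the table body).
#' @param strict If \code{TRUE}, the coverage identity is enforced and a
#'   violation is an error naming the first offending position (always the
#'   case when \code{coverage} is consistent); if \code{FALSE}, the stored
#'   coverage column is discarded and recomputed from the end counts.
#' @return An \code{end_count_profile}.
#' @export
read_profile_table <- function(path, reference = NULL,
                               strand = c("plus", "minus"), meta,
                               strict = TRUE) {
  strand <- match.arg(strand)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("position", "coverage", "starts5", "ends3")
  if (!all(need %in% names(df)))
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  L <- nrow(df)
  if (anyDuplicated(df$position))
    stop("duplicate position ", df$position[duplicated(df$position)][1L])
  if (!identical(as.integer(df$position), seq_len(L)))
    stop("positions must be contiguous 1..L (1-based); got first mismatch at row ",
         which(as.integer(df$position) != seq_len(L))[1L])
  if (any(df$coverage < 0) || any(df$starts5 < 0) || any(df$ends3 < 0))
    stop("negative counts in profile table")
  if (is.null(reference)) {
    reference <- reference_index("unknown", L)
  } else if (reference$length_nt != L)
    stop("table length ", L, " != reference length ", reference$length_nt)
  end_count_profile(reference, strand,
                    starts5 = df$starts5, ends3 = df$ends3,
                    coverage = if (strict) df$coverage else NULL,
                    meta = meta)
}

#' Merge end-count profiles by element-wise summation
#'
#' Pools technical lanes of the same library: all profiles must share
#' reference, strand and metadata apart from \code{sample_id}.
#'
#' @param profiles A list of \code{end_count_profile} objects.
#' @return A merged \code{end_count_profile} whose \code{sample_id}
#'   concatenates the inputs'.
#' @export
merge_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "end_count_profile")))
  p1 <- profiles[[1L]]
  for (p in profiles[-1L]) {
    if (p$reference$length_nt != p1$reference$length_nt ||
        p$reference$name != p1$reference$name)
      stop("profiles map to different references")
    if (p$strand != p1$strand)
      stop("profiles are on different strands")
    m1 <- p1$meta; m2 <- p$meta
    if (!identical(m1[c("genotype", "assay", "dntp", "replicate")],
                   m2[c("genotype", "assay", "dntp", "replicate")]))
      stop("profiles have incompatible library metadata")
  }
  add <- function(field) Reduce(`+`, lapply(profiles, `[[`, field))
  meta <- p1$meta
  meta$sample_id <- paste(vapply(profiles, function(p) p$meta$sample_id,
                                 character(1)), collapse = "+")
  end_count_profile(p1$reference, p1$strand,
                    starts5 = add("starts5"), ends3 = add("ends3"),
                    coverage = add("coverage"), meta = meta)
}
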