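#' Correct SILAC ratios for imperfect mixing
#'
#' SILAC density-gradient experiments mix heavy- and light-labelled cell
#' populations nominally 1:1; the realised mixing ratio is estimated as
#' the median heavy/light ratio of a whole-cell lysate mix and divided
#' out of every fraction-level ratio.
#'
#' @param ratios Data frame with at least a \code{ratio} column of
#'   strictly positive heavy/light ratios (see
#'   \code{\link{simulate_silac_table}} for the full layout).
#' @param whole_cell_median Positive median label ratio of the whole-cell
#'   mix.
#' @return The table with \code{ratio} divided by
#'   \code{whole_cell_median}.
#' @export
correct_mixing <- function(ratios, whole_cell_median) {
  if (length(whole_cell_median) != 1L || is.na(whole_cell_median) ||
      whole_cell_median <= 0)
    stop("'whole_cell_median' must be a single positive number")
  stopifnot(is.data.frame(ratios), "ratio" %in% names(ratios))
  if (any(ratios$ratio <= 0)) stop("ratios must be strictly positive")
  ratios$ratio <- ratios$ratio / whole_cell_median
  ratios
}

#' Per-protein and per-subunit SILAC enrichment
#'
#' Combines two reciprocal labelling experiments: the per-protein
#' enrichment is the mean of the log2 corrected ratios over both label
#' orientations, with the swapped orientation's log-ratio sign-flipped
#' first (so a protein enriched in the knock-out scores positive in
#' both). Per-subunit distributions are summarised by their median.
#' Linear-space averaging (mean of ratio and 1/swapped-ratio, then log2)
#' is available behind \code{log_space = FALSE}.
#'
#' @param corrected Mixing-corrected ratio table with columns
#'   \code{protein}, \code{subunit} (\code{mtSSU}/\code{mtLSU}/
#'   \code{other}), \code{ratio}, \code{orientation}
#'   (\code{forward}/\code{swapped}).
#' @param log_space Average in log2 space (default) or linear space.
#' @return List with \code{per_protein} (data frame: protein, subunit,
#'   enrichment in log2 units, complete flag — \code{FALSE} when only one
#'   orientation was observed) and \code{per_subunit} (data frame:
#'   subunit, median enrichment, n).
#' @export
subunit_enrichment <- function(corrected, log_space = TRUE) {
  need <- c("protein", "subunit", "ratio", "orientation")
  stopifnot(is.data.frame(corrected), all(need %in% names(corrected)))
  sp <- split(corrected, corrected$protein)
  per <- do.call(rbind, lapply(sp, function(d) {
    fwd <- d$ratio[d$orientation == "forward"]
    swp <- d$ratio[d$orientation == "swapped"]
    complete <- length(fwd) > 0L && length(swp) > 0L
    vals <- if (log_space) {
      c(log2(fwd), -log2(swp))
    } else {
      log2(c(fwd, 1 / swp))
    }
    data.frame(protein = d$protein[1L], subunit = d$subunit[1L],
               enrichment = mean(vals), complete = complete,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  per_subunit <- do.call(rbind, lapply(split(per, per$subunit), function(d)
    data.frame(subunit = d$subunit[1L],
               median_enrichment = stats::median(d$enrichment),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(per_subunit) <- NULL
  list(per_protein = per, per_subunit = per_subunit)
}

#' Efficiency-corrected comparative-Ct relative expression
#'
#' Pfaffl-style relative quantification: per sample,
#' \deqn{\mathrm{level} = \frac{E_t^{\,\overline{Ct}_{t,\mathrm{ctrl}} - Ct_t}}
#'                             {E_{ref}^{\,\overline{Ct}_{ref,\mathrm{ctrl}} - Ct_{ref}}}}
#' where the calibrator Ct values are the control-group means and the
#' amplification efficiencies are fold-per-cycle (2 = perfect doubling).
#' The geometric mean level of the control group is 1 by construction.
#'
#' @param group Character vector, \code{"control"} or \code{"test"}, one
#'   per sample.
#' @param target_ct,ref_ct Numeric Ct values per sample for the target and
#'   the reference amplicon (technical replicates already averaged).
#' @param e_target,e_ref Amplification efficiencies, in (1, 2].
#' @return Data frame with columns \code{group}, \code{target_ct},
#'   \code{ref_ct}, \code{level}.
#' @export
relative_expression <- function(group, target_ct, ref_ct,
                                e_target, e_ref) {
  stopifnot(length(group) == length(target_ct),
            length(group) == length(ref_ct),
            all(group %in% c("control", "test")))
  if (!any(group == "control")) stop("control group is empty")
  if (any(is.na(ref_ct))) stop("missing reference Ct value")
  if (any(c(e_target, e_ref) <= 1) || any(c(e_target, e_ref) > 2))
    stop("efficiencies must lie in (1, 2] (fold per cycle)")
  if (any(c(target_ct, ref_ct) <= 0)) stop("Ct values must be positive")
  cal_t <- mean(target_ct[group == "control"])
  cal_r <- mean(ref_ct[group == "control"])
  level <- e_target^(cal_t - target_ct) / e_ref^(cal_r - ref_ct)
  data.frame(group = group, target_ct = target_ct, ref_ct = ref_ct,
             level = level, stringsAsFactors = FALSE)
}

#' Climbing index from a counter-current negative-geotaxis assay
#'
#' Flies start in chamber 0 and may complete up to \code{K} successive
#' climbs (one per chamber transfer). With \code{c_k} flies ending after
#' \code{k} successful climbs, the weighted performance normalised to the
#' maximum possible score is
#' \deqn{CI = \frac{\sum_k k\, c_k}{K \sum_k c_k} \in [0, 1].}
#'
#' @param counts Vector \code{c_0, ..., c_K} of fly counts per final
#'   chamber (length \code{K + 1}; default assay has \code{K = 5}).
#' @return The climbing index, a number in [0, 1].
#' @export
climbing_index <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("no flies counted")
  k_max <- length(counts) - 1L
  if (k_max < 1L) stop("need at least two chambers")
  sum(seq.int(0L, k_max) * counts) / (k_max * n)
}
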