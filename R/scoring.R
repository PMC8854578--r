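#' Parameters for cleavage-protection scoring
#'
#' @param flank_len Flank half-width \code{w} in nucleotides: the score at
#'   a position contrasts it against \code{w} bonds on each side ("flanking
#'   12 nucleotides" for the default \code{w = 6}).
#' @param min_median_reads Coverage qualification threshold \code{T}: a
#'   position is scored only if the median cleavage count over its
#'   \code{2w}-bond flank (centre excluded) is strictly greater than
#'   \code{T} (default 15).
#' @param count_convention How a cleavage of the bond 3' of nucleotide
#'   \code{i} is witnessed: \code{"ends_plus_nextstart"} (default; both the
#'   upstream fragment's 3' end at \code{i} and the downstream fragment's
#'   5' start at \code{i + 1}), \code{"starts_only"} or \code{"ends_only"}.
#' @return An object of class \code{cleavage_params}.
#' @export
cleavage_params <- function(flank_len = 6L, min_median_reads = 15,
                            count_convention = c("ends_plus_nextstart",
                                                 "starts_only", "ends_only")) {
  count_convention <- match.arg(count_convention)
  flank_len <- as.integer(flank_len)
  stopifnot(flank_len >= 1L, min_median_reads >= 0)
  structure(list(flank_len = flank_len,
                 min_median_reads = min_median_reads,
                 count_convention = count_convention),
            class = "cleavage_params")
}

#' Per-bond cleavage counts from an end-count profile
#'
#' Alkaline fragmentation cleaves phosphodiester bonds; 2'-O-methylation of
#' the ribose of nucleotide \code{i} protects the bond 3' of \code{i}.
#' Bond \code{i} (between nucleotides \code{i} and \code{i + 1}) is
#' witnessed by fragment 3' ends at \code{i} and fragment 5' starts at
#' \code{i + 1}.
#'
#' @param profile An \code{end_count_profile}.
#' @param convention Counting convention; see \code{\link{cleavage_params}}.
#' @return A numeric vector of length \code{L - 1}: cleavage events per
#'   bond, indexed by the upstream nucleotide.
#' @export
cleavage_counts <- function(profile,
                            convention = c("ends_plus_nextstart",
                                           "starts_only", "ends_only")) {
  convention <- match.arg(convention)
  stopifnot(inherits(profile, "end_count_profile"))
  L <- profile$reference$length_nt
  E <- profile$ends3[-L]          # E_i, i = 1..L-1
  S <- profile$starts5[-1L]       # S_{i+1}
  switch(convention,
         ends_plus_nextstart = E + S,
         starts_only = S,
         ends_only = E)
}

flank_stats <- function(n, w) {
  # rolling mean and population SD over [i-w, i-1] (left) and [i+1, i+w]
  # (right) for each bond i; NA where the window leaves [1, length(n)]
  len <- length(n)
  cs <- c(0, cumsum(n))
  cs2 <- c(0, cumsum(n^2))
  win <- function(from, to) {
    ok <- from >= 1L & to <= len
    s <- s2 <- rep(NA_real_, len)
    s[ok] <- cs[to[ok] + 1L] - cs[from[ok]]
    s2[ok] <- cs2[to[ok] + 1L] - cs2[from[ok]]
    m <- s / w
    v <- pmax(s2 / w - m^2, 0)
    list(mean = m, sd = sqrt(v))
  }
  i <- seq_len(len)
  left <- win(i - w, i - 1L)
  right <- win(i + 1L, i + w)
  list(m_l = left$mean, s_l = left$sd, m_r = right$mean, s_r = right$sd)
}

#' Qualify positions by flank read depth
#'
#' A position qualifies for cleavage-protection scoring if the median of
#' the cleavage counts over the \code{2w} flanking bonds (the measured bond
#' excluded) is strictly greater than \code{min_median_reads} and the full
#' flank lies within bounds; edge positions are unqualified.
#'
#' @param n Cleavage count track (length \code{L - 1}).
#' @param params A \code{\link{cleavage_params}}.
#' @return Logical vector of length \code{length(n)}.
#' @export
qualify_positions <- function(n, params = cleavage_params()) {
  w <- params$flank_len
  len <- length(n)
  q <- rep(FALSE, len)
  if (len < 2L * w + 1L) return(q)
  idx <- (w + 1L):(len - w)
  med <- vapply(idx, function(i)
    stats::median(n[c((i - w):(i - 1L), (i + 1L):(i + w))]), numeric(1))
  q[idx] <- med > params$min_median_reads
  q
}

#' Cleavage-protection score (score A)
#'
#' For each qualified bond \code{i}, with \code{m_L, s_L} the mean and
#' population standard deviation of the cleavage counts over the left
#' flank \code{[i - w, i - 1]} and \code{m_R, s_R} over the right flank
#' \code{[i + 1, i + w]}:
#' \deqn{A_i = \max\left(0,\; 1 - \frac{2 n_i + 1}
#'   {\tfrac12\max(m_L - s_L, 0) + n_i + \tfrac12\max(m_R - s_R, 0) + 1}\right)}
#' A methylated (hydrolysis-resistant) bond has a cleavage deficit relative
#' to its flanks and scores near 1; an unprotected bond in a uniform
#' neighbourhood scores 0. Unqualified positions are \code{NA}.
#'
#' @param n Cleavage count track (length \code{L - 1}).
#' @param params A \code{\link{cleavage_params}}.
#' @return An object of class \code{score_track}: a list with
#'   \code{score_a} (numeric, \code{NA} where undefined), \code{qualified}
#'   (logical), flank statistics \code{m_l}, \code{s_l}, \code{m_r},
#'   \code{s_r} retained for audit, and \code{params}.
#' @export
score_a <- function(n, params = cleavage_params()) {
  w <- params$flank_len
  qual <- qualify_positions(n, params)
  fs <- flank_stats(n, w)
  denom <- 0.5 * pmax(fs$m_l - fs$s_l, 0) + n +
    0.5 * pmax(fs$m_r - fs$s_r, 0) + 1
  a <- pmax(0, 1 - (2 * n + 1) / denom)
  a[!qual] <- NA_real_
  structure(list(score_a = a, qualified = qual,
                 m_l = fs$m_l, s_l = fs$s_l, m_r = fs$m_r, s_r = fs$s_r,
                 params = params),
            class = "score_track")
}

#' RT-stop ratio track
#'
#' Under limiting dNTPs the reverse transcriptase stalls one nucleotide
#' downstream (3' in transcript sense) of a 2'-O-methylated site, leaving a
#' cDNA whose 5' end maps at \code{i + 1}. The per-position RT-stop ratio
#' is the fraction of reads covering the downstream position that start
#' there: \code{r_i = S[i+1] / C[i+1]}, defined only where
#' \code{C[i+1] > 0} (and never at the last position).
#'
#' @param profile An \code{end_count_profile}.
#' @return Numeric vector of length \code{L}; \code{NA} where undefined.
#' @export
rt_stop_ratio <- function(profile) {
  stopifnot(inherits(profile, "end_count_profile"))
  L <- profile$reference$length_nt
  S <- profile$starts5; C <- profile$coverage
  r <- rep(NA_real_, L)
  ok <- which(C[-1L] > 0)         # i such that C[i+1] > 0
  r[ok] <- S[ok + 1L] / C[ok + 1L]
  r
}

#' RT-stop fold change between low- and high-dNTP conditions
#'
#' \code{F_i = r_i(low) / r_i(high)} wherever both ratios are defined and
#' the high-dNTP ratio is positive; elsewhere undefined (never infinite).
#' Methylated sites enrich for stops under low dNTP, so \code{F >> 1}.
#'
#' @param low,high RT-stop ratio tracks from matched low/high dNTP
#'   libraries of the same reference and strand.
#' @return Numeric vector; \code{NA} where undefined.
#' @export
rt_stop_fold_change <- function(low, high) {
  if (length(low) != length(high))
    stop("low and high dNTP tracks have different lengths (",
         length(low), " vs ", length(high), ")")
  f <- low / high
  f[!is.finite(f) | is.na(low) | is.na(high) |
      (!is.na(high) & high == 0)] <- NA_real_
  f
}

#' Two-sample replicate comparison at one position
#'
#' Two-tailed Student's t test (pooled variance) comparing per-replicate
#' scores between two genotype groups, on the raw untransformed scores.
#' With zero pooled variance the test degenerates: equal means give
#' \code{p = 1}; unequal means are flagged degenerate with \code{p = 0}
#' and a warning.
#'
#' @param group_a,group_b Numeric vectors of per-replicate scores
#'   (\code{NA} = replicate undefined at this position).
#' @param position 1-based position (bookkeeping only).
#' @param method \code{"cleavage"} or \code{"rtstop"} (bookkeeping only).
#' @param alpha Significance level for the \code{significant} flag.
#' @return A one-row data frame with columns \code{position},
#'   \code{method}, \code{n_a}, \code{n_b}, \code{mean_a}, \code{mean_b},
#'   \code{t}, \code{p}, \code{testable}, \code{degenerate},
#'   \code{significant}.
#' @export
test_differential <- function(group_a, group_b, position = NA_integer_,
                              method = c("cleavage", "rtstop"),
                              alpha = 0.05) {
  method <- match.arg(method)
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  out <- data.frame(position = as.integer(position), method = method,
                    n_a = length(a), n_b = length(b),
                    mean_a = if (length(a)) mean(a) else NA_real_,
                    mean_b = if (length(b)) mean(b) else NA_real_,
                    t = NA_real_, p = NA_real_,
                    testable = FALSE, degenerate = FALSE,
                    significant = FALSE,
                    stringsAsFactors = FALSE)
  if (length(a) < 2L || length(b) < 2L) return(out)
  out$testable <- TRUE
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      out$t <- 0; out$p <- 1
    } else {
      out$t <- sign(mean(a) - mean(b)) * Inf
      out$p <- 0
      out$degenerate <- TRUE
      warning("zero pooled variance with unequal means at position ",
              position, " (", method, "): flagged degenerate-significant")
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
  }
  out$significant <- is.finite(out$p) && out$p < alpha
  out
}

group_profiles <- function(profiles, genotype, assay, dntp = NULL) {
  keep <- vapply(profiles, function(p) {
    m <- p$meta
    m$genotype == genotype && m$assay == assay &&
      (is.null(dntp) || m$dntp == dntp)
  }, logical(1))
  profiles[keep]
}

#' Transcriptome-wide differential methylation scan
#'
#' For each scoring method and each position qualified in enough
#' replicates, compares per-replicate scores between a knock-out genotype
#' and the parental genotype by two-tailed Student's t test. Cleavage
#' libraries contribute score A per replicate; RT-stop libraries
#' contribute the low/high dNTP fold change per replicate (each replicate
#' must have both dNTP conditions).
#'
#' @param profiles List of \code{end_count_profile} objects covering both
#'   genotypes (replicates distinguished by \code{meta$replicate}).
#' @param ko_genotype Knock-out genotype to contrast against
#'   \code{"parental"}.
#' @param params A \code{\link{cleavage_params}} (cleavage method only).
#' @param alpha Significance level on raw p-values.
#' @param methods Which scoring methods to run.
#' @param adjust If \code{TRUE} (default), append a Benjamini-Hochberg
#'   \code{q} column per method; raw p-values remain the primary output.
#' @param min_frag_len Smallest size-selected fragment length of the
#'   libraries (default 25 nt). RT-stop positions within this distance of
#'   the 3' terminus cannot receive fragment-boundary read starts and are
#'   left untested.
#' @return A data frame of per-position calls (one row per tested position
#'   and method), sorted by position, with the columns of
#'   \code{\link{test_differential}} plus \code{q} when \code{adjust}.
#'   Group a is parental, group b the knock-out. Empty input gives an
#'   empty table.
#' @export
scan_transcriptome <- function(profiles, ko_genotype,
                               params = cleavage_params(), alpha = 0.05,
                               methods = c("cleavage", "rtstop"),
                               adjust = TRUE, min_frag_len = 25L) {
  methods <- match.arg(methods, several.ok = TRUE)
  empty <- test_differential(numeric(0), numeric(0))[0, ]
  if (adjust) empty$q <- numeric(0)
  if (!length(profiles)) return(empty)

  res <- list()
  if ("cleavage" %in% methods) {
    scores <- function(genotype) {
      ps <- group_profiles(profiles, genotype, "cleavage")
      if (!length(ps)) return(NULL)
      sapply(ps, function(p)
        score_a(cleavage_counts(p, params$count_convention), params)$score_a)
    }
    sa <- scores("parental"); sb <- scores(ko_genotype)
    if (!is.null(sa) && !is.null(sb))
      res$cleavage <- scan_matrix(sa, sb, "cleavage", alpha,
                                  position_offset = 0L)
  }
  if ("rtstop" %in% methods) {
    folds <- function(genotype) {
      lows <- group_profiles(profiles, genotype, "rtstop", "low")
      highs <- group_profiles(profiles, genotype, "rtstop", "high")
      if (!length(lows) && !length(highs)) return(NULL)
      reps_low <- vapply(lows, function(p) p$meta$replicate, integer(1))
      reps_high <- vapply(highs, function(p) p$meta$replicate, integer(1))
      miss <- setdiff(union(reps_low, reps_high),
                      intersect(reps_low, reps_high))
      if (length(miss)) {
        ids <- vapply(c(lows, highs)[match(miss, c(reps_low, reps_high))],
                      function(p) p$meta$sample_id, character(1))
        stop("rtstop replicate(s) missing a dNTP partner: ",
             paste(ids, collapse = ", "))
      }
      sapply(sort(intersect(reps_low, reps_high)), function(r) {
        lo <- lows[[match(r, reps_low)]]
        hi <- highs[[match(r, reps_high)]]
        f <- rt_stop_fold_change(rt_stop_ratio(lo), rt_stop_ratio(hi))
        # depth qualification: the stop-position coverage must exceed the
        # same read-depth threshold the cleavage score uses, in both dNTP
        # conditions, or the ratio estimate is unstable
        L <- lo$reference$length_nt
        deep <- c(lo$coverage[-1L] > params$min_median_reads, FALSE) &
          c(hi$coverage[-1L] > params$min_median_reads, FALSE)
        # positions closer than the smallest size-selected fragment to the
        # 3' terminus receive no fragment-boundary 5' starts, so their stop
        # ratios rest on rare drop-off events; structurally unqualified
        if (min_frag_len > 0L && L > min_frag_len)
          deep[(L - min_frag_len + 1L):L] <- FALSE
        f[!deep] <- NA_real_
        f
      })
    }
    fa <- folds("parental"); fb <- folds(ko_genotype)
    if (!is.null(fa) && !is.null(fb))
      res$rtstop <- scan_matrix(fa, fb, "rtstop", alpha,
                                position_offset = 0L)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  if (adjust && nrow(out)) {
    out$q <- NA_real_
    for (m in unique(out$method)) {
      i <- out$method == m
      out$q[i] <- stats::p.adjust(out$p[i], method = "BH")
    }
  }
  out <- out[order(out$position, out$method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_matrix <- function(sa, sb, method, alpha, position_offset = 0L) {
  # sa, sb: position x replicate score matrices (NA = undefined)
  testable <- rowSums(!is.na(sa)) >= 2L & rowSums(!is.na(sb)) >= 2L
  idx <- which(testable)
  if (!length(idx)) return(NULL)
  rows <- lapply(idx, function(i)
    suppressWarnings(
      test_differential(sa[i, ], sb[i, ],
                        position = i + position_offset,
                        method = method, alpha = alpha)))
  do.call(rbind, rows)
}
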