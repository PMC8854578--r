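#' Planted simulation ground truth
#'
#' Bundles the features every generator plants so recovery tests can
#' assert against them: methylated sites (with cleavage protection and
#' condition-specific RT stop efficiencies), per-gene footprint occupancy
#' factors, and SILAC effects.
#'
#' @param sites Data frame with columns \code{position},
#'   \code{protection} (in [0, 1]; 1 = the bond 3' of the site is never
#'   cleaved), \code{q_low}, \code{q_high} (RT stall probabilities at the
#'   site under low/high dNTP, in [0, 1]). Empty by default. A warning is
#'   given when \code{q_low < q_high}, which contradicts the assay premise
#'   (stalling is elicited by limiting dNTPs).
#' @param occupancy_factors Named numeric vector of per-gene occupancy
#'   factors for footprint simulation.
#' @param mixing_bias Positive SILAC mixing bias \code{b}.
#' @param subunit_effect mtLSU log2 enrichment effect \code{e}.
#' @return An object of class \code{sim_truth}.
#' @export
sim_truth <- function(sites = data.frame(position = integer(0),
                                         protection = numeric(0),
                                         q_low = numeric(0),
                                         q_high = numeric(0)),
                      occupancy_factors = NULL,
                      mixing_bias = 1, subunit_effect = 0) {
  stopifnot(is.data.frame(sites),
            all(c("position", "protection", "q_low", "q_high") %in%
                  names(sites)))
  if (nrow(sites)) {
    stopifnot(all(sites$protection >= 0 & sites$protection <= 1),
              all(sites$q_low >= 0 & sites$q_low <= 1),
              all(sites$q_high >= 0 & sites$q_high <= 1))
    if (any(sites$q_low < sites$q_high))
      warning("q_low < q_high at site(s) ",
              paste(sites$position[sites$q_low < sites$q_high],
                    collapse = ", "),
              ": contradicts the low-dNTP stalling premise")
  }
  stopifnot(mixing_bias > 0)
  structure(list(sites = sites, occupancy_factors = occupancy_factors,
                 mixing_bias = mixing_bias,
                 subunit_effect = subunit_effect),
            class = "sim_truth")
}

sample_fragments <- function(n_frag, weights, frag_len, max_batches = 200L) {
  # weights over cut points 0..L (index 1..L+1); a fragment is the span
  # between two cut points a < b, i.e. positions a+1..b, length b - a
  L <- length(weights) - 1L
  keep_s <- integer(0); keep_e <- integer(0)
  batch <- max(n_frag, 1000L)
  for (it in seq_len(max_batches)) {
    if (length(keep_s) >= n_frag) break
    a <- sample.int(L + 1L, batch, replace = TRUE, prob = weights) - 1L
    b <- sample.int(L + 1L, batch, replace = TRUE, prob = weights) - 1L
    lo <- pmin(a, b); hi <- pmax(a, b)
    len <- hi - lo
    ok <- len >= frag_len[1L] & len <= frag_len[2L]
    keep_s <- c(keep_s, lo[ok] + 1L)
    keep_e <- c(keep_e, hi[ok])
  }
  if (length(keep_s) < n_frag)
    stop("could not draw enough in-range fragments; widen 'frag_len' or ",
         "relax the cut-weight distribution")
  data.frame(start = keep_s[seq_len(n_frag)], end = keep_e[seq_len(n_frag)])
}

bond_weights <- function(L, phi, truth, rng_drawn = TRUE) {
  # mean-1 gamma heterogeneity over interior bonds 1..L-1 (variance phi),
  # protection multiplies the weight by (1 - p); terminal cut points
  # (molecule ends) have unit weight
  u <- if (phi > 0 && rng_drawn)
    stats::rgamma(L - 1L, shape = 1 / phi, scale = phi) else rep(1, L - 1L)
  if (nrow(truth$sites)) {
    pos <- truth$sites$position
    stopifnot(all(pos >= 1L & pos <= L - 1L))
    u[pos] <- u[pos] * (1 - truth$sites$protection)
  }
  c(1, u, 1)   # cut points 0, 1..L-1, L
}

#' Simulate alkaline-fragmentation (cleavage) sequencing replicates
#'
#' Per-bond cleavage propensities are mean-1 gamma draws (variance
#' \code{phi}; \code{phi = 0} gives uniform hydrolysis), multiplied by
#' \code{1 - protection} at planted methylated bonds. Each sequenced
#' fragment is the span between two cut points sampled from that weight
#' distribution, accepted when its length falls in \code{frag_len}.
#' Deterministic given \code{seed}; the heterogeneity field is drawn once
#' and shared across replicates (it emulates sequence-dependent
#' hydrolysis, a property of the molecule, not of the library).
#'
#' @param L Reference length in nt.
#' @param n_frag Fragments per replicate library.
#' @param truth A \code{\link{sim_truth}}; sites must lie in
#'   \code{[1, L - 1]}.
#' @param phi Per-bond heterogeneity dispersion (variance of the mean-1
#'   gamma), default 0.3.
#' @param frag_len Accepted fragment length range, default 25-55 nt.
#' @param replicates Number of replicate libraries.
#' @param seed Integer master seed; replicate r uses substream
#'   \code{seed * 1000 + r}.
#' @param hetero_seed Seed for the per-bond heterogeneity field. It
#'   defaults to \code{seed}, but libraries of different genotypes over
#'   the same transcript should share it (sequence-dependent hydrolysis
#'   is a property of the RNA, not of the sample).
#' @param genotype,sample_prefix Metadata for the emitted profiles.
#' @return List of \code{end_count_profile}s, one per replicate.
#' @export
simulate_cleavage_profiles <- function(L, n_frag, truth = sim_truth(),
                                       phi = 0.3, frag_len = c(25L, 55L),
                                       replicates = 3L, seed = 1L,
                                       hetero_seed = seed,
                                       genotype = "parental",
                                       sample_prefix = "sim_cleavage") {
  stopifnot(frag_len[1L] <= frag_len[2L], n_frag > 0, phi >= 0)
  ref <- reference_index("sim", L)
  set.seed(hetero_seed)
  w <- bond_weights(L, phi, truth)
  lapply(seq_len(replicates), function(r) {
    set.seed((as.numeric(seed) * 1000 + r) %% .Machine$integer.max)
    fr <- sample_fragments(n_frag, w, frag_len)
    fr$strand <- "+"
    count_read_ends(fr, ref, "plus",
                    library_meta(sprintf("%s_%s_rep%d", sample_prefix,
                                         genotype, r),
                                 genotype = genotype, assay = "cleavage",
                                 replicate = r))
  })
}

#' Simulate an RT-stop (low/high dNTP) sequencing library
#'
#' Template molecules are random fragments (uniform hydrolysis); reverse
#' transcription enters at each fragment's 3' end and walks towards its
#' 5' end, failing with per-nucleotide background drop-off \code{dropoff}
#' and, when attempting to read through a planted methylated site
#' \code{i}, stalling with probability \code{q_low} or \code{q_high}
#' according to \code{condition}. A stall at site \code{i} leaves a cDNA
#' whose 5' end maps at \code{i + 1}, so fragmentation ends and
#' stall-generated starts coexist in the emitted profile, which satisfies
#' the coverage identity by construction.
#'
#' @param L,n_frag,truth,frag_len,seed As in
#'   \code{\link{simulate_cleavage_profiles}}.
#' @param condition \code{"low"} or \code{"high"} dNTP.
#' @param dropoff Background per-nucleotide drop-off probability.
#' @param genotype,replicate,sample_prefix Metadata.
#' @return An \code{end_count_profile} with \code{assay = "rtstop"}.
#' @export
simulate_rtstop_profiles <- function(L, n_frag, truth = sim_truth(),
                                     condition = c("low", "high"),
                                     dropoff = 0.001,
                                     frag_len = c(25L, 55L), seed = 1L,
                                     genotype = "parental", replicate = 1L,
                                     sample_prefix = "sim_rtstop") {
  condition <- match.arg(condition)
  stopifnot(dropoff >= 0, dropoff < 1)
  ref <- reference_index("sim", L)
  set.seed(seed)
  w <- bond_weights(L, 0, truth, rng_drawn = FALSE)
  w[] <- 1   # fragmentation in this assay is modelled as uniform
  fr <- sample_fragments(n_frag, w, frag_len)

  sites <- truth$sites
  q <- if (condition == "low") sites$q_low else sites$q_high
  # first failing RT step for each molecule: background geometric vs
  # site-specific stalls; step k extends coverage from e-k+1 to e-k
  e <- fr$end; s <- fr$start
  span <- e - s
  fail_bg <- if (dropoff > 0)
    stats::rgeom(length(e), dropoff) + 1L else rep(Inf, length(e))
  first_fail <- fail_bg
  if (nrow(sites)) {
    for (j in seq_len(nrow(sites))) {
      i <- sites$position[j]
      k_i <- e - i                       # step that reads through site i
      applicable <- k_i >= 1L & k_i <= span
      stalled <- applicable &
        stats::runif(length(e)) < q[j]
      first_fail <- ifelse(stalled, pmin(first_fail, k_i), first_fail)
    }
  }
  read_start <- ifelse(first_fail > span, s, e - first_fail + 1L)
  al <- data.frame(start = as.integer(read_start), end = e, strand = "+")
  count_read_ends(al, ref, "plus",
                  library_meta(sprintf("%s_%s_%s_rep%d", sample_prefix,
                                       genotype, condition, replicate),
                               genotype = genotype, assay = "rtstop",
                               dntp = condition, replicate = replicate))
}

allowed_offsets <- function(g, start_window, stop_window) {
  len <- g$cds_end - g$cds_start + 1L
  if (len <= start_window + stop_window) return(integer(0))
  if (g$strand == "+") {
    (g$cds_start + start_window):(g$cds_end - stop_window)
  } else {
    (g$cds_start + stop_window):(g$cds_end - start_window)
  }
}

#' Simulate a mitoribosome footprint library
#'
#' Per-gene expected read counts are proportional to the length of the
#' allowed CDS interval (outside the initiation/termination exclusion
#' windows), the gene's planted occupancy factor and the library scale;
#' realised counts are Poisson and 5' positions uniform over the allowed
#' interval. Footprint lengths are uniform over \code{fp_len}
#' (size-selected libraries). Deterministic given \code{seed}.
#'
#' @param annotation An \code{mt_annotation}.
#' @param truth A \code{\link{sim_truth}} whose \code{occupancy_factors}
#'   name every mRNA gene (missing genes default to 1).
#' @param scale Expected reads per allowed CDS nucleotide at factor 1.
#' @param normaliser Positive-sense nuclear-mRNA read count emitted with
#'   the library (the RPM denominator).
#' @param fp_len Footprint length range, default 25-35 nt.
#' @param start_window,stop_window Exclusion windows matching the
#'   downstream filter, defaults 15 and 45 nt.
#' @param seed Integer seed.
#' @return List with \code{reads} (data frame: five_prime_pos, length,
#'   strand) and \code{normaliser}.
#' @export
simulate_footprint_library <- function(annotation, truth, scale,
                                       normaliser, fp_len = c(25L, 35L),
                                       start_window = 15L,
                                       stop_window = 45L, seed = 1L) {
  stopifnot(inherits(annotation, "mt_annotation"),
            scale >= 0, normaliser > 0)
  set.seed(seed)
  genes <- annotation$genes[annotation$genes$category == "mRNA", ]
  fac <- truth$occupancy_factors
  reads <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    f <- if (!is.null(fac) && g$gene %in% names(fac)) fac[[g$gene]] else 1
    stopifnot(f >= 0)
    off <- allowed_offsets(g, start_window, stop_window)
    n <- stats::rpois(1L, scale * length(off) * f)
    if (n == 0L || !length(off)) return(NULL)
    data.frame(five_prime_pos = sample(off, n, replace = TRUE),
               length = sample(fp_len[1L]:fp_len[2L], n, replace = TRUE),
               strand = g$strand, stringsAsFactors = FALSE)
  })
  reads <- do.call(rbind, reads)
  if (is.null(reads))
    reads <- data.frame(five_prime_pos = integer(0), length = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  list(reads = reads, normaliser = normaliser)
}

#' Simulate a reciprocal-labelling SILAC ratio table
#'
#' Log2 heavy/light ratios are the mtLSU subunit effect (for mtLSU
#' proteins; 0 otherwise) plus the log2 mixing bias plus gaussian noise;
#' the swapped label orientation carries the subunit effect with opposite
#' sign (the bias does not flip: it reflects how much of each labelled
#' population entered the mix). The emitted whole-cell median equals the
#' mixing bias, so correcting with it exactly inverts the bias at zero
#' noise.
#'
#' @param truth A \code{\link{sim_truth}} providing \code{mixing_bias}
#'   and \code{subunit_effect}.
#' @param n_per_subunit Named counts of proteins per subunit class,
#'   default \code{c(mtSSU = 30, mtLSU = 50, other = 40)}.
#' @param noise_sd Gaussian log2 noise SD, >= 0.
#' @param seed Integer seed.
#' @return List with \code{table} (data frame: protein, subunit,
#'   fraction, orientation, ratio) and \code{whole_cell_median}.
#' @export
simulate_silac_table <- function(truth,
                                 n_per_subunit = c(mtSSU = 30L,
                                                   mtLSU = 50L,
                                                   other = 40L),
                                 noise_sd = 0.2, seed = 1L) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  subunits <- rep(names(n_per_subunit), n_per_subunit)
  proteins <- paste0(subunits, "_", unlist(lapply(n_per_subunit, seq_len)))
  e <- ifelse(subunits == "mtLSU", truth$subunit_effect, 0)
  lb <- log2(truth$mixing_bias)
  n <- length(proteins)
  tab <- rbind(
    data.frame(protein = proteins, subunit = subunits, fraction = 1L,
               orientation = "forward",
               ratio = 2^(e + lb + stats::rnorm(n, sd = noise_sd)),
               stringsAsFactors = FALSE),
    data.frame(protein = proteins, subunit = subunits, fraction = 1L,
               orientation = "swapped",
               ratio = 2^(-e + lb + stats::rnorm(n, sd = noise_sd)),
               stringsAsFactors = FALSE))
  list(table = tab, whole_cell_median = truth$mixing_bias)
}
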