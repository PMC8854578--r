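# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately avoid the package's vectorised code paths.

# per-position tally of interval membership and endpoints
brute_force_profile <- function(starts, ends, L) {
  cov <- s5 <- e3 <- integer(L)
  for (k in seq_along(starts)) {
    s5[starts[k]] <- s5[starts[k]] + 1L
    e3[ends[k]] <- e3[ends[k]] + 1L
    for (j in starts[k]:ends[k]) cov[j] <- cov[j] + 1L
  }
  list(coverage = cov, starts5 = s5, ends3 = e3)
}

# literal per-position re-implementation of the cleavage-protection score
brute_force_score_a <- function(n, w = 6L, min_median = 15) {
  len <- length(n)
  a <- rep(NA_real_, len)
  for (i in seq_len(len)) {
    if (i - w < 1L || i + w > len) next
    flank <- n[c((i - w):(i - 1L), (i + 1L):(i + w))]
    if (!(median(flank) > min_median)) next
    left <- n[(i - w):(i - 1L)]
    right <- n[(i + 1L):(i + w)]
    pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
    m_l <- mean(left); s_l <- pop_sd(left)
    m_r <- mean(right); s_r <- pop_sd(right)
    a[i] <- max(0, 1 - (2 * n[i] + 1) /
                  (0.5 * max(m_l - s_l, 0) + n[i] +
                     0.5 * max(m_r - s_r, 0) + 1))
  }
  a
}

# textbook pooled-variance two-sample t-test via the t CDF
brute_force_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  list(t = t, p = p)
}

random_profile <- function(L, n_reads, seed, max_len = 55L) {
  set.seed(seed)
  starts <- sample.int(L - max_len, n_reads, replace = TRUE)
  lens <- sample(25:max_len, n_reads, replace = TRUE)
  data.frame(start = starts, end = starts + lens - 1L, strand = "+")
}

toy_meta <- function(id = "toy", assay = "cleavage",
                     dntp = if (assay == "rtstop") "low" else "not_applicable",
                     replicate = 1L, genotype = "parental") {
  library_meta(id, genotype = genotype, assay = assay, dntp = dntp,
               replicate = replicate)
}

# single-CDS toy annotation on a bare reference, plus strand
toy_annotation <- function(cds_start = 1L, cds_end = 300L, gene = "G1") {
  structure(list(
    genes = data.frame(gene = gene, category = "mRNA", strand = "+",
                       cds_start = cds_start, cds_end = cds_end,
                       stringsAsFactors = FALSE),
    overlaps = data.frame(gene_a = character(0), gene_b = character(0),
                          start = integer(0), end = integer(0))),
    class = "mt_annotation")
}

# profile collection for a two-genotype contrast, both assays
simulate_contrast <- function(L, n_frag, truth_par, truth_ko, seed,
                              hetero_seed = seed, replicates = 3L) {
  prof <- c(
    simulate_cleavage_profiles(L, n_frag, truth_par, seed = seed,
                               hetero_seed = hetero_seed,
                               genotype = "parental",
                               replicates = replicates),
    simulate_cleavage_profiles(L, n_frag, truth_ko, seed = seed + 37,
                               hetero_seed = hetero_seed,
                               genotype = "MRM2_KO",
                               replicates = replicates))
  for (r in seq_len(replicates)) {
    prof <- c(prof, list(
      simulate_rtstop_profiles(L, n_frag, truth_par, "low",
                               seed = seed + 100 + r,
                               genotype = "parental", replicate = r),
      simulate_rtstop_profiles(L, n_frag, truth_par, "high",
                               seed = seed + 200 + r,
                               genotype = "parental", replicate = r),
      simulate_rtstop_profiles(L, n_frag, truth_ko, "low",
                               seed = seed + 300 + r,
                               genotype = "MRM2_KO", replicate = r),
      simulate_rtstop_profiles(L, n_frag, truth_ko, "high",
                               seed = seed + 400 + r,
                               genotype = "MRM2_KO", replicate = r)))
  }
  prof
}
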