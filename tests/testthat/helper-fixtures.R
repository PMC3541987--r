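# Shared fixtures and independent oracles for the test-suite. Oracles here
# are deliberately naive (exhaustive enumeration, double loops) so they stay
# independent of the implementation paths they check.

# score one RET/UPD state path left-to-right, the same accumulation order the
# exhaustive enumerator uses, so maxima compare exactly
score_path <- function(states, calls, positions, params,
                       het_rate = params$het_rate) {
  idx <- match(states, c("RET", "UPD"))
  lp0 <- log(c(1 - params$prior_upd, params$prior_upd))
  e <- rbind(emission_logprob(calls, "RET", params, het_rate),
             emission_logprob(calls, "UPD", params, het_rate))
  acc <- lp0[idx[1]] + e[idx[1], 1]
  if (length(states) > 1) {
    for (t in 2:length(states)) {
      tm <- transition_probs(positions[t] - positions[t - 1], params)
      acc <- acc + log(tm[idx[t - 1], idx[t]]) + e[idx[t], t]
    }
  }
  acc
}

# exhaustive-enumeration maximum over all 2^n state paths
brute_force_max_logprob <- function(calls, positions, params,
                                    het_rate = params$het_rate) {
  n <- length(calls)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  lp0 <- log(c(1 - params$prior_upd, params$prior_upd))
  e <- rbind(emission_logprob(calls, "RET", params, het_rate),
             emission_logprob(calls, "UPD", params, het_rate))
  acc <- lp0[paths[, 1]] + e[cbind(paths[, 1], 1)]
  if (n > 1) {
    for (t in 2:n) {
      tm <- log(transition_probs(positions[t] - positions[t - 1], params))
      acc <- acc + tm[cbind(paths[, t - 1], paths[, t])] +
        e[cbind(paths[, t], t)]
    }
  }
  max(acc)
}

# brute-force recurrence: double loop over samples x bands, >= 1 bp overlap
brute_force_band_frequency <- function(segments, manifest, genome) {
  bands <- genome$cytobands
  seg <- segments[segments$status == "aUPD", , drop = FALSE]
  freq <- numeric(nrow(bands))
  for (i in seq_len(nrow(bands))) {
    hit <- 0L
    for (sid in manifest$sample_id) {
      s <- seg[seg$sample_id == sid & seg$chrom == bands$chrom[i], ,
               drop = FALSE]
      any_ov <- FALSE
      for (j in seq_len(nrow(s)))
        if (min(s$end[j], bands$end[i]) - max(s$start[j], bands$start[i]) > 0)
          any_ov <- TRUE
      if (any_ov) hit <- hit + 1L
    }
    freq[i] <- hit / nrow(manifest)
  }
  data.frame(chrom = bands$chrom, band = bands$band, frequency = freq)
}

# small rendered cohort on the toy genome
make_test_cohort <- function(seed = 101, n_markers = 1200,
                             specs = demo_subtype_specs(), ...) {
  cfg <- simulation_config(genome = toy_genome(),
                           markers_per_chromosome = n_markers,
                           subtype_specs = specs, seed = seed, ...)
  list(config = cfg, cohort = simulate_cohort(cfg))
}

# random classified segment table for recurrence/statistics tests
random_segments <- function(n_samples, genome, seed, max_per_sample = 3) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_samples)) {
    k <- sample(0:max_per_sample, 1)
    for (j in seq_len(k)) {
      ci <- sample(nrow(genome$chromosomes), 1)
      len <- genome$chromosomes$length[ci]
      b <- sort(floor(runif(2, 0, len)))
      if (b[2] - b[1] < 1e6) next
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("S%03d", i),
        chrom = genome$chromosomes$chrom[ci],
        start = b[1], end = b[2], n_markers = 100L, n_het_markers = 1L,
        mean_logr = 0, status = "aUPD",
        class = sample(c("whole", "telomeric", "centromeric"), 1))
    }
  }
  if (!length(rows)) return(aupdscan:::empty_segments())
  do.call(rbind, rows)
}

manifest_for <- function(n_samples, subtype = "fixture",
                         translocation_class = "non_translocation") {
  data.frame(sample_id = sprintf("S%03d", seq_len(n_samples)),
             subtype = subtype, translocation_class = translocation_class,
             file = NA_character_)
}
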