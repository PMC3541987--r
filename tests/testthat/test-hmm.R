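test_that("emission probabilities are normalized and match closed forms", {
  p <- hmm_params(het_rate = 0.30, upd_het_leak = 0.02, no_call_rate = 0.02)
  for (st in c("RET", "UPD")) {
    probs <- exp(emission_logprob(c("Het", "Hom", "NoCall"), st, p))
    expect_equal(sum(probs), 1)
  }
  p0 <- hmm_params(het_rate = 0.30, no_call_rate = 0)
  expect_equal(exp(emission_logprob("Het", "RET", p0)), 0.30)
  expect_equal(exp(emission_logprob("Het", "UPD", p)), 0.02 * 0.98)
  expect_error(emission_logprob("Weird", "RET", p), "call")
})

test_that("transitions interpolate identity and stationarity with distance", {
  p <- hmm_params(prior_upd = 0.01, decay_length = 1e7)
  expect_equal(transition_probs(0, p), diag(2), ignore_attr = TRUE)
  far <- transition_probs(1e12, p)
  expect_equal(far[1, ], far[2, ])
  expect_equal(unname(far[1, ]), c(0.99, 0.01))
  # one decay length: P(RET -> UPD) = (1 - exp(-1)) * prior
  m <- transition_probs(1e7, p)
  expect_equal(m["RET", "UPD"], (1 - exp(-1)) * 0.01)
  expect_equal(rowSums(m), c(RET = 1, UPD = 1))
})

test_that("viterbi matches exhaustive enumeration on short random sequences", {
  p <- hmm_params()
  set.seed(2024)
  for (rep in 1:300) {
    n <- sample(1:12, 1)
    positions <- sort(sample.int(5e7, n))
    calls <- sample(c("Het", "Hom", "NoCall"), n, replace = TRUE,
                    prob = c(0.3, 0.6, 0.1))
    path <- viterbi_decode(calls, positions, p)
    expect_identical(score_path(path, calls, positions, p),
                     brute_force_max_logprob(calls, positions, p))
  }
})

test_that("viterbi recovers an embedded homozygous block and prefers RET on all-het input", {
  p <- hmm_params()
  # all heterozygous: RET everywhere
  pos <- seq(0, by = 2e4, length.out = 300)
  expect_true(all(viterbi_decode(rep("Het", 300), pos, p) == "RET"))
  # 200 Hom markers flanked by het-rich runs decode as one UPD block
  calls <- c(rep(c("Het", "Hom", "Hom"), 50),
             rep("Hom", 200),
             rep(c("Het", "Hom", "Hom"), 50))
  pos <- seq(0, by = 2e4, length.out = length(calls))
  path <- viterbi_decode(calls, pos, p)
  block <- 151:350
  expect_true(all(path[block] == "UPD"))
  expect_true(all(path[1:120] == "RET"))
  expect_error(viterbi_decode(c("Het", "Het"), c(10, 10), p), "increasing")
})

test_that("segments are maximal UPD runs with marker and length floors", {
  p <- hmm_params(min_markers = 25, min_length = 1e6)
  pos <- seq(0, by = 1e5, length.out = 100)
  path <- rep("RET", 100)
  expect_equal(nrow(segments_from_path(path, pos, rep("Hom", 100), p)), 0L)
  # 24-marker run is dropped at min_markers = 25
  path[10:33] <- "UPD"
  expect_equal(nrow(segments_from_path(path, pos, rep("Hom", 100), p)), 0L)
  # a single intervening RET marker keeps two runs separate
  path <- rep("RET", 100)
  path[10:39] <- "UPD"; path[41:70] <- "UPD"
  seg <- segments_from_path(path, pos, rep("Hom", 100), p)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$n_markers, c(30L, 30L))
  expect_equal(seg$start, pos[c(10, 41)])
  expect_equal(seg$end, pos[c(39, 70)] + 1)
})

test_that("copy-neutrality filter separates aUPD, deletion-LOH and rejects gains", {
  p <- hmm_params(neutral_band = 0.3, deletion_threshold = -0.8)
  expect_equal(loh_status(0, p), "aUPD")
  expect_equal(loh_status(-1.0, p), "deletion_LOH")
  expect_equal(loh_status(0.5, p), "rejected")
  expect_equal(loh_status(c(0.29, -0.31, -0.85), p),
               c("aUPD", "rejected", "deletion_LOH"))
  expect_error(loh_status(numeric(0), p), "markers")
})

test_that("noise-free samples are recovered exactly in both calling modes", {
  cfg <- simulation_config(markers_per_chromosome = 3000,
                           genotype_error = 0, no_call_rate = 0)
  germ <- simulate_germline(cfg, 55)
  ev <- data.frame(chrom = "chr1", start = 20e6, end = 40e6,
                   mechanism = "interstitial", parent = "paternal")
  set.seed(55)
  m <- render_sample(germ, ev, NULL, cfg)
  p <- hmm_params()
  for (mode in c("paired", "unpaired")) {
    seg <- call_sample(m, p, mode, sample_id = "t1")
    seg <- seg[seg$status == "aUPD", ]
    expect_equal(nrow(seg), 1L)
    # the called interval contains every het marker planted inside the event
    hets <- m$pos[m$chrom == "chr1" & m$gt_normal == "AB" &
                    m$pos >= 20e6 & m$pos < 40e6]
    expect_true(all(hets >= seg$start & hets < seg$end))
    # and its boundaries sit within one inter-het spacing of the truth
    expect_lt(abs(seg$start - 20e6), 1e6)
    expect_lt(abs(seg$end - 40e6), 1e6)
  }
})

test_that("calls are invariant to marker row order and empty cohorts work", {
  cc <- make_test_cohort(seed = 61, n_markers = 800)
  m <- cc$cohort$samples[[2]]
  p <- hmm_params()
  a <- call_sample(m, p, "unpaired", "x")
  set.seed(99)
  b <- call_sample(m[sample(nrow(m)), ], p, "unpaired", "x")
  expect_equal(a, b, ignore_attr = TRUE)

  empty <- data.frame(sample_id = character(0), subtype = character(0),
                      translocation_class = character(0),
                      file = character(0))
  expect_equal(nrow(call_cohort(empty, p, "unpaired", samples = list())), 0L)

  no_normal <- m
  no_normal$gt_normal <- NA_character_
  expect_error(call_sample(no_normal, p, "paired"), "gt_normal")
})

test_that("recall never improves when genotype error grows", {
  p <- hmm_params()
  recalls <- sapply(c(0.0, 0.05, 0.12), function(eps) {
    mean(sapply(1:12, function(s) {
      cfg <- simulation_config(markers_per_chromosome = 1000,
                               subtype_specs = data.frame(
                                 subtype = "grp",
                                 translocation_class = "non_translocation",
                                 n_samples = 3L, aupd_prevalence = 1,
                                 events_per_positive = 2),
                               genotype_error = eps, seed = 700 + s)
      coh <- simulate_cohort(cfg)
      segs <- call_cohort(coh$manifest, p, "unpaired",
                          samples = coh$samples)
      segs <- classify_segments(segs, cfg$genome, markers = coh$samples)
      recovery_stats(coh$truth, segs, coh$samples)$recall
    }))
  })
  expect_true(all(diff(recalls) <= 0.02 + 1e-9))
})

test_that("paired-mode breakpoints land within five informative-marker spacings", {
  cc <- make_test_cohort(seed = 66, n_markers = 2500,
                         specs = data.frame(
                           subtype = "grp",
                           translocation_class = "non_translocation",
                           n_samples = 12L, aupd_prevalence = 1,
                           events_per_positive = 2))
  coh <- cc$cohort
  p <- hmm_params()
  segs <- call_cohort(coh$manifest, p, "paired", samples = coh$samples)
  segs <- classify_segments(segs, cc$config$genome, markers = coh$samples)
  rs <- recovery_stats(coh$truth, segs, coh$samples,
                       boundary_marker_set = "normal_het")
  expect_gte(rs$recall, 0.9)
  expect_gte(mean(rs$boundary_errors <= 5), 0.9)
})
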