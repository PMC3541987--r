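test_that("single-sample maps behave like indicators and dedup within sample", {
  g <- toy_genome()
  man <- manifest_for(1)
  seg <- data.frame(sample_id = "S001", chrom = "chr1",
                    start = 2e6, end = 10e6, n_markers = 50L,
                    n_het_markers = 0L, mean_logr = 0, status = "aUPD",
                    class = "centromeric")
  m <- band_frequency_map(seg, man, g)
  expect_equal(m$frequency[m$region == "1p14"], 1)
  expect_true(all(m$frequency[m$region != "1p14"] == 0))

  # two segments in the same band still count the sample once
  seg2 <- rbind(seg, transform(seg, start = 11e6, end = 14e6))
  m2 <- band_frequency_map(seg2, man, g)
  expect_equal(m2$n_samples_hit[m2$region == "1p14"], 1L)
})

test_that("band frequencies equal the brute-force sample-by-band double loop", {
  g <- toy_genome()
  for (seed in c(11, 12, 13)) {
    man <- manifest_for(20)
    segs <- random_segments(20, g, seed = seed)
    mine <- band_frequency_map(segs, man, g)
    ref <- brute_force_band_frequency(segs, man, g)
    expect_equal(mine$frequency, ref$frequency)
    expect_true(all(mine$frequency >= 0 & mine$frequency <= 1))
  }
})

test_that("frequencies are invariant to splitting a segment into abutting halves", {
  g <- toy_genome()
  man <- manifest_for(5)
  segs <- random_segments(5, g, seed = 21)
  split_at_mid <- function(s) {
    mid <- floor((s$start + s$end) / 2)
    rbind(transform(s, end = mid), transform(s, start = mid))
  }
  segs_split <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i)
    split_at_mid(segs[i, ])))
  expect_equal(band_frequency_map(segs, man, g)$frequency,
               band_frequency_map(segs_split, man, g)$frequency)
})

test_that("arm map aggregates bands and a centromere-spanning segment hits both arms", {
  g <- toy_genome()
  man <- manifest_for(1)
  seg <- data.frame(sample_id = "S001", chrom = "chr2",
                    start = 30e6, end = 50e6, n_markers = 50L,
                    n_het_markers = 0L, mean_logr = 0, status = "aUPD",
                    class = "centromeric")
  arms <- arm_frequency_map(seg, man, g)
  expect_equal(arms$frequency[arms$region %in% c("2p", "2q")], c(1, 1))
  expect_true(all(arms$frequency[!arms$region %in% c("2p", "2q")] == 0))

  # empty segment table: all zero
  arms0 <- arm_frequency_map(aupdscan:::empty_segments(), man, g)
  expect_true(all(arms0$frequency == 0))

  # arm hit = OR over the arm's band hits, sample by sample (aggregation
  # oracle against the band-level double loop)
  segs <- random_segments(15, g, seed = 31)
  man15 <- manifest_for(15)
  arms15 <- arm_frequency_map(segs, man15, g)
  for (i in seq_len(nrow(arms15))) {
    cb <- g$cytobands[g$cytobands$chrom == arms15$chrom[i] &
                        g$cytobands$arm ==
                          sub("^[0-9]+", "", arms15$region[i]), ]
    hit <- 0L
    for (sid in man15$sample_id) {
      s <- segs[segs$sample_id == sid & segs$chrom == arms15$chrom[i], ]
      sample_hits <- FALSE
      for (j in seq_len(nrow(s)))
        for (k in seq_len(nrow(cb)))
          if (min(s$end[j], cb$end[k]) - max(s$start[j], cb$start[k]) > 0)
            sample_hits <- TRUE
      if (sample_hits) hit <- hit + 1L
    }
    expect_equal(arms15$n_samples_hit[i], hit)
  }
  expect_error(band_frequency_map(segs, man15, g, subtype = "nope"), "nope")
})

test_that("recurrent regions are maximal qualifying band runs with a telomeric tie-break", {
  g <- toy_genome()
  base <- band_frequency_map(aupdscan:::empty_segments(), manifest_for(10), g)
  # nothing qualifies on an empty map
  expect_equal(nrow(recurrent_regions(base, 0.2, 3, g)), 0L)

  # hand-built frequencies: one plateau on chr1p, an isolated band on chr2
  m <- base
  m$n_samples_hit[m$region %in% c("1p14", "1p13")] <- 5L
  m$n_samples_hit[m$region == "1q12"] <- 4L  # below the frequency floor
  m$n_samples_hit[m$region == "2q12"] <- 6L
  m$frequency <- m$n_samples_hit / m$n_samples_total
  rec <- recurrent_regions(m, min_frequency = 0.45, min_samples = 3,
                           genome = g)
  expect_equal(nrow(rec), 2L)
  # highest peak first
  expect_equal(rec$region[1], "2q12")
  expect_equal(rec$peak_band[1], "2q12")
  # the chr1 plateau spans p14-p13 and the tie resolves to the more
  # telomeric band p14
  expect_equal(rec$region[2], "1p14-p13")
  expect_equal(rec$peak_band[2], "1p14")
  expect_equal(rec$n_bands[2], 2L)

  # single qualifying band is its own region and peak
  m2 <- base
  m2$n_samples_hit[m2$region == "3q13"] <- 3L
  m2$frequency <- m2$n_samples_hit / m2$n_samples_total
  rec2 <- recurrent_regions(m2, 0.3, 3, g)
  expect_equal(rec2$region, "3q13")
  expect_equal(rec2$peak_band, "3q13")
})

test_that("an enriched band region is rediscovered from planted cohorts", {
  g <- toy_genome()
  hit <- 0L
  for (s in 1:25) {
    set.seed(4000 + s)
    n <- 24
    man <- manifest_for(n)
    rows <- list()
    for (i in seq_len(n)) {
      # half the cohort carries an event inside chr3 q12-q13 (30-60 Mb)
      if (runif(1) < 0.5) {
        b <- sort(floor(runif(2, 31e6, 59e6)))
        if (b[2] - b[1] < 3e6) b[2] <- b[1] + 3e6
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("S%03d", i), chrom = "chr3",
          start = b[1], end = b[2], n_markers = 100L, n_het_markers = 0L,
          mean_logr = 0, status = "aUPD", class = "centromeric")
      }
    }
    segs <- do.call(rbind, rows)
    map <- band_frequency_map(segs, man, g)
    rec <- recurrent_regions(map, min_frequency = 0.25, min_samples = 3,
                             genome = g)
    if (nrow(rec) > 0 && any(rec$chrom == "chr3" & rec$start <= 45e6 &
                               rec$end >= 45e6)) hit <- hit + 1L
  }
  expect_gte(hit / 25, 0.95)
})
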