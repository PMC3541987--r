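make_counts <- function(classes_by_sample, n_samples) {
  segs <- do.call(rbind, lapply(names(classes_by_sample), function(sid) {
    cls <- classes_by_sample[[sid]]
    if (!length(cls)) return(NULL)
    data.frame(sample_id = sid, chrom = "chr1",
               start = seq(0, by = 2e6, length.out = length(cls)),
               end = seq(1e6, by = 2e6, length.out = length(cls)),
               n_markers = 30L, n_het_markers = 0L, mean_logr = 0,
               status = "aUPD", class = cls)
  }))
  man <- manifest_for(n_samples)
  if (is.null(segs)) segs <- aupdscan:::empty_segments()
  per_sample_counts(segs, man)
}

test_that("per-sample counting follows the class ledger and zero-fills", {
  counts <- make_counts(list(S001 = c("whole", "telomeric", "centromeric",
                                      "centromeric")), 3)
  r <- counts[counts$sample_id == "S001", ]
  expect_equal(r$total, 4L)
  expect_equal(r$whole, 1L)
  expect_equal(r$segmental, 3L)
  expect_equal(r$telomeric, 1L)
  expect_equal(r$centromeric, 2L)
  # manifest-only samples are all-zero rows
  expect_true(all(counts$total[counts$sample_id != "S001"] == 0))
  expect_equal(nrow(counts), 3L)

  # conservation holds on random tables
  g <- toy_genome()
  segs <- random_segments(30, g, seed = 91)
  c2 <- per_sample_counts(segs, manifest_for(30))
  expect_equal(c2$total, c2$segmental + c2$whole)
  expect_equal(c2$segmental, c2$telomeric + c2$centromeric)

  # orphan segments are a consistency error
  bad <- segs
  bad$sample_id[1] <- "GHOST"
  expect_error(per_sample_counts(bad, manifest_for(30)), "GHOST")
})

test_that("group summaries reproduce printed cohort percentages", {
  # published numerator/denominator pairs and their printed percentages
  printed <- list(
    list(pos = 151, n = 315, pct = 47.9),  # all STS
    list(pos = 27, n = 37, pct = 73.0),    # myxofibrosarcoma
    list(pos = 28, n = 45, pct = 62.2),    # GIST
    list(pos = 35, n = 57, pct = 61.4),    # alveolar RMS
    list(pos = 14, n = 27, pct = 51.9),    # leiomyosarcoma
    list(pos = 5, n = 10, pct = 50.0),     # Ewing sarcoma
    list(pos = 41, n = 115, pct = 35.7),   # liposarcoma pooled
    list(pos = 0, n = 23, pct = 0.0),      # synovial sarcoma
    list(pos = 17, n = 24, pct = 70.8),    # pleomorphic liposarcoma
    list(pos = 12, n = 50, pct = 24.0),    # dedifferentiated liposarcoma
    list(pos = 3, n = 21, pct = 14.3)      # myxoid/round-cell liposarcoma
  )
  for (case in printed) {
    man <- manifest_for(case$n)
    cls <- lapply(seq_len(case$pos), function(i) "centromeric")
    names(cls) <- sprintf("S%03d", seq_len(case$pos))
    counts <- make_counts(cls, case$n)
    gs <- group_summary(counts, man, "subtype")
    expect_equal(gs$n_positive, case$pos)
    expect_equal(format_percentage(gs$percentage_positive), case$pct)
  }
  # published mechanism proportions (94 whole, 189 telomeric, 441
  # centromeric of 724 regions) as percentages of the total
  expect_equal(format_percentage(100 * 94 / 724), 13.0)
  expect_equal(format_percentage(100 * 189 / 724), 26.1)
  expect_equal(format_percentage(100 * 441 / 724), 60.9)
  expect_equal(format_percentage(100 * (189 + 441) / 724), 87.0)
})

test_that("empty groups are flagged rather than silently zero", {
  man <- manifest_for(4)
  man$subtype <- c("a", "a", "a", "a")
  counts <- make_counts(list(), 4)
  gs <- group_summary(counts, man, "subtype")
  expect_equal(gs$percentage_positive, 0)
  expect_false(gs$undefined)
})

test_that("kruskal_wallis matches the textbook evaluation and handles ties", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 12 / 42 * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2))
  expect_equal(kw$H, 27 / 7)
  expect_equal(kw$df, 1L)
  expect_equal(kw$tie_correction, 1)

  # two identical constant groups: degenerate, H = 0, p = 1
  kw0 <- kruskal_wallis(list(rep(2, 5), rep(2, 7)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
  expect_error(kruskal_wallis(list(1, 2)), "3 observations")

  # rank-based: invariant under strictly monotone transforms
  set.seed(17)
  gs <- list(rpois(8, 2), rpois(6, 3), rpois(9, 2))
  expect_equal(kruskal_wallis(gs)$H,
               kruskal_wallis(lapply(gs, function(x) exp(x / 2)))$H)
})

test_that("kruskal_wallis agrees with the reference implementation", {
  set.seed(404)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    gs <- lapply(seq_len(k), function(j)
      if (runif(1) < 0.5) rnorm(sample(2:12, 1))
      else as.numeric(rpois(sample(2:12, 1), 3)))
    if (length(unique(unlist(gs))) == 1) next
    kw <- kruskal_wallis(gs)
    ref <- stats::kruskal.test(unlist(gs),
                               factor(rep(seq_len(k), lengths(gs))))
    expect_lt(abs(kw$H - unname(ref$statistic)), 1e-10)
    expect_lt(abs(kw$p_value - ref$p.value), 1e-10)
  }
})

test_that("translocation comparison reports five categories with direction", {
  cc <- make_test_cohort(seed = 51, n_markers = 1000)
  coh <- cc$cohort
  segs <- classify_segments(
    call_cohort(coh$manifest, hmm_params(), "unpaired",
                samples = coh$samples),
    cc$config$genome, markers = coh$samples)
  counts <- per_sample_counts(segs, coh$manifest)
  cmp <- translocation_comparison(counts, coh$manifest)
  expect_equal(cmp$category,
               c("total", "telomeric", "centromeric", "segmental", "whole"))
  expect_true(all(cmp$H >= 0))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))

  # missing class or too-small input are errors
  man_one <- coh$manifest
  man_one$translocation_class <- "translocation"
  expect_error(translocation_comparison(counts, man_one), "classes")
  tiny_man <- coh$manifest[1:2, ]
  tiny_man$translocation_class <- c("translocation", "non_translocation")
  expect_error(
    translocation_comparison(counts[counts$sample_id %in%
                                      tiny_man$sample_id, ], tiny_man),
    "3 observations")
})
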