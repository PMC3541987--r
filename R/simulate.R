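#' Default subtype specification for the synthetic cohort
#'
#' Nine sarcoma subtypes with sample sizes, translocation class, and the
#' fraction of samples carrying at least one aUPD event set to published
#' cohort values (295 classified samples in total). Mean event counts per
#' aUPD-positive sample are not published per subtype; defaults place a
#' higher burden on the karyotypically complex (non-translocation) subtypes,
#' consistent with the reported direction of the group difference, and
#' reproduce the published overall region total at cohort scale.
#'
#' @return data.frame with columns `subtype`, `translocation_class`,
#'   `n_samples`, `aupd_prevalence`, `events_per_positive`.
#' @export
default_subtype_specs <- function() {
  data.frame(
    subtype = c("alveolar_rhabdomyosarcoma", "ewing_sarcoma",
                "synovial_sarcoma", "mrc_liposarcoma",
                "gist", "leiomyosarcoma", "myxofibrosarcoma",
                "pleomorphic_liposarcoma", "dedifferentiated_liposarcoma"),
    translocation_class = c(rep("translocation", 4L),
                            rep("non_translocation", 5L)),
    n_samples = c(57L, 10L, 23L, 21L, 45L, 27L, 38L, 24L, 50L),
    aupd_prevalence = c(0.614, 0.50, 0.0, 0.143,
                        0.622, 0.519, 0.73, 0.708, 0.24),
    events_per_positive = c(rep(3.0, 4L), rep(5.5, 5L))
  )
}

#' Two-group demo subtype specification (40 samples)
#'
#' A small cohort used by the demo pipeline and the recovery benchmarks: one
#' karyotypically complex group with high aUPD prevalence and one
#' fusion-driven group with low prevalence.
#'
#' @return data.frame in the format of [default_subtype_specs()]
#' @export
demo_subtype_specs <- function() {
  data.frame(
    subtype = c("complex_karyotype", "fusion_driven"),
    translocation_class = c("non_translocation", "translocation"),
    n_samples = c(20L, 20L),
    aupd_prevalence = c(0.70, 0.35),
    events_per_positive = c(4.0, 2.5)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic SNP-array cohort generator. Markers are
#' uniformly spaced per chromosome; germline genotypes are AB with
#' probability `het_rate` and AA/BB equiprobably otherwise; planted aUPD
#' events duplicate one parental haplotype, turning germline-heterozygous
#' markers homozygous. Tumor and matched-normal genotype calls are perturbed
#' by a call-error rate and a no-call rate; BAF and logR carry Gaussian
#' noise.
#'
#' @param genome a [genome_build()] (default [toy_genome()])
#' @param markers_per_chromosome markers per chromosome, uniformly spaced
#' @param het_rate population heterozygosity at markers
#' @param genotype_error probability a call flips to another category
#' @param no_call_rate probability a call is reported as NC
#' @param logr_sd Gaussian sd of log2 intensity ratio (copy-neutral mean 0)
#' @param baf_sd Gaussian sd of the B-allele frequency around its genotype
#'   mean (0, 0.5, 1)
#' @param tumor_purity tumor cell fraction in (0,1]; below 1, BAF at LOH
#'   markers is attenuated toward 0.5 by `1 - tumor_purity`
#' @param subtype_specs data.frame as [default_subtype_specs()]
#' @param mechanism_mix probabilities of (whole, telomeric, interstitial)
#'   event mechanisms; defaults follow published whole/telomeric/centromeric
#'   region proportions (94:189:441 of 724)
#' @param min_interstitial_span minimum span of an interstitial event (bp)
#' @param breakpoint_margin planted breakpoints keep this distance clear of
#'   chromosome ends so the generating mechanism is well defined under the
#'   segment taxonomy's telomere-proximity convention
#' @param del_rate,amp_rate per-positive-sample probability of planting one
#'   homozygous deletion / focal amplification inside an aUPD event
#' @param lesion_markers number of markers spanned by a planted lesion
#' @param del_logr_mean,amp_logr_mean mean logR inside planted lesions
#' @param marker_jitter if TRUE, marker positions are jittered uniformly by
#'   up to 30% of the spacing
#' @param seed integer seed; the whole cohort is reproducible from it
#' @return a list of class `simulation_config`
#' @export
simulation_config <- function(genome = toy_genome(),
                              markers_per_chromosome = 5000L,
                              het_rate = 0.30,
                              genotype_error = 0.01,
                              no_call_rate = 0.02,
                              logr_sd = 0.15,
                              baf_sd = 0.04,
                              tumor_purity = 1.0,
                              subtype_specs = default_subtype_specs(),
                              mechanism_mix = c(whole = 0.13,
                                                telomeric = 0.26,
                                                interstitial = 0.61),
                              min_interstitial_span = 3e6,
                              breakpoint_margin = 2e6,
                              del_rate = 0,
                              amp_rate = 0,
                              lesion_markers = 30L,
                              del_logr_mean = -1.2,
                              amp_logr_mean = 1.0,
                              marker_jitter = FALSE,
                              seed = 1L) {
  stopifnot(inherits(genome, "genome_build"),
            markers_per_chromosome >= 10L,
            length(mechanism_mix) == 3L)
  probs <- c(het_rate, genotype_error, no_call_rate, tumor_purity,
             mechanism_mix, subtype_specs$aupd_prevalence, del_rate, amp_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0,1]", call. = FALSE)
  if (tumor_purity <= 0) stop("tumor_purity must be in (0,1]", call. = FALSE)
  if (abs(sum(mechanism_mix) - 1) > 1e-8)
    stop("mechanism_mix must sum to 1", call. = FALSE)
  if (any(subtype_specs$events_per_positive < 1))
    stop("events_per_positive is a zero-truncated Poisson mean and must be >= 1",
         call. = FALSE)
  cfg <- list(genome = genome,
              markers_per_chromosome = as.integer(markers_per_chromosome),
              het_rate = het_rate, genotype_error = genotype_error,
              no_call_rate = no_call_rate, logr_sd = logr_sd,
              baf_sd = baf_sd, tumor_purity = tumor_purity,
              subtype_specs = subtype_specs,
              mechanism_mix = stats::setNames(as.numeric(mechanism_mix),
                                              c("whole", "telomeric",
                                                "interstitial")),
              min_interstitial_span = min_interstitial_span,
              breakpoint_margin = breakpoint_margin,
              del_rate = del_rate, amp_rate = amp_rate,
              lesion_markers = as.integer(lesion_markers),
              del_logr_mean = del_logr_mean, amp_logr_mean = amp_logr_mean,
              marker_jitter = marker_jitter,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# uniformly spaced 0-based marker positions for every chromosome
marker_grid <- function(config) {
  g <- config$genome
  m <- config$markers_per_chromosome
  out <- lapply(seq_len(nrow(g$chromosomes)), function(i) {
    ch <- g$chromosomes$chrom[i]
    len <- g$chromosomes$length[i]
    spacing <- len / m
    pos <- floor(spacing * (seq_len(m) - 0.5))
    if (isTRUE(config$marker_jitter))
      pos <- pmin(len - 1, pmax(0, pos + round(stats::runif(m, -0.3, 0.3) *
                                                 spacing)))
    data.frame(marker_id = sprintf("%s_%05d", ch, seq_len(m)),
               chrom = ch, pos = pos)
  })
  do.call(rbind, out)
}

#' Simulate phased germline genotypes for one sample
#'
#' Each marker is heterozygous (AB) with probability `het_rate`, otherwise
#' AA or BB equiprobably. The phase records which allele sits on the
#' maternal haplotype, so a planted event can duplicate a specific parent.
#'
#' @param config a [simulation_config()]
#' @param sample_seed integer seed; identical seeds give identical output
#' @return data.frame: marker_id, chrom, pos (0-based), gt ("AA","AB","BB"),
#'   maternal_allele ("A"/"B")
#' @export
simulate_germline <- function(config, sample_seed) {
  set.seed(as.integer(sample_seed %% 2147483647))
  grid <- marker_grid(config)
  n <- nrow(grid)
  u <- stats::runif(n)
  gt <- ifelse(u < config$het_rate, "AB",
               ifelse(u < config$het_rate + (1 - config$het_rate) / 2,
                      "AA", "BB"))
  mat <- ifelse(gt == "AA", "A",
                ifelse(gt == "BB", "B",
                       ifelse(stats::runif(n) < 0.5, "A", "B")))
  grid$gt <- gt
  grid$maternal_allele <- mat
  grid
}

# zero-truncated Poisson: solve the rate from the target mean, then sample
# by inverse-cdf restricted to {1,2,...}
ztpois_lambda <- function(mean) {
  if (mean <= 1 + 1e-9) return(1e-8)
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                 lower = 1e-8, upper = mean * 2 + 10)$root
}

rztpois <- function(n, mean) {
  lambda <- ztpois_lambda(mean)
  stats::qpois(stats::runif(n, exp(-lambda), 1), lambda)
}

#' Plant mechanism-labelled aUPD events on a genome
#'
#' Draws `n_events` events: mechanism by `mechanism_mix`; a whole event
#' spans its entire chromosome; a telomeric event has one uniform breakpoint
#' and extends to a randomly chosen chromosome end; an interstitial event
#' has two ordered uniform breakpoints with a minimum span. Events
#' overlapping an existing event of the same sample are redrawn, as are
#' events containing no germline-heterozygous marker (when `het_positions`
#' is supplied).
#'
#' @param config a [simulation_config()]
#' @param n_events number of events to place (>= 0)
#' @param het_positions optional named list (per chromosome) of 0-based
#'   positions of germline-heterozygous markers; events must contain one
#' @return data.frame: chrom, start, end (0-based half-open), mechanism
#'   ("whole","telomeric","interstitial"), parent ("maternal"/"paternal")
#' @export
plant_events <- function(config, n_events, het_positions = NULL) {
  g <- config$genome
  chroms <- g$chromosomes$chrom
  lens <- g$chromosomes$length
  mix <- config$mechanism_mix
  margin <- config$breakpoint_margin
  ev <- data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), mechanism = character(0),
                   parent = character(0))
  if (n_events == 0L) return(ev)
  for (k in seq_len(n_events)) {
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      mech <- sample(names(mix), 1L, prob = mix)
      ci <- sample(length(chroms), 1L)
      len <- lens[ci]
      if (mech == "whole") {
        start <- 0; end <- len
      } else if (mech == "telomeric") {
        b <- floor(stats::runif(1, margin, len - margin))
        if (stats::runif(1) < 0.5) { start <- 0; end <- b }
        else { start <- b; end <- len }
      } else {
        # breakpoints are redrawn (mechanism kept) until the minimum span
        # holds, so span rejection cannot distort the mechanism mix
        ok <- FALSE
        for (bt in seq_len(100L)) {
          b <- sort(floor(stats::runif(2, margin, len - margin)))
          if (b[2] - b[1] >= config$min_interstitial_span) { ok <- TRUE; break }
        }
        if (!ok) next
        start <- b[1]; end <- b[2]
      }
      # events on one chromosome must not overlap and must keep a margin of
      # separation: closer pairs would decode as a single segment, leaving
      # the planted mechanism labels unidentifiable
      same <- ev[ev$chrom == chroms[ci], , drop = FALSE]
      if (nrow(same) > 0 &&
          any(pmin(same$end, end + margin) >
                pmax(same$start, start - margin))) next
      if (!is.null(het_positions)) {
        hp <- het_positions[[chroms[ci]]]
        if (is.null(hp) || !any(hp >= start & hp < end)) next
      }
      ev <- rbind(ev, data.frame(
        chrom = chroms[ci], start = start, end = end, mechanism = mech,
        parent = if (stats::runif(1) < 0.5) "maternal" else "paternal"))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place event ", k, " after 100 attempts", call. = FALSE)
  }
  ev
}

#' Render observed SNP-array data for one sample
#'
#' Applies planted events to the germline (heterozygous markers inside an
#' event become homozygous for the duplicated parent's allele), then layers
#' the observation model: genotype-call errors and no-calls, BAF as the
#' genotype mean (0, 0.5, 1) with Gaussian noise and purity attenuation at
#' LOH markers, and logR as Gaussian noise around 0 except inside planted
#' copy-number lesions.
#'
#' @param germline output of [simulate_germline()]
#' @param events data.frame as returned by [plant_events()] (may be empty)
#' @param lesions data.frame with chrom, start, end, kind
#'   ("homozygous_deletion"/"focal_amplification"); may be NULL
#' @param config a [simulation_config()]
#' @return data.frame: marker_id, chrom, pos, gt_tumor, gt_normal, baf, logr
#' @export
render_sample <- function(germline, events, lesions, config) {
  n <- nrow(germline)
  gt_true <- germline$gt
  in_loh <- rep(FALSE, n)
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      idx <- germline$chrom == events$chrom[i] &
        germline$pos >= events$start[i] & germline$pos < events$end[i]
      het <- idx & germline$gt == "AB"
      dup <- if (events$parent[i] == "maternal") germline$maternal_allele
             else ifelse(germline$maternal_allele == "A", "B", "A")
      gt_true[het] <- paste0(dup[het], dup[het])
      in_loh <- in_loh | het
    }
  }

  # BAF from the true (post-event) genotype
  baf_mean <- c(AA = 0, AB = 0.5, BB = 1)[gt_true]
  pur <- config$tumor_purity
  baf_mean[in_loh] <- pur * baf_mean[in_loh] + (1 - pur) * 0.5
  baf <- pmin(1, pmax(0, stats::rnorm(n, baf_mean, config$baf_sd)))

  logr <- stats::rnorm(n, 0, config$logr_sd)
  if (!is.null(lesions) && nrow(lesions) > 0) {
    for (i in seq_len(nrow(lesions))) {
      idx <- germline$chrom == lesions$chrom[i] &
        germline$pos >= lesions$start[i] & germline$pos < lesions$end[i]
      mu <- if (lesions$kind[i] == "homozygous_deletion")
        config$del_logr_mean else config$amp_logr_mean
      logr[idx] <- stats::rnorm(sum(idx), mu, config$logr_sd)
    }
  }

  perturb_calls <- function(gt) {
    out <- gt
    flip <- stats::runif(n) < config$genotype_error
    if (any(flip)) {
      cats <- c("AA", "AB", "BB")
      out[flip] <- vapply(out[flip], function(x)
        sample(setdiff(cats, x), 1L), "")
    }
    out[stats::runif(n) < config$no_call_rate] <- "NC"
    out
  }

  # 9-decimal values so the in-memory table equals its TSV round-trip
  data.frame(marker_id = germline$marker_id,
             chrom = germline$chrom,
             pos = germline$pos,
             gt_tumor = perturb_calls(gt_true),
             gt_normal = perturb_calls(germline$gt),
             baf = round(baf, 9L),
             logr = round(logr, 9L))
}

#' Simulate a full synthetic SNP-array cohort
#'
#' For each subtype specification, draws `n_samples` samples; each is
#' aUPD-positive with the subtype's prevalence, and positive samples carry a
#' zero-truncated-Poisson number of mechanism-labelled events. Optionally
#' plants copy-number lesions inside events and renders per-marker data.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()]
#' @param dir if non-NULL, write per-sample marker TSVs plus `manifest.tsv`,
#'   `truth.tsv` and `truth_lesions.tsv` into this directory
#' @param render if FALSE, skip marker rendering (truth and manifest only;
#'   used for burden-level statistical simulations)
#' @return list with `manifest` (sample_id, subtype, translocation_class,
#'   file), `truth` (planted events), `lesions`, and — when rendered —
#'   `samples`, a named list of marker data.frames
#' @export
simulate_cohort <- function(config, dir = NULL, render = TRUE) {
  specs <- config$subtype_specs
  set.seed(config$seed)
  # pre-draw per-sample seeds so downstream draws cannot desynchronize
  total_n <- sum(specs$n_samples)
  sample_seeds <- sample.int(2147483646L, total_n)

  manifest <- data.frame(sample_id = character(0), subtype = character(0),
                         translocation_class = character(0),
                         file = character(0))
  truth <- list(); lesions <- list(); samples <- list()
  si <- 0L
  for (r in seq_len(nrow(specs))) {
    for (j in seq_len(specs$n_samples[r])) {
      si <- si + 1L
      sid <- sprintf("S%03d", si)
      set.seed(sample_seeds[si])
      positive <- stats::runif(1) < specs$aupd_prevalence[r]
      n_events <- if (positive) rztpois(1, specs$events_per_positive[r]) else 0L

      germ <- NULL
      het_pos <- NULL
      if (render) {
        # distinct derived seeds (double arithmetic: the sum can exceed
        # .Machine$integer.max) so germline draws do not reuse the
        # positive/event-count stream
        germ <- simulate_germline(
          config, (as.numeric(sample_seeds[si]) + 1000003) %% 2147483647)
        set.seed((as.numeric(sample_seeds[si]) + 2000003) %% 2147483647)
        hp <- germ[germ$gt == "AB", c("chrom", "pos")]
        het_pos <- split(hp$pos, hp$chrom)
      }
      # on small test genomes a large event draw may not fit; retry the
      # sample's placement, then trim the count as a last resort
      ev <- NULL
      ne <- n_events
      while (is.null(ev)) {
        for (round in seq_len(20L)) {
          ev <- tryCatch(plant_events(config, ne, het_pos),
                         error = function(e) NULL)
          if (!is.null(ev)) break
        }
        if (is.null(ev)) {
          if (ne <= 1L)
            stop("cannot place any event for sample ", sid, call. = FALSE)
          ne <- ne - 1L
        }
      }
      if (nrow(ev) > 0) ev <- cbind(sample_id = sid, ev)

      les <- NULL
      if (n_events > 0 && (config$del_rate > 0 || config$amp_rate > 0)) {
        les <- plant_lesions(config, ev)
        if (!is.null(les) && nrow(les) > 0) les <- cbind(sample_id = sid, les)
      }

      if (render) {
        rend <- render_sample(germ, ev, les, config)
        samples[[sid]] <- rend
        if (!is.null(dir)) {
          fp <- file.path("markers", paste0(sid, ".tsv"))
          dir.create(file.path(dir, "markers"), showWarnings = FALSE,
                     recursive = TRUE)
          write_marker_table(rend, file.path(dir, fp))
        }
      }
      manifest <- rbind(manifest, data.frame(
        sample_id = sid, subtype = specs$subtype[r],
        translocation_class = specs$translocation_class[r],
        file = if (render && !is.null(dir))
          file.path("markers", paste0(sid, ".tsv")) else NA_character_))
      if (nrow(ev) > 0) truth[[sid]] <- ev
      if (!is.null(les) && nrow(les) > 0) lesions[[sid]] <- les
    }
  }
  empty_truth <- data.frame(sample_id = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            mechanism = character(0), parent = character(0))
  empty_les <- data.frame(sample_id = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          kind = character(0))
  out <- list(
    manifest = manifest,
    truth = if (length(truth)) do.call(rbind, c(truth, list(make.row.names = FALSE))) else empty_truth,
    lesions = if (length(lesions)) do.call(rbind, c(lesions, list(make.row.names = FALSE))) else empty_les
  )
  if (render) out$samples <- samples
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_with_header(out$manifest, file.path(dir, "manifest.tsv"))
    write_tsv_with_header(out$truth, file.path(dir, "truth.tsv"))
    write_tsv_with_header(out$lesions, file.path(dir, "truth_lesions.tsv"))
  }
  out
}

# place one deletion and/or amplification inside randomly chosen events
plant_lesions <- function(config, events) {
  spacing <- min(config$genome$chromosomes$length) /
    config$markers_per_chromosome
  span <- config$lesion_markers * spacing
  rows <- list()
  draw <- function(kind) {
    big <- events[events$end - events$start > 3 * span, , drop = FALSE]
    if (nrow(big) == 0) return(NULL)
    e <- big[sample(nrow(big), 1L), ]
    s <- floor(stats::runif(1, e$start, e$end - span))
    data.frame(chrom = e$chrom, start = s, end = s + span, kind = kind)
  }
  if (stats::runif(1) < config$del_rate)
    rows <- c(rows, list(draw("homozygous_deletion")))
  if (stats::runif(1) < config$amp_rate)
    rows <- c(rows, list(draw("focal_amplification")))
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) do.call(rbind, rows) else NULL
}
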