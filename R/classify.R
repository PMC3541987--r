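#' Thresholds for segment taxonomy and lesion overlay
#'
#' The taxonomy is breakpoint-based: a segment reaching both chromosome ends
#' arose by chromosome loss plus reduplication (whole), one inferred mitotic
#' recombination leaves a telomere-bounded segment (telomeric), two or more
#' leave an interstitial segment (centromeric). Array probes never reach the
#' literal telomere, so "reaches an end" means within `telomere_proximity`
#' of position 0 / chromosome length, or including the outermost marker.
#'
#' @param telomere_proximity bp within which a boundary counts as reaching a
#'   chromosome end
#' @param whole_coverage fraction of the chromosome a whole-chromosome
#'   segment must cover, in addition to reaching both ends
#' @param focal_max_span maximum span of a focal amplification (bp)
#' @param amp_logr run mean logR at or above this is an amplification
#' @param del_logr run mean logR at or below this is a homozygous deletion
#' @param lesion_min_markers minimum markers in a lesion run
#' @return list of class `classifier_thresholds`
#' @export
classifier_thresholds <- function(telomere_proximity = 1e6,
                                  whole_coverage = 0.90,
                                  focal_max_span = 3e6,
                                  amp_logr = 0.9,
                                  del_logr = -1.0,
                                  lesion_min_markers = 10L) {
  if (whole_coverage <= 0 || whole_coverage > 1)
    stop("whole_coverage must lie in (0,1]", call. = FALSE)
  if (telomere_proximity < 0)
    stop("telomere_proximity must be >= 0", call. = FALSE)
  structure(list(telomere_proximity = telomere_proximity,
                 whole_coverage = whole_coverage,
                 focal_max_span = focal_max_span,
                 amp_logr = amp_logr, del_logr = del_logr,
                 lesion_min_markers = as.integer(lesion_min_markers)),
            class = "classifier_thresholds")
}

#' Classify aUPD segments as whole / telomeric / centromeric
#'
#' Deterministic, total classification of every copy-neutral (status `aUPD`)
#' segment. A segment reaching both ends and covering at least
#' `whole_coverage` of its chromosome is `whole`; reaching exactly one end
#' is `telomeric`; reaching neither is `centromeric` (interstitial). The
#' rare both-ends-but-under-coverage case (only possible on chromosomes
#' shorter than `2 * telomere_proximity / (1 - whole_coverage)`) falls back
#' to `telomeric`.
#'
#' @param segments segment table from [call_cohort()]
#' @param genome a [genome_build()]
#' @param th a [classifier_thresholds()]
#' @param markers optional marker table (or named list per sample) used to
#'   determine the outermost marker per chromosome as a telomere fallback
#' @return `segments` with the `class` column filled for aUPD rows
#' @export
classify_segments <- function(segments, genome, th = classifier_thresholds(),
                              markers = NULL) {
  if (nrow(segments) == 0L) return(segments)
  bad <- setdiff(unique(segments$chrom), genome$chromosomes$chrom)
  if (length(bad))
    stop("segment chromosome not in genome: ", paste(bad, collapse = ", "),
         call. = FALSE)

  extent <- marker_extent(markers)
  lens <- chrom_length(genome, segments$chrom)
  d <- th$telomere_proximity

  first_pos <- if (is.null(extent)) rep(NA_real_, nrow(segments))
               else unname(extent$first[segments$chrom])
  last_pos <- if (is.null(extent)) rep(NA_real_, nrow(segments))
              else unname(extent$last[segments$chrom])
  reach_start <- segments$start <= d |
    (!is.na(first_pos) & segments$start <= first_pos)
  reach_end <- segments$end >= lens - d |
    (!is.na(last_pos) & segments$end >= last_pos + 1)
  coverage <- (segments$end - segments$start) / lens

  cls <- ifelse(reach_start & reach_end & coverage >= th$whole_coverage,
                "whole",
                ifelse(xor(reach_start, reach_end) |
                         (reach_start & reach_end), "telomeric",
                       "centromeric"))
  segments$class <- ifelse(segments$status == "aUPD", cls, segments$class)
  segments
}

# outermost marker position per chromosome as named vectors; NULL when no
# markers were supplied
marker_extent <- function(markers) {
  if (is.null(markers)) return(NULL)
  if (is.list(markers) && !is.data.frame(markers))
    markers <- do.call(rbind, lapply(markers, function(m)
      m[, c("chrom", "pos")]))
  first <- tapply(markers$pos, markers$chrom, min)
  last <- tapply(markers$pos, markers$chrom, max)
  list(first = first, last = last)
}

#' Overlay copy-number lesions onto aUPD segments
#'
#' Scans the markers inside (and within `telomere_proximity` of) each aUPD
#' segment for runs of clearly aberrant logR. A marker enters a candidate
#' run when its logR passes half the lesion threshold; a maximal run is
#' reported as a homozygous deletion when it has at least
#' `lesion_min_markers` markers and run mean logR at or below `del_logr`,
#' and as a focal amplification when the run mean is at or above `amp_logr`
#' and the run spans at most `focal_max_span`.
#'
#' @param segments classified segment table
#' @param samples named list of marker data.frames (per sample)
#' @param th a [classifier_thresholds()]
#' @return data.frame: sample_id, seg_chrom, seg_start, seg_end, kind,
#'   lesion_start, lesion_end, n_markers, mean_logr
#' @export
overlay_cn_features <- function(segments, samples,
                                th = classifier_thresholds()) {
  empty <- data.frame(sample_id = character(0), seg_chrom = character(0),
                      seg_start = numeric(0), seg_end = numeric(0),
                      kind = character(0), lesion_start = numeric(0),
                      lesion_end = numeric(0), n_markers = integer(0),
                      mean_logr = numeric(0))
  seg <- segments[segments$status == "aUPD", , drop = FALSE]
  if (nrow(seg) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(seg))) {
    m <- samples[[seg$sample_id[i]]]
    if (is.null(m)) next
    m <- m[m$chrom == seg$chrom[i] &
             m$pos >= seg$start[i] - th$telomere_proximity &
             m$pos < seg$end[i] + th$telomere_proximity, , drop = FALSE]
    m <- m[order(m$pos), , drop = FALSE]
    if (nrow(m) == 0L) next
    for (kind in c("homozygous_deletion", "focal_amplification")) {
      if (kind == "homozygous_deletion") {
        gate <- m$logr <= th$del_logr / 2
      } else {
        gate <- m$logr >= th$amp_logr / 2
      }
      r <- rle(gate)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        a <- starts[k]; b <- ends[k]
        n <- b - a + 1L
        if (n < th$lesion_min_markers) next
        mu <- mean(m$logr[a:b])
        span <- m$pos[b] + 1 - m$pos[a]
        ok <- if (kind == "homozygous_deletion") mu <= th$del_logr
              else mu >= th$amp_logr && span <= th$focal_max_span
        if (!ok) next
        out[[length(out) + 1L]] <- data.frame(
          sample_id = seg$sample_id[i], seg_chrom = seg$chrom[i],
          seg_start = seg$start[i], seg_end = seg$end[i], kind = kind,
          lesion_start = m$pos[a], lesion_end = m$pos[b] + 1,
          n_markers = n, mean_logr = mu)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
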