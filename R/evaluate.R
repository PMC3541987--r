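#' Compare called segments against planted truth
#'
#' Event-level benchmarking of the caller on simulated data. A planted event
#' is *recovered* when called copy-neutral segments of the same sample cover
#' at least `min_het_coverage` of the event's informative markers (markers
#' heterozygous in the matched normal). Symmetrically, a called segment is a
#' *true positive* when at least `min_het_coverage` of its informative
#' markers lie inside planted events. Mechanism-to-class agreement maps
#' whole to whole, telomeric to telomeric and interstitial to centromeric,
#' using the called segment with the largest overlap. Boundary errors are
#' reported in units of the median inter-marker spacing of the marker set
#' used for decoding.
#'
#' @param truth planted-event table from [simulate_cohort()]
#' @param segments classified segment table
#' @param samples named list of marker data.frames
#' @param min_het_coverage marker-coverage fraction defining a match
#' @param boundary_marker_set "all" (unpaired decoding) or "normal_het"
#'   (paired decoding) — which markers set the spacing unit
#' @return list: precision, recall, n_events, n_recovered, n_segments,
#'   class_agreement (fraction of recovered events whose class matches the
#'   planted mechanism), boundary_errors (vector, in spacings, two entries
#'   per recovered event), events (per-event detail data.frame)
#' @export
recovery_stats <- function(truth, segments, samples,
                           min_het_coverage = 0.8,
                           boundary_marker_set = c("all", "normal_het")) {
  boundary_marker_set <- match.arg(boundary_marker_set)
  seg <- segments[segments$status == "aUPD", , drop = FALSE]
  mech2class <- c(whole = "whole", telomeric = "telomeric",
                  interstitial = "centromeric")

  ev_rows <- list()
  boundary <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    sid <- truth$sample_id[i]
    m <- samples[[sid]]
    mm <- m[m$chrom == truth$chrom[i], , drop = FALSE]
    info <- mm$pos[mm$gt_normal == "AB"]
    info_in <- info[info >= truth$start[i] & info < truth$end[i]]
    s <- seg[seg$sample_id == sid & seg$chrom == truth$chrom[i], ,
             drop = FALSE]
    covered <- if (nrow(s) == 0L || length(info_in) == 0L) 0L else
      sum(vapply(info_in, function(p)
        any(p >= s$start & p < s$end), TRUE))
    recovered <- length(info_in) > 0L &&
      covered / length(info_in) >= min_het_coverage
    cls <- NA_character_
    if (recovered) {
      ov <- pmax(0, pmin(s$end, truth$end[i]) - pmax(s$start, truth$start[i]))
      best <- s[which.max(ov), ]
      cls <- best$class
      sp_pos <- if (boundary_marker_set == "all") mm$pos else
        mm$pos[mm$gt_normal == "AB"]
      spacing <- stats::median(diff(sort(sp_pos)))
      boundary <- c(boundary,
                    abs(best$start - truth$start[i]) / spacing,
                    abs(best$end - truth$end[i]) / spacing)
    }
    ev_rows[[i]] <- data.frame(
      sample_id = sid, chrom = truth$chrom[i], start = truth$start[i],
      end = truth$end[i], mechanism = truth$mechanism[i],
      n_informative = length(info_in), n_covered = covered,
      recovered = recovered, called_class = cls,
      class_match = identical(cls, unname(mech2class[truth$mechanism[i]])))
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(recovered = logical(0), class_match = logical(0))

  # segment-level precision
  tp <- 0L
  for (j in seq_len(nrow(seg))) {
    sid <- seg$sample_id[j]
    m <- samples[[sid]]
    mm <- m[m$chrom == seg$chrom[j], , drop = FALSE]
    info <- mm$pos[mm$gt_normal == "AB" & mm$pos >= seg$start[j] &
                     mm$pos < seg$end[j]]
    tr <- truth[truth$sample_id == sid & truth$chrom == seg$chrom[j], ,
                drop = FALSE]
    inside <- if (nrow(tr) == 0L || length(info) == 0L) 0L else
      sum(vapply(info, function(p)
        any(p >= tr$start & p < tr$end), TRUE))
    if (length(info) > 0L && inside / length(info) >= min_het_coverage)
      tp <- tp + 1L
  }

  n_rec <- sum(events$recovered)
  list(precision = if (nrow(seg) > 0) tp / nrow(seg) else NA_real_,
       recall = if (nrow(truth) > 0) n_rec / nrow(truth) else NA_real_,
       n_events = nrow(truth), n_recovered = n_rec, n_segments = nrow(seg),
       class_agreement = if (n_rec > 0)
         sum(events$class_match[events$recovered]) / n_rec else NA_real_,
       boundary_errors = boundary,
       events = events)
}

#' Convert planted truth events to a classified-segment table
#'
#' Lets burden-level statistical simulations (group comparisons over many
#' replicate cohorts) run on planted truth directly, without rendering
#' markers and re-calling them.
#'
#' @param truth planted-event table from [simulate_cohort()]
#' @return a segment table with status "aUPD" and class mapped from the
#'   mechanism label (interstitial becomes centromeric)
#' @export
truth_as_segments <- function(truth) {
  mech2class <- c(whole = "whole", telomeric = "telomeric",
                  interstitial = "centromeric")
  if (nrow(truth) == 0L) return(empty_segments())
  data.frame(sample_id = truth$sample_id, chrom = truth$chrom,
             start = truth$start, end = truth$end,
             n_markers = NA_integer_, n_het_markers = NA_integer_,
             mean_logr = 0, status = "aUPD",
             class = unname(mech2class[truth$mechanism]))
}
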