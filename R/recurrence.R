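#' Cytoband-level aUPD recurrence map
#'
#' A sample "hits" a band when any of its copy-neutral (status `aUPD`)
#' segments overlaps the band by at least 1 bp; each sample counts at most
#' once per band. Frequencies use the full sample count of the subtype
#' (aUPD-negative samples included) as denominator, matching the
#' percentage-of-cohort convention used for published recurrence figures.
#'
#' @param segments classified segment table
#' @param manifest cohort manifest (sample_id, subtype, ...)
#' @param genome a [genome_build()]
#' @param subtype optional subtype filter; NULL uses the whole cohort
#' @return data.frame: subtype, unit ("cytoband"), chrom, start, end,
#'   region (e.g. "1p12"), n_samples_hit, n_samples_total, frequency
#' @export
band_frequency_map <- function(segments, manifest, genome, subtype = NULL) {
  units <- genome$cytobands[, c("chrom", "start", "end", "band")]
  units$region <- paste0(sub("^chr", "", units$chrom), units$band)
  frequency_map(segments, manifest, genome, units, "cytoband", subtype)
}

#' Chromosome-arm-level aUPD recurrence map
#'
#' Same hit rule as [band_frequency_map()], aggregated over all bands of an
#' arm (a sample hitting any band of the arm hits the arm; a segment
#' spanning the centromere hits both arms).
#'
#' @inheritParams band_frequency_map
#' @return data.frame as [band_frequency_map()] with unit "arm" and regions
#'   like "1p"
#' @export
arm_frequency_map <- function(segments, manifest, genome, subtype = NULL) {
  units <- arm_intervals(genome)
  units$band <- units$arm
  units$region <- paste0(sub("^chr", "", units$chrom), units$arm)
  frequency_map(segments, manifest, genome,
                units[, c("chrom", "start", "end", "band", "region")],
                "arm", subtype)
}

frequency_map <- function(segments, manifest, genome, units, unit, subtype) {
  if (!is.null(subtype)) {
    if (!subtype %in% manifest$subtype)
      stop("subtype not in manifest: ", subtype, call. = FALSE)
    manifest <- manifest[manifest$subtype == subtype, , drop = FALSE]
  }
  n_total <- nrow(manifest)
  seg <- segments[segments$status == "aUPD" &
                    segments$sample_id %in% manifest$sample_id, ,
                  drop = FALSE]
  hits <- integer(nrow(units))
  if (nrow(seg) > 0L) {
    for (i in seq_len(nrow(units))) {
      ov <- overlap_bp_vec(units$chrom[i], units$start[i], units$end[i],
                           seg$chrom, seg$start, seg$end)
      hits[i] <- length(unique(seg$sample_id[ov > 0]))
    }
  }
  data.frame(subtype = if (is.null(subtype)) "all" else subtype,
             unit = unit,
             chrom = units$chrom, start = units$start, end = units$end,
             region = units$region,
             n_samples_hit = hits,
             n_samples_total = n_total,
             frequency = if (n_total > 0) hits / n_total else NaN)
}

#' Extract recurrent aUPD regions from a cytoband map
#'
#' Maximal runs of coordinate-adjacent bands that each meet the frequency
#' and hit-count thresholds are reported as one recurrent region. The peak
#' band is the run's band of maximum frequency; frequency ties resolve to
#' the most telomeric band of the run (smallest distance to its chromosome
#' end). Regions are sorted by peak frequency, descending.
#'
#' @param map a cytoband-resolution map from [band_frequency_map()]
#' @param min_frequency minimum per-band hit frequency
#' @param min_samples minimum per-band hit count (default 3, suppressing
#'   singleton "recurrence")
#' @param genome a [genome_build()] (for chromosome lengths in the
#'   telomere-distance tie-break)
#' @return data.frame: chrom, start, end, region (band range), peak_band,
#'   peak_frequency, n_bands
#' @export
recurrent_regions <- function(map, min_frequency, min_samples = 3L,
                              genome = NULL) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), region = character(0),
                      peak_band = character(0), peak_frequency = numeric(0),
                      n_bands = integer(0))
  if (!all(map$unit == "cytoband"))
    stop("recurrent_regions needs a cytoband-resolution map", call. = FALSE)
  if (nrow(map) == 0L) return(empty)
  map <- map[order(match(map$chrom, unique(map$chrom)), map$start), ,
             drop = FALSE]
  ok <- map$frequency >= min_frequency & map$n_samples_hit >= min_samples
  if (!any(ok)) return(empty)
  # runs of qualifying bands, broken at chromosome changes
  grp <- cumsum(c(TRUE, map$chrom[-1L] != map$chrom[-nrow(map)] |
                    diff(as.integer(ok)) != 0))
  out <- list()
  for (g in unique(grp[ok])) {
    run <- map[grp == g, , drop = FALSE]
    band_names <- sub("^[^pq]*", "", run$region)
    len <- if (!is.null(genome)) chrom_length(genome, run$chrom[1L])
           else max(map$end[map$chrom == run$chrom[1L]])
    tel_dist <- pmin(run$start, len - run$end)
    peak <- which(run$frequency == max(run$frequency))
    peak <- peak[which.min(tel_dist[peak])]
    out[[length(out) + 1L]] <- data.frame(
      chrom = run$chrom[1L], start = min(run$start), end = max(run$end),
      region = if (nrow(run) == 1L) run$region[1L]
               else paste0(run$region[1L], "-", band_names[nrow(run)]),
      peak_band = run$region[peak],
      peak_frequency = run$frequency[peak],
      n_bands = nrow(run))
  }
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(-out$peak_frequency), , drop = FALSE]
}
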