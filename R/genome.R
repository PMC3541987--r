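#' Reference genome build for aUPD analysis
#'
#' A `genome_build` bundles the coordinate frame every other component works
#' in: ordered chromosomes with lengths, centromere intervals, and a cytoband
#' table with arm assignments. All coordinates are 0-based half-open
#' internally; readers of 1-based file formats convert at the boundary.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`.
#' @param centromeres data.frame with columns `chrom`, `start`, `end`.
#' @param cytobands data.frame with columns `chrom`, `start`, `end`, `band`,
#'   `stain`. Arm is derived from the band name prefix (`p` or `q`).
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(chromosomes, centromeres, cytobands) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(centromeres),
            is.data.frame(cytobands))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  centromeres$chrom <- as.character(centromeres$chrom)
  cytobands$chrom <- as.character(cytobands$chrom)
  cytobands$arm <- substr(cytobands$band, 1L, 1L)

  g <- structure(
    list(chromosomes = chromosomes,
         centromeres = centromeres,
         cytobands = cytobands),
    class = "genome_build"
  )
  validate_genome_build(g)
  g
}

validate_genome_build <- function(g) {
  chroms <- g$chromosomes$chrom
  if (anyDuplicated(chroms))
    stop("duplicated chromosome names in build", call. = FALSE)
  for (ch in chroms) {
    len <- chrom_length(g, ch)
    cen <- g$centromeres[g$centromeres$chrom == ch, , drop = FALSE]
    if (nrow(cen) != 1L)
      stop("chromosome ", ch, ": expected exactly one centromere interval",
           call. = FALSE)
    if (cen$start < 0 || cen$end > len || cen$start >= cen$end)
      stop("chromosome ", ch, ": centromere [", cen$start, ",", cen$end,
           ") outside [0,", len, ")", call. = FALSE)
    b <- g$cytobands[g$cytobands$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0L)
      stop("chromosome ", ch, ": no cytobands", call. = FALSE)
    b <- b[order(b$start), , drop = FALSE]
    if (b$start[1L] != 0)
      stop("chromosome ", ch, ": cytobands do not start at 0", call. = FALSE)
    if (b$end[nrow(b)] != len)
      stop("chromosome ", ch, ": cytobands do not reach chromosome end",
           call. = FALSE)
    if (nrow(b) > 1L) {
      gaps <- b$start[-1L] != b$end[-nrow(b)]
      if (any(gaps))
        stop("chromosome ", ch, ": cytoband tiling broken (gap or overlap) ",
             "after band ", b$band[which(gaps)[1L]], call. = FALSE)
    }
    if (any(b$end <= b$start))
      stop("chromosome ", ch, ": empty cytoband interval", call. = FALSE)
    if (!all(b$arm %in% c("p", "q")))
      stop("chromosome ", ch, ": band arm must be 'p' or 'q'", call. = FALSE)
    # p bands precede q bands in coordinate order
    if (is.unsorted(match(b$arm, c("p", "q"))))
      stop("chromosome ", ch, ": p bands must precede q bands", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$cytobands), "cytobands\n")
  cat(" total length:", sum(x$chromosomes$length), "bp\n")
  invisible(x)
}

#' Chromosome length lookup
#' @param genome a `genome_build`
#' @param chrom chromosome name
#' @return length in bp
#' @export
chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  if (anyNA(i))
    stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "),
         call. = FALSE)
  genome$chromosomes$length[i]
}

#' Load a genome build from a UCSC-style cytoband table
#'
#' Reads a tab-delimited cytoband file (columns chrom, chromStart, chromEnd,
#' name, gieStain; 0-based half-open; no header; `#` comments allowed).
#' Centromere intervals are taken as the union of the `acen`-stained bands of
#' each chromosome; chromosome lengths are inferred as the maximum band end.
#'
#' @param path path to the cytoband text file
#' @return a validated [genome_build()]
#' @export
load_genome <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("chrom", "start", "end", "band",
                                         "stain"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "character"))
  if (nrow(tab) == 0L) stop("empty cytoband table: ", path, call. = FALSE)
  tab <- tab[order(match(tab$chrom, unique(tab$chrom)), tab$start), ]
  chroms <- unique(tab$chrom)
  lengths <- vapply(chroms, function(ch) max(tab$end[tab$chrom == ch]),
                    numeric(1))
  cen <- do.call(rbind, lapply(chroms, function(ch) {
    a <- tab[tab$chrom == ch & tab$stain == "acen", , drop = FALSE]
    if (nrow(a) == 0L)
      stop("chromosome ", ch, ": no acen (centromere) bands in ", path,
           call. = FALSE)
    data.frame(chrom = ch, start = min(a$start), end = max(a$end))
  }))
  genome_build(
    chromosomes = data.frame(chrom = chroms, length = unname(lengths)),
    centromeres = cen,
    cytobands = tab
  )
}

#' Four-chromosome toy genome
#'
#' A compact build (290 Mb over chr1-chr4, each with p/q bands and an acen
#' centromere) used throughout the test-suite and the demo pipeline. All
#' segment-taxonomy and recurrence logic is band-level, so the toy build
#' exercises the same code paths as a full-size build.
#'
#' @return a [genome_build()]
#' @export
toy_genome <- function() {
  path <- system.file("extdata", "cytoband_toy.txt", package = "aupdscan",
                      mustWork = TRUE)
  load_genome(path)
}

#' Synthetic genome at human (hg18-like) scale
#'
#' A 22-autosome build whose chromosome lengths and centromere midpoints
#' approximate the hg18 human assembly, with uniform synthetic bands (about
#' 10 Mb each, named sequentially per arm). This is a synthetic stand-in for
#' a real cytoband annotation: band boundaries and names do NOT correspond to
#' Giemsa bands and must not be used to report real genomic loci. It exists
#' so simulations can be run at realistic chromosome-number/length scale.
#'
#' @param band_size target band width in bp (default 10 Mb)
#' @return a [genome_build()]
#' @export
synthetic_hg18_genome <- function(band_size = 1e7) {
  # approximate hg18 autosome lengths (bp) and centromere midpoints
  len <- c(247e6, 243e6, 199e6, 191e6, 181e6, 171e6, 159e6, 146e6, 140e6,
           135e6, 134e6, 132e6, 114e6, 106e6, 100e6, 89e6, 79e6, 76e6,
           64e6, 62e6, 47e6, 50e6)
  cen_mid <- c(124e6, 93e6, 91e6, 50e6, 48e6, 60e6, 60e6, 45e6, 49e6,
               40e6, 53e6, 35e6, 17e6, 17e6, 18e6, 38e6, 23e6, 17e6,
               27e6, 28e6, 13e6, 14e6)
  cen_half <- 1.5e6
  rows <- list()
  for (i in seq_along(len)) {
    ch <- paste0("chr", i)
    cs <- cen_mid[i] - cen_half
    ce <- cen_mid[i] + cen_half
    p_cuts <- unique(c(seq(0, cs, by = band_size), cs))
    q_cuts <- unique(c(seq(ce, len[i], by = band_size), len[i]))
    np <- length(p_cuts) - 1L
    nq <- length(q_cuts) - 1L
    starts <- c(p_cuts[-length(p_cuts)], cs, cen_mid[i],
                q_cuts[-length(q_cuts)])
    ends <- c(p_cuts[-1L], cen_mid[i], ce, q_cuts[-1L])
    rows[[ch]] <- data.frame(
      chrom = ch,
      start = starts,
      end   = ends,
      # p bands numbered outward from the centromere; acen halves p11/q11
      band  = c(paste0("p", rev(seq_len(np) + 11L)), "p11", "q11",
                paste0("q", seq_len(nq) + 11L)),
      stain = c(rep("gneg", np), "acen", "acen", rep("gneg", nq))
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  genome_build(
    chromosomes = data.frame(chrom = paste0("chr", seq_along(len)),
                             length = len),
    centromeres = data.frame(chrom = paste0("chr", seq_along(len)),
                             start = cen_mid - cen_half,
                             end = cen_mid + cen_half),
    cytobands = tab
  )
}

#' Locate the cytoband containing a position
#'
#' Bands are half-open, so a position equal to a band's end falls in the next
#' band.
#'
#' @param genome a `genome_build`
#' @param chrom chromosome name
#' @param pos 0-based position(s); must satisfy `0 <= pos < length`
#' @return band name(s)
#' @export
locate_band <- function(genome, chrom, pos) {
  len <- chrom_length(genome, chrom)
  if (any(pos < 0 | pos >= len))
    stop("position out of range [0,", len, ") on ", chrom, call. = FALSE)
  b <- genome$cytobands[genome$cytobands$chrom == chrom, , drop = FALSE]
  b <- b[order(b$start), , drop = FALSE]
  b$band[findInterval(pos, b$start)]
}

#' Overlap length of two half-open genomic intervals
#'
#' @param a,b lists or one-row data.frames with fields `chrom`, `start`,
#'   `end` (0-based half-open)
#' @return overlap in bp (0 when chromosomes differ or intervals are
#'   disjoint; abutting intervals overlap by 0)
#' @export
overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

# vectorized overlap of one interval against parallel vectors
overlap_bp_vec <- function(chrom, start, end, chroms, starts, ends) {
  ifelse(chroms == chrom, pmax(0, pmin(ends, end) - pmax(starts, start)), 0)
}

# per-chromosome arm extents derived from the band table
arm_intervals <- function(genome) {
  cb <- genome$cytobands
  key <- paste(cb$chrom, cb$arm)
  starts <- tapply(cb$start, key, min)
  ends <- tapply(cb$end, key, max)
  parts <- strsplit(names(starts), " ", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    arm = vapply(parts, `[`, "", 2L),
    start = as.numeric(starts),
    end = as.numeric(ends)
  )
  out[order(match(out$chrom, genome$chromosomes$chrom), out$start), ]
}
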