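# Readers and writers for the pipeline's tab-delimited formats. Marker
# positions are 1-based in files and 0-based half-open in memory; the
# conversion happens here and nowhere else. Segment/truth tables are
# BED-compatible (0-based half-open) both on disk and in memory.

marker_cols <- c("marker_id", "chrom", "pos", "genotype_tumor",
                 "genotype_normal", "baf", "logr")

#' Read a per-sample SNP marker table
#'
#' Tab-delimited with header columns marker_id, chrom, pos (1-based),
#' genotype_tumor, optional genotype_normal, baf, logr. `#` lines are
#' ignored. Parse failures report the offending line number.
#'
#' @param path file path
#' @return data.frame: marker_id, chrom, pos (0-based), gt_tumor,
#'   gt_normal, baf, logr
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("no such marker table: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- setdiff(c("marker_id", "chrom", "pos", "genotype_tumor"),
                  names(tab))
  if (length(need))
    stop("marker table ", path, " lacks columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  pos <- suppressWarnings(as.numeric(tab$pos))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop("marker table ", path, ": unparseable position at data line ", bad,
         call. = FALSE)
  }
  if (any(pos < 1)) {
    bad <- which(pos < 1)[1L]
    stop("marker table ", path, ": position < 1 at data line ", bad,
         " (file positions are 1-based)", call. = FALSE)
  }
  data.frame(marker_id = as.character(tab$marker_id),
             chrom = as.character(tab$chrom),
             pos = pos - 1,
             gt_tumor = as.character(tab$genotype_tumor),
             gt_normal = if ("genotype_normal" %in% names(tab))
               as.character(tab$genotype_normal) else NA_character_,
             baf = if ("baf" %in% names(tab)) as.numeric(tab$baf)
                   else NA_real_,
             logr = if ("logr" %in% names(tab)) as.numeric(tab$logr)
                    else NA_real_)
}

#' Write a per-sample SNP marker table
#'
#' Inverse of [read_marker_table()]; in-memory 0-based positions are written
#' 1-based.
#'
#' @param markers marker data.frame (internal layout)
#' @param path file path
#' @param header optional `#` comment lines to prepend
#' @export
write_marker_table <- function(markers, path, header = NULL) {
  out <- data.frame(marker_id = markers$marker_id, chrom = markers$chrom,
                    pos = markers$pos + 1,
                    genotype_tumor = markers$gt_tumor,
                    genotype_normal = markers$gt_normal,
                    baf = markers$baf, logr = markers$logr)
  write_tsv_with_header(out, path, header)
}

#' Write a TSV with optional comment header
#' @param df data.frame (list-columns are dropped)
#' @param path file path
#' @param header character vector of comment lines (written as `# ...`)
#' @export
write_tsv_with_header <- function(df, path, header = NULL) {
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  # 9-decimal rounding makes write -> read -> write byte-stable (15
  # significant digits, the write.table default, does not round-trip)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], round, digits = 9L)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_with_header()]
#' @param path file path
#' @return data.frame
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a cohort manifest
#' @param path TSV with columns sample_id, subtype, translocation_class,
#'   file
#' @return data.frame
#' @export
read_manifest <- function(path) {
  tab <- read_tsv_table(path)
  need <- setdiff(c("sample_id", "subtype", "translocation_class"),
                  names(tab))
  if (length(need))
    stop("manifest ", path, " lacks columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' Read a planted-truth event table (0-based half-open on disk)
#' @param path file path
#' @return data.frame
#' @export
read_truth <- function(path) read_tsv_table(path)

#' Write / read the segment table (BED-like TSV, 0-based half-open)
#' @param segments segment data.frame
#' @param path file path
#' @param header optional comment lines
#' @export
write_segments <- function(segments, path, header = NULL)
  write_tsv_with_header(segments, path, header)

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  tab <- read_tsv_table(path)
  if (nrow(tab) > 0 && !"class" %in% names(tab)) tab$class <- NA_character_
  if (nrow(tab) > 0) tab$class <- as.character(tab$class)
  tab
}

# 32-bit FNV-1a over a string; used to stamp outputs with a config
# fingerprint (no cryptographic intent)
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor via 16-bit halves (bitwXor works on 32-bit signed ints)
    h <- bitwXor(h %% 65536, b) + (h %/% 65536) * 65536
    # modular multiply in 16-bit limbs to stay inside double precision
    lo <- (h %% 65536) * p
    hi <- ((h %/% 65536) * p) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
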