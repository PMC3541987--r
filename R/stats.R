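#' Per-sample aUPD counts by class
#'
#' Counts each sample's copy-neutral segments by taxonomy class. Total is
#' the count of all aUPD regions; segmental is telomeric plus centromeric;
#' total = segmental + whole by construction. Samples present in the
#' manifest but absent from the segment table get all-zero rows.
#'
#' @param segments classified segment table (every aUPD row must have a
#'   class)
#' @param manifest cohort manifest
#' @return data.frame: sample_id, total, whole, segmental, telomeric,
#'   centromeric
#' @export
per_sample_counts <- function(segments, manifest) {
  seg <- segments[segments$status == "aUPD", , drop = FALSE]
  if (nrow(seg) > 0L) {
    if (anyNA(seg$class))
      stop("unclassified aUPD segments; run classify_segments() first",
           call. = FALSE)
    orphan <- setdiff(unique(seg$sample_id), manifest$sample_id)
    if (length(orphan))
      stop("segments for samples missing from manifest: ",
           paste(orphan, collapse = ", "), call. = FALSE)
  }
  count_class <- function(sid, cl)
    sum(seg$sample_id == sid & seg$class == cl)
  out <- data.frame(
    sample_id = manifest$sample_id,
    whole = vapply(manifest$sample_id, count_class, 0L, cl = "whole"),
    telomeric = vapply(manifest$sample_id, count_class, 0L, cl = "telomeric"),
    centromeric = vapply(manifest$sample_id, count_class, 0L,
                         cl = "centromeric"))
  out$segmental <- out$telomeric + out$centromeric
  out$total <- out$segmental + out$whole
  rownames(out) <- NULL
  out[, c("sample_id", "total", "whole", "segmental", "telomeric",
          "centromeric")]
}

#' Per-group aUPD burden summary
#'
#' For each group (subtype or translocation class): sample count, number of
#' aUPD-positive samples (at least one region), the positive percentage,
#' per-class region totals, and the per-sample frequency vector used by the
#' rank tests. Percentages are stored at full precision; rounding to printed
#' precision is presentation-only (see [format_percentage()]).
#'
#' @param counts output of [per_sample_counts()]
#' @param manifest cohort manifest
#' @param grouping manifest column to group by
#' @return data.frame with one row per group and a list-column
#'   `frequencies` of per-sample total counts
#' @export
group_summary <- function(counts, manifest,
                          grouping = c("subtype", "translocation_class")) {
  grouping <- match.arg(grouping)
  if (!grouping %in% names(manifest))
    stop("manifest lacks grouping column ", grouping, call. = FALSE)
  merged <- merge(counts, manifest[, c("sample_id", grouping)],
                  by = "sample_id", sort = FALSE)
  groups <- unique(manifest[[grouping]])
  rows <- lapply(groups, function(g) {
    sub <- merged[merged[[grouping]] == g, , drop = FALSE]
    n <- nrow(sub)
    npos <- sum(sub$total >= 1)
    data.frame(group = g, n_samples = n, n_positive = npos,
               percentage_positive = if (n > 0) 100 * npos / n else NA_real_,
               total = sum(sub$total), whole = sum(sub$whole),
               segmental = sum(sub$segmental),
               telomeric = sum(sub$telomeric),
               centromeric = sum(sub$centromeric),
               mean_per_sample = if (n > 0) sum(sub$total) / n else NA_real_,
               median_per_sample = if (n > 0) stats::median(sub$total)
                                   else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$frequencies <- lapply(groups, function(g)
    merged$total[merged[[grouping]] == g])
  out$undefined <- out$n_samples == 0
  rownames(out) <- NULL
  out
}

#' Round a percentage to printed precision
#' @param x percentage value(s)
#' @param digits decimal places (default 1)
#' @return numeric, rounded
#' @export
format_percentage <- function(x, digits = 1L) round(x, digits)

#' Kruskal-Wallis rank test
#'
#' Mid-ranks over the pooled data;
#' `H = 12 / (N (N + 1)) * sum n_i (Rbar_i - (N + 1) / 2)^2`, divided by the
#' tie correction `1 - sum(t^3 - t) / (N^3 - N)`; p-value from the
#' chi-square upper tail with k - 1 degrees of freedom. When all pooled
#' values are identical the statistic is defined as 0 with p = 1.
#'
#' @param groups list of at least two non-empty numeric vectors
#' @return list: H, df, p_value, tie_correction
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("empty group", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("NA in group data", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations in total", call. = FALSE)
  r <- rank(x)
  g <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, g, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  t_counts <- table(x)
  corr <- 1 - sum(t_counts^3 - t_counts) / (n^3 - n)
  if (corr <= 0) {
    h <- 0; p <- 1
  } else {
    h <- h / corr
    p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  }
  list(H = h, df = length(groups) - 1L, p_value = p, tie_correction = corr)
}

#' Compare aUPD burden between translocation classes
#'
#' One two-group Kruskal-Wallis test per region category (total, telomeric,
#' centromeric, segmental, whole) between translocation and
#' non-translocation samples. Raw p-values, no multiplicity adjustment
#' (`adjust = "BH"` opts into Benjamini-Hochberg). Direction is the
#' difference of group means, non-translocation minus translocation.
#'
#' @param counts output of [per_sample_counts()]
#' @param manifest cohort manifest with `translocation_class` in
#'   {"translocation", "non_translocation"} for every sample
#' @param adjust "none" (default) or "BH"
#' @return data.frame: category, H, df, p_value, direction
#' @export
translocation_comparison <- function(counts, manifest, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  merged <- merge(counts, manifest[, c("sample_id", "translocation_class")],
                  by = "sample_id", sort = FALSE)
  if (!all(c("translocation", "non_translocation") %in%
             merged$translocation_class))
    stop("both translocation classes must be present", call. = FALSE)
  cats <- c("total", "telomeric", "centromeric", "segmental", "whole")
  rows <- lapply(cats, function(cat) {
    nt <- merged[[cat]][merged$translocation_class == "non_translocation"]
    tr <- merged[[cat]][merged$translocation_class == "translocation"]
    kw <- kruskal_wallis(list(non_translocation = nt, translocation = tr))
    data.frame(category = cat, H = kw$H, df = kw$df, p_value = kw$p_value,
               direction = mean(nt) - mean(tr))
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
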