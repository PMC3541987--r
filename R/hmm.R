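#' Parameters of the aUPD segmentation HMM
#'
#' A two-state hidden Markov model over per-chromosome genotype-call
#' sequences: state RET (retained heterozygosity) emits heterozygous calls at
#' the population rate, state UPD emits them only at a small leak rate
#' (genotyping error inside a uniparental region). Transitions relax toward
#' the stationary distribution with genomic distance. Copy number is not part
#' of the state space; copy-neutrality is enforced post hoc on the mean logR
#' of each called segment.
#'
#' @param het_rate probability of a Het call at a marker in the RET state
#'   (population heterozygosity; unpaired mode)
#' @param het_rate_paired same, when markers are pre-filtered to
#'   heterozygous-in-normal (paired mode): 1 minus the het-call error rate
#' @param upd_het_leak probability of a Het call inside aUPD
#' @param no_call_rate probability of an NC call in either state
#' @param prior_upd stationary probability of the UPD state
#' @param decay_length bp scale of state persistence
#' @param min_markers minimum markers for a reported segment
#' @param min_length minimum segment length (bp)
#' @param neutral_band segments with |mean logR| within this band are
#'   copy-neutral (status `aUPD`)
#' @param deletion_threshold mean logR at or below this is a deletion-LOH
#' @return list of class `hmm_params`
#' @export
hmm_params <- function(het_rate = 0.30,
                       het_rate_paired = 0.98,
                       upd_het_leak = 0.02,
                       no_call_rate = 0.02,
                       prior_upd = 0.01,
                       decay_length = 1e7,
                       min_markers = 25L,
                       min_length = 1e6,
                       neutral_band = 0.30,
                       deletion_threshold = -0.8) {
  probs <- c(het_rate, het_rate_paired, upd_het_leak, no_call_rate, prior_upd)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0,1]", call. = FALSE)
  if (upd_het_leak >= het_rate)
    stop("upd_het_leak must be smaller than het_rate", call. = FALSE)
  if (decay_length <= 0) stop("decay_length must be positive", call. = FALSE)
  structure(list(het_rate = het_rate, het_rate_paired = het_rate_paired,
                 upd_het_leak = upd_het_leak, no_call_rate = no_call_rate,
                 prior_upd = prior_upd, decay_length = decay_length,
                 min_markers = as.integer(min_markers),
                 min_length = min_length, neutral_band = neutral_band,
                 deletion_threshold = deletion_threshold),
            class = "hmm_params")
}

# genotype call -> emission category
call_category <- function(gt) {
  out <- ifelse(gt == "AB", "Het",
                ifelse(gt %in% c("AA", "BB"), "Hom",
                       ifelse(gt == "NC", "NoCall", NA_character_)))
  if (anyNA(out))
    stop("unknown genotype call: ",
         paste(unique(gt[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Emission log-probability
#'
#' In RET, Het calls occur at rate `h`; in UPD only at the leak rate. The
#' no-call rate is state-independent: P(Het) = h(1-nu), P(Hom) = (1-h)(1-nu),
#' P(NoCall) = nu, with h replaced by the leak inside UPD.
#'
#' @param call "Het", "Hom" or "NoCall" (vectorized)
#' @param state "RET" or "UPD"
#' @param params an [hmm_params()]
#' @param het_rate RET-state het rate; defaults to `params$het_rate`
#'   (paired callers pass `params$het_rate_paired`)
#' @return natural-log probabilities
#' @export
emission_logprob <- function(call, state, params,
                             het_rate = params$het_rate) {
  if (!state %in% c("RET", "UPD"))
    stop("state must be RET or UPD", call. = FALSE)
  if (!all(call %in% c("Het", "Hom", "NoCall")))
    stop("unknown call category: ",
         paste(setdiff(unique(call), c("Het", "Hom", "NoCall")),
               collapse = ", "), call. = FALSE)
  h <- if (state == "RET") het_rate else params$upd_het_leak
  nu <- params$no_call_rate
  p <- c(Het = h * (1 - nu), Hom = (1 - h) * (1 - nu), NoCall = nu)
  log(unname(p[call]))
}

#' Distance-dependent transition matrix
#'
#' With relaxation `rho = 1 - exp(-d / decay_length)` and stationary vector
#' `pi = (1 - prior_upd, prior_upd)`, the transition probability is
#' `(1 - rho) * [s == s'] + rho * pi[s']`: the identity at zero distance,
#' the stationary distribution in the long-distance limit.
#'
#' @param distance_bp inter-marker distance (>= 0)
#' @param params an [hmm_params()]
#' @return 2x2 row-stochastic matrix with rows/columns RET, UPD
#' @export
transition_probs <- function(distance_bp, params) {
  if (distance_bp < 0) stop("distance must be >= 0", call. = FALSE)
  rho <- 1 - exp(-distance_bp / params$decay_length)
  pi_vec <- c(1 - params$prior_upd, params$prior_upd)
  m <- (1 - rho) * diag(2) + rho * rbind(pi_vec, pi_vec)
  dimnames(m) <- list(c("RET", "UPD"), c("RET", "UPD"))
  m
}

#' Viterbi decoding of one chromosome
#'
#' Computes the jointly most probable RET/UPD state path in log space under
#' the stationary initial distribution, distance-dependent transitions and
#' the genotype-call emissions. Ties are broken toward RET (conservative
#' calling: false aUPD pollutes recurrence maps).
#'
#' @param calls emission categories ("Het"/"Hom"/"NoCall"), one per marker
#' @param positions 0-based positions, strictly increasing
#' @param params an [hmm_params()]
#' @param het_rate RET-state het rate (see [emission_logprob()])
#' @return character vector of states ("RET"/"UPD") along the sequence
#' @export
viterbi_decode <- function(calls, positions, params,
                           het_rate = params$het_rate) {
  n <- length(calls)
  if (n == 0L) return(character(0))
  if (length(positions) != n)
    stop("calls and positions differ in length", call. = FALSE)
  if (n > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)

  e_ret <- emission_logprob(calls, "RET", params, het_rate)
  e_upd <- emission_logprob(calls, "UPD", params, het_rate)
  lp0 <- log(c(1 - params$prior_upd, params$prior_upd))

  if (n > 1L) {
    rho <- 1 - exp(-diff(positions) / params$decay_length)
    piU <- params$prior_upd
    lt_rr <- log((1 - rho) + rho * (1 - piU))
    lt_ru <- log(rho * piU)
    lt_ur <- log(rho * (1 - piU))
    lt_uu <- log((1 - rho) + rho * piU)
  }

  d_ret <- lp0[1] + e_ret[1]
  d_upd <- lp0[2] + e_upd[1]
  bp <- matrix(1L, nrow = 2L, ncol = n)
  if (n > 1L) {
    for (t in 2:n) {
      i <- t - 1L
      # into RET: tie prefers RET predecessor
      a <- d_ret + lt_rr[i]; b <- d_upd + lt_ur[i]
      if (a >= b) { nr <- a; bp[1L, t] <- 1L } else { nr <- b; bp[1L, t] <- 2L }
      # into UPD
      a <- d_ret + lt_ru[i]; b <- d_upd + lt_uu[i]
      if (a >= b) { nu <- a; bp[2L, t] <- 1L } else { nu <- b; bp[2L, t] <- 2L }
      d_ret <- nr + e_ret[t]
      d_upd <- nu + e_upd[t]
    }
  }
  path <- integer(n)
  path[n] <- if (d_ret >= d_upd) 1L else 2L
  if (n > 1L) for (t in n:2) path[t - 1L] <- bp[path[t], t]
  c("RET", "UPD")[path]
}

#' Extract candidate segments from a state path
#'
#' Maximal runs of the UPD state become segments spanning the first to last
#' marker of the run (end exclusive: last position + 1). Runs with fewer than
#' `min_markers` markers or shorter than `min_length` are dropped.
#'
#' @param path state vector from [viterbi_decode()]
#' @param positions marker positions aligned with `path`
#' @param calls emission categories aligned with `path` (for the
#'   heterozygous-call count)
#' @param params an [hmm_params()]
#' @return data.frame: start, end, n_markers, n_het_markers, first_idx,
#'   last_idx (marker indices of the run)
#' @export
segments_from_path <- function(path, positions, calls, params) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_markers = integer(0), n_het_markers = integer(0),
                      first_idx = integer(0), last_idx = integer(0))
  if (length(path) != length(positions))
    stop("path and positions differ in length", call. = FALSE)
  if (!any(path == "UPD")) return(empty)
  r <- rle(path == "UPD")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    i <- starts[k]; j <- ends[k]
    data.frame(start = positions[i], end = positions[j] + 1,
               n_markers = j - i + 1L,
               n_het_markers = sum(calls[i:j] == "Het"),
               first_idx = i, last_idx = j)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_markers >= params$min_markers &
               (out$end - out$start) >= params$min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Copy-neutrality filter
#'
#' aUPD is loss of heterozygosity WITHOUT copy-number change; a candidate
#' segment is accepted as aUPD only if its mean logR sits inside the neutral
#' band. Deeply negative segments are deletion-LOH (hemizygous loss), all
#' others are rejected.
#'
#' @param mean_logr mean logR over the segment's markers
#' @param params an [hmm_params()]
#' @return "aUPD", "deletion_LOH" or "rejected"
#' @export
loh_status <- function(mean_logr, params) {
  if (length(mean_logr) == 0 || anyNA(mean_logr))
    stop("segment has no markers with logR", call. = FALSE)
  ifelse(abs(mean_logr) <= params$neutral_band, "aUPD",
         ifelse(mean_logr <= params$deletion_threshold, "deletion_LOH",
                "rejected"))
}

#' Call LOH segments in one sample
#'
#' Markers are canonicalized (sorted by position per chromosome; duplicate
#' positions rejected), decoded chromosome by chromosome, and candidate
#' segments are passed through the copy-neutrality filter. In paired mode
#' only markers heterozygous in the matched normal are decoded, with the
#' paired het rate.
#'
#' @param markers marker data.frame (marker_id, chrom, pos, gt_tumor,
#'   optional gt_normal, baf, logr), 0-based positions
#' @param params an [hmm_params()]
#' @param mode "unpaired" or "paired"
#' @param sample_id sample label attached to output rows
#' @return segment data.frame: sample_id, chrom, start, end, n_markers,
#'   n_het_markers, mean_logr, status, class (NA until classified)
#' @export
call_sample <- function(markers, params, mode = c("unpaired", "paired"),
                        sample_id = "sample") {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(markers$gt_normal) || all(is.na(markers$gt_normal)))
      stop("paired mode requires a gt_normal column", call. = FALSE)
    markers <- markers[markers$gt_normal == "AB", , drop = FALSE]
    h <- params$het_rate_paired
  } else {
    h <- params$het_rate
  }
  out <- list()
  for (ch in sort(unique(markers$chrom))) {
    m <- markers[markers$chrom == ch, , drop = FALSE]
    m <- m[order(m$pos), , drop = FALSE]
    if (anyDuplicated(m$pos))
      stop("duplicate marker positions on ", ch, call. = FALSE)
    if (nrow(m) == 0L) next
    calls <- call_category(m$gt_tumor)
    path <- viterbi_decode(calls, m$pos, params, het_rate = h)
    seg <- segments_from_path(path, m$pos, calls, params)
    if (nrow(seg) == 0L) next
    seg$mean_logr <- vapply(seq_len(nrow(seg)), function(i)
      mean(m$logr[seg$first_idx[i]:seg$last_idx[i]]), numeric(1))
    seg$status <- loh_status(seg$mean_logr, params)
    out[[ch]] <- data.frame(sample_id = sample_id, chrom = ch,
                            start = seg$start, end = seg$end,
                            n_markers = seg$n_markers,
                            n_het_markers = seg$n_het_markers,
                            mean_logr = seg$mean_logr,
                            status = seg$status,
                            class = NA_character_)
  }
  if (length(out) == 0L) return(empty_segments())
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

empty_segments <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), n_markers = integer(0),
             n_het_markers = integer(0), mean_logr = numeric(0),
             status = character(0), class = character(0))
}

#' Call LOH segments across a cohort
#'
#' @param manifest data.frame with at least `sample_id`; when `samples` is
#'   NULL it must also carry a `file` column with marker-table paths
#'   (interpreted relative to `dir`)
#' @param params an [hmm_params()]
#' @param mode "unpaired" or "paired"
#' @param samples optional named list of in-memory marker data.frames
#' @param dir base directory for manifest file paths
#' @return segment table over all samples (see [call_sample()])
#' @export
call_cohort <- function(manifest, params = hmm_params(),
                        mode = c("unpaired", "paired"),
                        samples = NULL, dir = ".") {
  mode <- match.arg(mode)
  if (nrow(manifest) == 0L) return(empty_segments())
  out <- lapply(manifest$sample_id, function(sid) {
    m <- if (!is.null(samples)) samples[[sid]]
         else read_marker_table(file.path(dir,
                                          manifest$file[manifest$sample_id == sid]))
    if (is.null(m)) stop("no marker data for sample ", sid, call. = FALSE)
    call_sample(m, params, mode, sample_id = sid)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
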