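#' Pipeline configuration
#'
#' One structured object drives the end-to-end pipeline. It can be built in
#' code or parsed from a JSON file with one block per component; unknown
#' keys are rejected so typos fail loudly.
#'
#' @param out_dir output directory for all artifacts
#' @param genome "toy", "hg18like", or a path to a UCSC-style cytoband file
#' @param manifest path to an existing cohort manifest (ignored when the
#'   simulate stage runs, which writes its own)
#' @param mode "unpaired" or "paired" calling
#' @param seed integer seed, recorded in every output header
#' @param hmm named list of [hmm_params()] overrides
#' @param classifier named list of [classifier_thresholds()] overrides
#' @param recurrence list with `min_frequency` and `min_samples`
#' @param simulation named list of [simulation_config()] overrides (the
#'   genome and seed come from this config)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir,
                            genome = "toy",
                            manifest = NULL,
                            mode = c("unpaired", "paired"),
                            seed = 1L,
                            hmm = list(),
                            classifier = list(),
                            recurrence = list(min_frequency = 0.1,
                                              min_samples = 3L),
                            simulation = list()) {
  mode <- match.arg(mode)
  allowed_sim <- setdiff(names(formals(simulation_config)),
                         c("genome", "seed"))
  check_keys(simulation, allowed_sim, "simulation")
  check_keys(hmm, names(formals(hmm_params)), "hmm")
  check_keys(classifier, names(formals(classifier_thresholds)), "classifier")
  check_keys(recurrence, c("min_frequency", "min_samples"), "recurrence")
  structure(list(out_dir = out_dir, genome = genome, manifest = manifest,
                 mode = mode, seed = as.integer(seed), hmm = hmm,
                 classifier = classifier, recurrence = recurrence,
                 simulation = simulation),
            class = "pipeline_config")
}

check_keys <- function(x, allowed, block) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", block, " config: ", paste(bad, collapse = ", "),
         call. = FALSE)
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with the blocks of [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(raw, names(formals(pipeline_config)), "top-level")
  do.call(pipeline_config, raw)
}

resolve_genome <- function(spec) {
  if (inherits(spec, "genome_build")) return(spec)
  if (identical(spec, "toy")) return(toy_genome())
  if (identical(spec, "hg18like")) return(synthetic_hg18_genome())
  load_genome(spec)
}

#' Run the aUPD analysis pipeline
#'
#' Stages run in fixed order (simulate, call, classify, recur, stats); each
#' stage reads the previous stage's on-disk artifacts from `config$out_dir`,
#' so a run can be split across invocations. Every output carries a header
#' with the package version, a config fingerprint and the seed; deterministic
#' stages are byte-identical on rerun.
#'
#' Artifacts: `manifest.tsv`, `markers/<sample>.tsv`, `truth.tsv`,
#' `truth_lesions.tsv` (simulate); `segments.tsv` (call); classified
#' `segments.tsv` plus `lesions.tsv` (classify); `recurrence_bands.tsv`,
#' `recurrence_arms.tsv`, `recurrent_regions.tsv` (recur);
#' `summary_subtype.tsv`, `summary_class.tsv`, `comparison.tsv` (stats).
#'
#' @param config a [pipeline_config()]
#' @param stages subset of c("simulate","call","classify","recur","stats")
#' @return invisibly, a list of the in-memory results of the stages run
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "call", "classify",
                                    "recur", "stats")) {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c("simulate", "call", "classify", "recur", "stats")
  bad <- setdiff(stages, order_all)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- order_all[order_all %in% stages]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- resolve_genome(config$genome)
  params <- do.call(hmm_params, config$hmm)
  th <- do.call(classifier_thresholds, config$classifier)
  hdr <- output_header(config)
  res <- list()

  stage_log <- function(name, expr) {
    t0 <- Sys.time()
    message("[aupdscan] stage ", name, " ...")
    v <- force(expr)
    message("[aupdscan] stage ", name, " done in ",
            format(round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                         1)), "s")
    v
  }

  path <- function(f) file.path(config$out_dir, f)

  if ("simulate" %in% stages) {
    res$cohort <- stage_log("simulate", {
      sim_args <- c(list(genome = genome, seed = config$seed),
                    config$simulation)
      sim_cfg <- do.call(simulation_config, sim_args)
      simulate_cohort(sim_cfg, dir = config$out_dir)
    })
  }

  if ("call" %in% stages) {
    res$segments <- stage_log("call", {
      manifest <- load_manifest(config)
      segs <- call_cohort(manifest, params, mode = config$mode,
                          samples = res$cohort$samples, dir = config$out_dir)
      write_segments(segs, path("segments.tsv"), hdr)
      segs
    })
  }

  if ("classify" %in% stages) {
    res$segments <- stage_log("classify", {
      segs <- if (!is.null(res$segments)) res$segments
              else read_segments(require_artifact(path("segments.tsv"),
                                                  "call"))
      samples <- load_samples(config, res)
      segs <- classify_segments(segs, genome, th, markers = samples)
      write_segments(segs, path("segments.tsv"), hdr)
      lesions <- overlay_cn_features(segs, samples, th)
      write_tsv_with_header(lesions, path("lesions.tsv"), hdr)
      res$lesions <- lesions
      segs
    })
  }

  if ("recur" %in% stages) {
    res$recurrence <- stage_log("recur", {
      segs <- if (!is.null(res$segments)) res$segments
              else read_segments(require_artifact(path("segments.tsv"),
                                                  "classify"))
      manifest <- load_manifest(config)
      bands <- do.call(rbind, lapply(
        c(list(NULL), as.list(unique(manifest$subtype))),
        function(st) band_frequency_map(segs, manifest, genome, st)))
      arms <- do.call(rbind, lapply(
        c(list(NULL), as.list(unique(manifest$subtype))),
        function(st) arm_frequency_map(segs, manifest, genome, st)))
      rec <- do.call(rbind, lapply(unique(bands$subtype), function(st)
        recurrent_regions(bands[bands$subtype == st, , drop = FALSE],
                          min_frequency = config$recurrence$min_frequency,
                          min_samples = config$recurrence$min_samples,
                          genome = genome)))
      write_tsv_with_header(bands, path("recurrence_bands.tsv"), hdr)
      write_tsv_with_header(arms, path("recurrence_arms.tsv"), hdr)
      write_tsv_with_header(rec, path("recurrent_regions.tsv"), hdr)
      list(bands = bands, arms = arms, regions = rec)
    })
  }

  if ("stats" %in% stages) {
    res$stats <- stage_log("stats", {
      segs <- if (!is.null(res$segments)) res$segments
              else read_segments(require_artifact(path("segments.tsv"),
                                                  "classify"))
      manifest <- load_manifest(config)
      counts <- per_sample_counts(segs, manifest)
      by_subtype <- group_summary(counts, manifest, "subtype")
      by_class <- group_summary(counts, manifest, "translocation_class")
      cmp <- translocation_comparison(counts, manifest)
      write_tsv_with_header(counts, path("sample_counts.tsv"), hdr)
      write_tsv_with_header(by_subtype, path("summary_subtype.tsv"), hdr)
      write_tsv_with_header(by_class, path("summary_class.tsv"), hdr)
      write_tsv_with_header(cmp, path("comparison.tsv"), hdr)
      list(counts = counts, by_subtype = by_subtype, by_class = by_class,
           comparison = cmp)
    })
  }

  invisible(res)
}

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing upstream artifact ", path, "; run stage '", stage,
         "' first", call. = FALSE)
  path
}

load_manifest <- function(config) {
  p <- file.path(config$out_dir, "manifest.tsv")
  if (file.exists(p)) return(read_manifest(p))
  if (!is.null(config$manifest)) return(read_manifest(config$manifest))
  stop("no manifest: run the simulate stage or set config$manifest",
       call. = FALSE)
}

load_samples <- function(config, res) {
  if (!is.null(res$cohort$samples)) return(res$cohort$samples)
  manifest <- load_manifest(config)
  out <- lapply(manifest$sample_id, function(sid) {
    f <- manifest$file[manifest$sample_id == sid]
    if (is.na(f)) return(NULL)
    read_marker_table(file.path(config$out_dir, f))
  })
  names(out) <- manifest$sample_id
  Filter(Negate(is.null), out)
}

output_header <- function(config) {
  cfg_string <- paste(
    jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                     auto_unbox = TRUE, force = TRUE),
    collapse = "")
  c(paste0("aupdscan ",
           as.character(utils::packageVersion("aupdscan"))),
    paste0("config_hash=", fnv1a(cfg_string)),
    paste0("seed=", config$seed))
}
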