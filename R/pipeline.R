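# Pipeline orchestration: one reproducible run from phantom simulation (or
# ingested projections) through preprocessing, alignment, reconstruction,
# segmentation and quantification, with per-stage caching and provenance.

config_blocks <- function() {
  list(phantom = names(formals(phantom_spec)),
       acquisition = names(formals(acquisition_spec)),
       preprocess = names(formals(preprocess_params)),
       reconstruct = names(formals(reconstruction_params)),
       segment = names(formals(segmentation_params)),
       quantify = c("edges_um", "reference_csv", "delineate_tumor"))
}

#' Assemble and validate a pipeline configuration
#'
#' A configuration is a named list with one block per stage (all optional;
#' defaults fill the gaps), a global `seed` that is fanned out to per-stage
#' seeds by a fixed derivation, and `reconstruct_from` selecting whether the
#' reconstruction consumes the range-cut-only projections (default; CLAHE is
#' non-linear, so quantitative work avoids it) or the CLAHE-equalized ones.
#' Unknown keys anywhere are rejected outright.
#'
#' @param config named list or path to a YAML file.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known_top <- c(names(config_blocks()), "seed", "reconstruct_from", "input_projections")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  blocks <- config_blocks()
  for (b in names(blocks)) {
    extra <- setdiff(names(config[[b]]), blocks[[b]])
    if (length(extra))
      stop("unknown keys in '", b, "' block: ", paste(extra, collapse = ", "))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$reconstruct_from <- match.arg(config$reconstruct_from %||% "range_cut",
                                       c("range_cut", "clahe"))
  q <- config$quantify %||% list()
  q$edges_um <- q$edges_um %||% seq(0, 400, by = 25)
  q$delineate_tumor <- isTRUE(q$delineate_tumor)
  config$quantify <- q
  structure(config, class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path optional output file.
#' @return The YAML string, invisibly if written to a file.
#' @export
write_pipeline_config <- function(config, path = NULL) {
  txt <- yaml::as.yaml(unclass(config), precision = 15L)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

stage_params <- function(config, block, constructor, seed_name = NULL) {
  args <- config[[block]] %||% list()
  if (!is.null(seed_name))
    args$seed <- args$seed %||% derive_seed(config$seed, block)
  do.call(constructor, args)
}

#' Run the full OPT analysis pipeline
#'
#' Executes simulate (or ingest) -> preprocess -> align -> reconstruct ->
#' segment -> quantify into `out_dir`. Each stage writes its outputs plus a
#' provenance record (parameter hash, input hash, wall time); a re-run with
#' an identical configuration loads cached stage outputs instead of
#' recomputing, and a stage re-executes when its record or outputs are
#' missing, its hash changed, or any upstream stage re-executed.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible to one).
#' @param out_dir run directory.
#' @param force re-execute everything, ignoring cached outputs.
#' @return A list: `dir`, `stages_run`, `alignment`, `islets` (data.frame),
#'   `distribution`, `comparison` (or NULL), `truth` (phantom ground-truth
#'   islet table, when simulated), `outputs` (file paths).
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  config <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  prov_path <- file.path(out_dir, "provenance.yaml")
  prov <- if (file.exists(prov_path)) yaml::read_yaml(prov_path) else list()
  stages_run <- character()
  upstream_ran <- FALSE
  # stage hashes chain parameters (not data): each stage's identity is its
  # own parameters plus the identity of everything upstream, so cache checks
  # are stable across lossy float32 round trips of intermediate files
  chain <- as.character(utils::packageVersion("aftomo"))

  run_stage <- function(name, hash_input, outputs, compute, load) {
    h <- md5_of(list(chain, name, hash_input))
    chain <<- h
    rec <- prov[[name]]
    cached <- !force && !upstream_ran && !is.null(rec) &&
      identical(rec$hash, h) && all(file.exists(file.path(out_dir, outputs)))
    if (cached) {
      message(sprintf("[aftomo] %-11s cached", name))
      return(load())
    }
    t0 <- proc.time()[["elapsed"]]
    res <- compute()
    dt <- proc.time()[["elapsed"]] - t0
    prov[[name]] <<- list(hash = h, outputs = outputs,
                          wall_s = round(dt, 3),
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    yaml::write_yaml(prov, prov_path)
    stages_run <<- c(stages_run, name)
    upstream_ran <<- TRUE
    message(sprintf("[aftomo] %-11s ran in %.1f s", name, dt))
    res
  }

  # --- simulate / ingest -----------------------------------------------
  truth <- NULL
  if (!is.null(config$input_projections)) {
    stack <- read_projection_stack(config$input_projections)
    chain <- md5_of(list(chain, unname(tools::md5sum(config$input_projections))))
  } else {
    pspec <- stage_params(config, "phantom", phantom_spec, seed_name = "seed")
    acq <- stage_params(config, "acquisition", acquisition_spec, seed_name = "seed")
    sim <- run_stage(
      "simulate", list(pspec, acq),
      c("projections.tif", "truth_labels.tif", "truth_islets.csv"),
      compute = function() {
        ph <- generate_phantom(pspec)
        st <- forward_project(ph$volume, acq)
        write_projection_stack(st, file.path(out_dir, "projections.tif"), bits = 32L)
        write_label_volume(label_volume(ph$label_volume, pspec$voxel_size_um),
                           file.path(out_dir, "truth_labels.tif"))
        write_csv_full(ph$islet_table, file.path(out_dir, "truth_islets.csv"))
        list(stack = st, islet_table = ph$islet_table)
      },
      load = function() list(
        stack = read_projection_stack(file.path(out_dir, "projections.tif")),
        islet_table = read.csv(file.path(out_dir, "truth_islets.csv"))))
    stack <- sim$stack
    truth <- sim$islet_table
  }

  # --- preprocess -------------------------------------------------------
  pp <- stage_params(config, "preprocess", preprocess_params)
  pre_files <- c("proj_rangecut.tif", if (pp$clahe_enabled) "proj_clahe.tif")
  pre <- run_stage(
    "preprocess", list(pp), pre_files,
    compute = function() {
      cut <- cut_range(stack, pp)
      write_projection_stack(cut, file.path(out_dir, "proj_rangecut.tif"), bits = 32L)
      cl <- NULL
      if (pp$clahe_enabled) {
        cl <- apply_clahe(cut, pp)
        write_projection_stack(cl, file.path(out_dir, "proj_clahe.tif"), bits = 32L)
      }
      list(cut = cut, clahe = cl)
    },
    load = function() list(
      cut = read_projection_stack(file.path(out_dir, "proj_rangecut.tif")),
      clahe = if (pp$clahe_enabled)
        read_projection_stack(file.path(out_dir, "proj_clahe.tif"))))

  # --- align ------------------------------------------------------------
  # the estimation runs on the CLAHE stack when available (better contrast);
  # the correction is applied to the stack chosen for reconstruction
  reco_input <- if (config$reconstruct_from == "clahe" && !is.null(pre$clahe))
    pre$clahe else pre$cut
  est_input <- pre$clahe %||% pre$cut
  aligned <- run_stage(
    "align", list(config$reconstruct_from),
    c("aligned.tif", "alignment.yaml"),
    compute = function() {
      al <- estimate_cor(est_input)
      corrected <- apply_cor_correction(reco_input, al)
      write_projection_stack(corrected, file.path(out_dir, "aligned.tif"), bits = 32L)
      yaml::write_yaml(list(cor_offset_px = al$cor_offset_px, method = al$method,
                            per_pair = lapply(seq_len(nrow(al$per_pair_estimates)),
                                              function(i) as.list(al$per_pair_estimates[i, ]))),
                       file.path(out_dir, "alignment.yaml"), precision = 15L)
      list(stack = corrected, result = al)
    },
    load = function() list(
      stack = read_projection_stack(file.path(out_dir, "aligned.tif")),
      result = yaml::read_yaml(file.path(out_dir, "alignment.yaml"))))

  # --- reconstruct ------------------------------------------------------
  rp <- stage_params(config, "reconstruct", reconstruction_params)
  volume <- run_stage(
    "reconstruct", list(rp), "volume.tif",
    compute = function() {
      vol <- reconstruct_volume(aligned$stack, rp)
      write_volume(vol, file.path(out_dir, "volume.tif"))
      vol
    },
    load = function() read_volume(file.path(out_dir, "volume.tif")))

  # --- segment ----------------------------------------------------------
  sp <- stage_params(config, "segment", segmentation_params)
  seg_files <- c("islet_labels.tif",
                 if (config$quantify$delineate_tumor) "tumor_mask.tif")
  seg <- run_stage(
    "segment", list(sp, config$quantify$delineate_tumor),
    seg_files,
    compute = function() {
      m <- tissue_mask(volume)
      bs <- subtract_baseline(volume, sp, m)
      lv <- label_islets(bs, sp, m)
      lv <- remove_artifacts(lv, sp)
      write_label_volume(lv, file.path(out_dir, "islet_labels.tif"))
      tum <- NULL
      if (config$quantify$delineate_tumor) {
        tum <- delineate_low_af_region(volume, sp, m)
        write_label_volume(label_volume(array(as.integer(tum), dim(tum)),
                                        volume$voxel_size_um),
                           file.path(out_dir, "tumor_mask.tif"))
      }
      list(labels = lv, tumor = tum)
    },
    load = function() list(
      labels = read_label_volume(file.path(out_dir, "islet_labels.tif")),
      tumor = if (config$quantify$delineate_tumor)
        read_label_volume(file.path(out_dir, "tumor_mask.tif"))$labels > 0L))

  # --- quantify ---------------------------------------------------------
  qc <- config$quantify
  quant <- run_stage(
    "quantify", list(qc),
    c("islets.csv", "distribution.csv",
      if (!is.null(qc$reference_csv)) "comparison.csv"),
    compute = function() {
      rec <- measure_islets(seg$labels, volume)
      dist <- if (nrow(rec)) size_distribution(rec, qc$edges_um)
      cmp <- NULL
      if (!is.null(qc$reference_csv) && !is.null(dist)) {
        ref <- read_reference_distribution(qc$reference_csv)
        cmp <- compare_to_reference(dist, ref)
      }
      export_statistics(rec, dist, cmp, out_dir)
      list(records = rec, distribution = dist, comparison = cmp)
    },
    load = function() {
      rec <- read.csv(file.path(out_dir, "islets.csv"))
      dist <- if (nrow(rec)) size_distribution(rec, qc$edges_um)
      list(records = rec, distribution = dist, comparison = NULL)
    })

  list(dir = out_dir, stages_run = stages_run,
       alignment = aligned$result, islets = quant$records,
       distribution = quant$distribution, comparison = quant$comparison,
       truth = truth, labels = seg$labels, volume = volume,
       tumor_mask = seg$tumor)
}
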