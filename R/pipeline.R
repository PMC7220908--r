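# End-to-end orchestration: simulate -> filter -> beta-diversity ->
# scale scan -> classes -> path models, with a written manifest.

#' Configure an end-to-end pipeline run
#'
#' A single global `seed` is expanded into per-stage seeds by a fixed
#' deterministic scheme (`seed + 100 * stage index`), so toggling stages does
#' not perturb the randomness of the stages that still run.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed (mandatory: every stochastic stage derives from
#'   it).
#' @param stages Character vector of stages to run, in dependency order, a
#'   subset of `simulate`, `filter`, `betadiv`, `scale_scan`, `classes`,
#'   `pathmodel`.
#' @param succession A [succession_spec()] for the simulate stage (its seed
#'   field is overridden by the pipeline scheme).
#' @param pathmodel A [path_model_spec()] for the simulate stage (idem).
#' @param betadiv_opts A [beta_div_options()].
#' @param thresholds Spatial threshold ladder for the scan.
#' @param k_range Candidate class counts for [find_classes()].
#' @param n_perm Permutations for all tests.
#' @param min_reads_per_sample,min_reads_per_taxon Filtering thresholds.
#' @param counts_path,metadata_path,functions_path Input files used when the
#'   simulate stage is disabled.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            stages = c("simulate", "filter", "betadiv",
                                       "scale_scan", "classes", "pathmodel"),
                            succession = succession_spec(),
                            pathmodel = path_model_spec(),
                            betadiv_opts = beta_div_options(),
                            thresholds = threshold_ladder(),
                            k_range = 2:20,
                            n_perm = 999,
                            min_reads_per_sample = 10000,
                            min_reads_per_taxon = 100,
                            counts_path = NULL, metadata_path = NULL,
                            functions_path = NULL) {
  all_stages <- c("simulate", "filter", "betadiv", "scale_scan", "classes", "pathmodel")
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    stages = all_stages[all_stages %in% stages],
    succession = succession, pathmodel = pathmodel,
    betadiv_opts = betadiv_opts, thresholds = thresholds,
    k_range = k_range, n_perm = n_perm,
    min_reads_per_sample = min_reads_per_sample,
    min_reads_per_taxon = min_reads_per_taxon,
    counts_path = counts_path, metadata_path = metadata_path,
    functions_path = functions_path
  ), class = "pipeline_config")
}

stage_seed <- function(cfg, stage) {
  all_stages <- c("simulate", "filter", "betadiv", "scale_scan", "classes", "pathmodel")
  cfg$seed + 100L * match(stage, all_stages)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every artifact as
#' TSV/JSON under `out_dir` together with a manifest (stage, parameters,
#' seed and an md5 checksum per artifact). Identical config and seed yield
#' byte-identical outputs. Any stage failure aborts with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`counts`,
#'   `metadata`, `functions`, `dist_beta`, `dist_space`, `profile`,
#'   `class_model`, `anosim_report`, `pathmodel`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list()
  artifacts <- character(0)

  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    elapsed <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    message(sprintf("[%s] done in %.2fs", stage, elapsed))
    # timing goes to the log only, so reruns stay byte-identical
    manifest[[stage]] <<- list(
      stage = stage,
      seed = stage_seed(cfg, stage),
      artifacts = out
    )
    invisible(NULL)
  }

  emit <- function(path) {
    artifacts <<- c(artifacts, path)
    basename(path)
  }

  run_stage("simulate", function() {
    spec <- cfg$succession
    spec$seed <- stage_seed(cfg, "simulate")
    sim <- simulate_succession_communities(spec)
    res$counts <<- sim$counts
    res$metadata <<- sim$metadata
    res$truth <<- sim$classes
    pspec <- cfg$pathmodel
    pspec$seed <- stage_seed(cfg, "simulate") + 1L
    res$functions <<- simulate_functions(pspec, sim$classes)
    c(
      emit(write_count_table(sim$counts, file.path(cfg$out_dir, "counts.tsv"))),
      emit(write_sample_metadata(sim$metadata, file.path(cfg$out_dir, "metadata.tsv"))),
      emit({
        p <- file.path(cfg$out_dir, "truth_classes.tsv")
        readr::write_tsv(sim$classes, p, progress = FALSE); p
      }),
      emit(write_function_table(res$functions, file.path(cfg$out_dir, "functions.tsv")))
    )
  })

  if (is.null(res$counts)) {
    if (!is.null(cfg$counts_path)) {
      if (!file.exists(cfg$counts_path)) abort("counts_path does not exist")
      res$counts <- read_count_table(cfg$counts_path)
    }
    if (!is.null(cfg$metadata_path)) res$metadata <- read_sample_metadata(cfg$metadata_path)
    if (!is.null(cfg$functions_path)) res$functions <- read_function_table(cfg$functions_path)
  }

  run_stage("filter", function() {
    if (is.null(res$counts)) abort("no count table: enable simulate or set counts_path")
    fl <- filter_samples_taxa(res$counts, cfg$min_reads_per_sample,
                              cfg$min_reads_per_taxon, metadata = res$metadata)
    res$counts <<- fl$counts
    res$metadata <<- fl$metadata
    emit(write_count_table(fl$counts, file.path(cfg$out_dir, "counts_filtered.tsv")))
  })

  run_stage("betadiv", function() {
    if (is.null(res$counts)) abort("no count table: enable simulate or set counts_path")
    res$dist_beta <<- jsd_matrix(res$counts, cfg$betadiv_opts)
    out <- emit(write_distance_matrix(res$dist_beta, file.path(cfg$out_dir, "dist_jsd.tsv")))
    if (!is.null(res$metadata)) {
      res$dist_space <<- spatial_distance_matrix(res$metadata)
      out <- c(out, emit(write_distance_matrix(res$dist_space,
                                               file.path(cfg$out_dir, "dist_space.tsv"))))
    }
    out
  })

  run_stage("scale_scan", function() {
    if (is.null(res$dist_beta) || is.null(res$dist_space)) {
      abort("scale_scan needs the betadiv stage (or precomputed matrices)")
    }
    res$profile <<- scale_scan(res$dist_space, res$dist_beta, cfg$thresholds,
                               n_perm = cfg$n_perm, seed = stage_seed(cfg, "scale_scan"))
    emit({
      p <- file.path(cfg$out_dir, "profile.tsv")
      readr::write_tsv(tibble::as_tibble(res$profile), p, progress = FALSE); p
    })
  })

  run_stage("classes", function() {
    if (is.null(res$dist_beta)) abort("classes stage needs the betadiv stage")
    cm <- find_classes(res$dist_beta, cfg$k_range)
    res$class_model <<- cm
    res$anosim_report <<- grouping_anosim_report(
      res$dist_beta, res$metadata, classes = cm$labels,
      n_perm = cfg$n_perm, seed = stage_seed(cfg, "classes"))
    c(
      emit({
        p <- file.path(cfg$out_dir, "classes.tsv")
        readr::write_tsv(cm$labels, p, progress = FALSE); p
      }),
      emit({
        p <- file.path(cfg$out_dir, "ch_curve.tsv")
        readr::write_tsv(cm$ch_curve, p, progress = FALSE); p
      }),
      emit({
        p <- file.path(cfg$out_dir, "anosim_report.tsv")
        readr::write_tsv(res$anosim_report, p, progress = FALSE); p
      })
    )
  })

  run_stage("pathmodel", function() {
    if (is.null(res$functions)) abort("pathmodel stage needs a function table")
    cls <- if (!is.null(res$class_model)) res$class_model$labels else res$truth
    if (is.null(cls)) abort("pathmodel stage needs classes (run the classes stage)")
    keep <- res$functions$sample_id %in% cls$sample_id
    f <- res$functions[keep, , drop = FALSE]
    # classes too small for the largest equation cannot support a per-class
    # fit; drop them (logged) rather than failing the whole stage
    dag <- cfg$pathmodel$dag
    min_needed <- length(dag$nodes) + 1
    sizes <- table(cls$label[match(f$sample_id, cls$sample_id)])
    small <- names(sizes)[sizes < min_needed]
    if (length(small) > 0) {
      message(sprintf("[pathmodel] dropping undersized class(es): %s",
                      paste(small, collapse = ", ")))
      keep2 <- !(cls$label[match(f$sample_id, cls$sample_id)] %in% small)
      f <- f[keep2, , drop = FALSE]
      cls <- cls[cls$sample_id %in% f$sample_id, , drop = FALSE]
      if (length(unique(cls$label)) < 1) abort("no class large enough for path models")
    }
    sel <- select_constraint_model(f, cls, dag)
    inter <- if (length(unique(cls$label)) >= 2) {
      interaction_report(f, cls, dag)
    } else {
      tibble(exposure = character(0), outcome = character(0))
    }
    res$pathmodel <<- list(fit = sel, interactions = inter)
    emit({
      p <- file.path(cfg$out_dir, "pathmodel.json")
      jsonlite::write_json(list(
        scenario = sel$scenario,
        aic = sel$aic, loglik = sel$loglik, n_params = sel$n_params,
        chi_square = sel$chi_square, df = sel$df, rmsea = sel$rmsea,
        r2 = as.list(sel$r2),
        coefficients = sel$coefficients,
        search = sel$search,
        interactions = inter
      ), p, auto_unbox = TRUE, digits = 10)
      p
    })
  })

  manifest$config <- list(
    seed = cfg$seed, stages = cfg$stages, n_perm = cfg$n_perm,
    k_range = range(cfg$k_range), thresholds = cfg$thresholds,
    min_reads_per_sample = cfg$min_reads_per_sample,
    min_reads_per_taxon = cfg$min_reads_per_taxon
  )
  manifest$checksums <- as.list(tools::md5sum(sort(artifacts)))
  names(manifest$checksums) <- basename(sort(artifacts))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
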