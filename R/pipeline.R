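## Pipeline orchestration. Stages run in dependency order on persisted
## intermediate tables, so every stage is also runnable standalone from a
## previous run's outputs. A JSON manifest records inputs (with content
## digests), the config snapshot, the seed and the package version; rerun
## with the same config and seed and the result tables are byte-identical
## (the manifest's timestamp is the only thing that moves).

PIPELINE_STAGES <- c("simulate", "summarize", "varcomp", "plasticity",
                     "gwa", "annotate", "correlate", "kinetics")

#' Run the analysis pipeline
#'
#' @param config either a list or a YAML/JSON file path. Recognized
#'   entries: `stages` (subset of `simulate`, `summarize`, `varcomp`,
#'   `plasticity`, `gwa`, `annotate`, `correlate`, `kinetics`), `inputs`
#'   (named paths `events`, `genotypes`, `covariates`, `gene_models`,
#'   `cfu` for stages not fed by `simulate`), `sim` (arguments for
#'   [architecture_spec()]), `gwa` (`trait`, `p_threshold`,
#'   `min_minor_lines`), `scoring_grid_hours`.
#' @param out_dir output directory (created); receives the result tables
#'   and `manifest.json`.
#' @param seed integer seed overriding the config's (flags win).
#' @return invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$seed <- cfg$seed %||% 1L
  stages <- cfg$stages %||% PIPELINE_STAGES[1:4]
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0)
    stop_format("usage error: unknown stage(s) %s", paste(unknown, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]   # dependency order
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  state <- new.env(parent = emptyenv())

  need <- function(what, stage, reader) {
    if (!is.null(state[[what]])) return(state[[what]])
    path <- cfg$inputs[[what]]
    if (is.null(path))
      stop_format("dependency error: stage '%s' needs '%s' (run the producing stage or set inputs$%s)",
                  stage, what, what)
    state[[what]] <- reader(path)
    state[[what]]
  }

  for (stage in stages) {
    message(sprintf("[panelsurv] stage %s", stage))
    switch(stage,
      simulate = {
        sim_args <- cfg$sim %||% list()
        sim_args$seed <- cfg$seed
        spec <- do.call(architecture_spec, sim_args)
        pan <- simulate_panel(spec)
        sv <- simulate_survival(pan$panel, pan$covariates, spec)
        state$events <- sv$events
        state$genotypes <- pan$panel
        state$covariates <- pan$covariates
        state$truth <- sv$truth
        paths$events <- file.path(out_dir, "events.csv")
        write_events(sv$events, paths$events)
        paths$genotypes <- file.path(out_dir, "genotypes.tsv")
        write_genotype_panel(pan$panel, paths$genotypes)
        paths$covariates <- file.path(out_dir, "covariates.csv")
        write_covariates(pan$covariates, paths$covariates)
        paths$truth <- file.path(out_dir, "sim_truth.json")
        jsonlite::write_json(
          list(causal_mean = sv$truth$causal_mean,
               causal_var = sv$truth$causal_var,
               realized = as.list(sv$truth$realized)),
          paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      summarize = {
        events <- need("events", "summarize",
                       function(p) read_events(p, cfg$scoring_grid_hours))
        state$summaries <- line_summaries(events)
        state$rep_summaries <- replicate_summaries(events)
        paths$line_summaries <- file.path(out_dir, "line_summaries.tsv")
        write_line_summaries(state$summaries, paths$line_summaries)
      },
      varcomp = {
        events <- need("events", "varcomp",
                       function(p) read_events(p, cfg$scoring_grid_hours))
        vc <- anova_mixed(events, model = "pooled_sex")
        paths$varcomp <- file.path(out_dir, "varcomp.json")
        write_varcomp_report(vc, paths$varcomp)
      },
      plasticity = {
        events <- need("events", "plasticity",
                       function(p) read_events(p, cfg$scoring_grid_hours))
        if (is.null(state$rep_summaries))
          state$rep_summaries <- replicate_summaries(events)
        res <- lapply(split(state$rep_summaries, state$rep_summaries$sex),
                      variance_level_heritability)
        paths$plasticity <- file.path(out_dir, "plasticity.json")
        jsonlite::write_json(
          lapply(res, function(r) list(h2 = r$h2,
                                       components = as.list(r$vc$components))),
          paths$plasticity, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      gwa = {
        panel <- need("genotypes", "gwa",
                      function(p) read_genotype_panel(p, "tsv"))
        covariates <- need("covariates", "gwa", read_covariates)
        if (is.null(state$summaries)) {
          events <- need("events", "gwa",
                         function(p) read_events(p, cfg$scoring_grid_hours))
          state$summaries <- line_summaries(events)
        }
        gcfg <- cfg$gwa %||% list()
        variants <- phenotype_variants(state$summaries,
                                       trait = gcfg$trait %||% "lt50")
        recs <- lapply(names(variants), function(v) {
          adj <- adjust_phenotype(variants[[v]], covariates)
          marker_scan(adj$adjusted, panel,
                      min_minor_lines = gcfg$min_minor_lines %||% 4,
                      pheno_variant = v)
        })
        state$associations <- do.call(rbind, recs)
        paths$associations <- file.path(out_dir, "associations.tsv")
        write_association_records(state$associations, paths$associations)
        manifest_extra <- list(p_threshold = gcfg$p_threshold %||% 1e-5)
        state$gwa_manifest <- manifest_extra
      },
      annotate = {
        if (is.null(state$associations))
          stop_format("dependency error: stage 'annotate' needs the gwa stage's associations")
        gm <- need("gene_models", "annotate",
                   function(p) read_gene_models(p, "bed_like"))
        thr <- (cfg$gwa$p_threshold %||% 1e-5)
        sig <- state$associations[!is.na(state$associations$p) &
                                    state$associations$p < thr, , drop = FALSE]
        cls <- classify_sites(sig[, c("chrom", "pos", "ref", "alt")], gm)
        paths$classifications <- file.path(out_dir, "classifications.tsv")
        write_classifications(cls, paths$classifications)
        inv <- if (nrow(cls) > 0) class_inventory(cls) else NULL
        enr <- if (!is.null(inv))
          list(genic = enrichment_chisq(sum(inv$counts[setdiff(SITE_CLASSES, "intergenic")]),
                                        inv$n, GENOME_COMPOSITION[["genic"]]),
               functional = enrichment_chisq(
                 sum(inv$counts[c("intron", "utr5", "utr3", "non_synonymous")]),
                 inv$n, GENOME_COMPOSITION[["genic"]]))
        paths$enrichment <- file.path(out_dir, "enrichment.json")
        write_enrichment_report(list(inventory = inv, enrichment = enr),
                                paths$enrichment)
      },
      correlate = {
        if (is.null(state$summaries)) {
          events <- need("events", "correlate",
                         function(p) read_events(p, cfg$scoring_grid_hours))
          state$summaries <- line_summaries(events)
        }
        v <- phenotype_variants(state$summaries, trait = "lt50")
        lines <- union(names(v$male), names(v$female))
        tt <- data.frame(line_id = lines,
                         lt50_male = v$male[lines],
                         lt50_female = v$female[lines])
        res <- trait_matrix(tt, family_alpha = cfg$family_alpha %||% 0.05)
        paths$correlations <- file.path(out_dir, "correlations.tsv")
        write_correlation_results(res, paths$correlations)
      },
      kinetics = {
        cfu <- if (!is.null(cfg$inputs$cfu)) read_cfu_series(cfg$inputs$cfu)
          else if (!is.null(state$summaries)) {
            v <- phenotype_variants(state$summaries, trait = "lt50")
            simulate_cfu(v$male, seed = cfg$seed)
          } else stop_format("dependency error: stage 'kinetics' needs a cfu input or line summaries")
        cross <- threshold_crossing_time(cfu, cfg$cfu_threshold %||% 100)
        paths$crossings <- file.path(out_dir, "cfu_crossings.tsv")
        write_result_table(cross, paths$crossings, sep = "\t")
      })
  }

  manifest <- list(
    subcommand = "run_pipeline",
    stages = stages,
    inputs = lapply(cfg$inputs %||% list(), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(paths, function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    config = cfg, seed = cfg$seed,
    package_version = as.character(utils::packageVersion("panelsurv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(paths)
}

load_config <- function(config) {
  if (is.character(config)) {
    if (grepl("\\.ya?ml$", config)) return(yaml::read_yaml(config))
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  stopifnot(is.list(config))
  config
}

#' Validate a set of input files without running the pipeline
#'
#' Report-only schema checks plus line-id join coverage across events,
#' genotypes and covariates.
#'
#' @param events,genotypes,covariates,gene_models optional file paths.
#' @param scoring_grid_hours optional grid declared for the events file.
#' @return data frame `level` (`error`/`warning`/`info`), `file`,
#'   `message`; zero `error`/`warning` rows means a clean dataset.
#' @export
validate_inputs <- function(events = NULL, genotypes = NULL, covariates = NULL,
                            gene_models = NULL, scoring_grid_hours = NULL) {
  issues <- list()
  add <- function(level, file, msg)
    issues[[length(issues) + 1]] <<- data.frame(level = level, file = file,
                                                message = msg,
                                                stringsAsFactors = FALSE)
  ev <- gt <- cov <- NULL
  if (!is.null(events)) {
    ev <- tryCatch(read_events(events, scoring_grid_hours),
                   error = function(e) { add("error", events, conditionMessage(e)); NULL })
    if (!is.null(ev)) {
      cnt <- attr(ev, "counts")
      add("info", events, sprintf("%d records, %d lines, %d dead, %d censored",
                                  cnt["n_records"], cnt["n_lines"],
                                  cnt["n_dead"], cnt["n_censored"]))
    }
  }
  if (!is.null(genotypes)) {
    gt <- tryCatch(read_genotype_panel(genotypes, "tsv"),
                   error = function(e) { add("error", genotypes, conditionMessage(e)); NULL })
    if (!is.null(gt))
      add("info", genotypes, sprintf("%d markers x %d lines",
                                     nrow(gt$markers), length(gt$line_ids)))
  }
  if (!is.null(covariates)) {
    cov <- tryCatch(read_covariates(covariates),
                    error = function(e) { add("error", covariates, conditionMessage(e)); NULL })
  }
  if (!is.null(gene_models)) {
    tryCatch(read_gene_models(gene_models, "bed_like"),
             error = function(e) add("error", gene_models, conditionMessage(e)))
  }
  if (!is.null(ev) && !is.null(gt)) {
    missing <- setdiff(unique(ev$line_id), gt$line_ids)
    for (ln in missing)
      add("warning", genotypes, sprintf("phenotyped line %s absent from genotype panel", ln))
  }
  if (!is.null(ev) && !is.null(cov)) {
    missing <- setdiff(unique(ev$line_id), cov$line_id)
    for (ln in missing)
      add("warning", covariates, sprintf("phenotyped line %s absent from covariates", ln))
  }
  if (length(issues) == 0)
    return(data.frame(level = character(0), file = character(0),
                      message = character(0)))
  res <- do.call(rbind, issues)
  rownames(res) <- NULL
  res
}
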