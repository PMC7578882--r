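# Configuration-driven end-to-end runner: load or simulate cohorts, run
# diversity / differential-abundance / marker-discovery / POD-evaluation /
# correlation stages, and write every stage output plus a deterministic
# manifest into a run directory.

#' Build (or read) a pipeline configuration
#'
#' A configuration is a plain named list; this helper fills defaults,
#' validates it, and can read it from a YAML or JSON file.  Either
#' `synthetic` (a list of [synthetic_spec()] arguments) or `input` (a list
#' with `otu_table`, `metadata`, optional `taxonomy` and `samples_in`
#' paths) must be present.  For file input the metadata `cohort` column
#' assigns samples to the discovery / validation / independent cohorts.
#'
#' @param config Named list, or path to a YAML/JSON config file.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                                 simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  defaults <- list(
    synthetic = NULL,          # list of synthetic_spec() arguments
    input = NULL,              # list(otu_table=, metadata=, taxonomy=, samples_in=)
    site_log_sd = 0.3,         # site effect of the synthetic independent cohort
    rarefy_depth = NULL,       # NULL = minimum library size
    rarefy_for_diversity = TRUE,
    screen_alpha = 0.05,
    lda_threshold = 2,
    lda_boot = 30,
    cv_trials = 5,
    cv_folds = 5,
    n_trees = 500,
    cv_trees = NULL,           # NULL = n_trees
    case_level = NULL,
    taxonomy_rank = "genus",
    seed = 1,
    out_dir = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$synthetic) && is.null(cfg$input)) {
    abort("config needs either 'synthetic' (generator parameters) or 'input' (file paths)")
  }
  if (is.null(cfg$cv_trees)) cfg$cv_trees <- cfg$n_trees
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

# assemble the three cohorts either from the generator or from files
pipeline_cohorts <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    spec <- do.call(synthetic_spec, cfg$synthetic)
    list(
      discovery = generate_cohort(spec, "discovery",
                                  seed = derive_seed(cfg$seed, 11)),
      validation = generate_cohort(spec, "validation",
                                   seed = derive_seed(cfg$seed, 12)),
      independent = generate_cohort(spec, "independent",
                                    seed = derive_seed(cfg$seed, 13),
                                    site_log_sd = cfg$site_log_sd),
      taxonomy = NULL
    )
  } else {
    tab <- read_otu_table(cfg$input$otu_table,
                          samples_in = cfg$input$samples_in %||% "columns")
    meta <- read_sample_metadata(cfg$input$metadata)
    tax <- if (!is.null(cfg$input$taxonomy)) read_taxonomy(cfg$input$taxonomy)
           else NULL
    meta <- align_metadata(tab, meta)
    split_one <- function(name) {
      keep <- meta$cohort == name
      if (!any(keep)) return(NULL)
      list(table = tab[keep, ], metadata = sample_metadata(meta[keep, ]),
           truth = NULL)
    }
    out <- list(discovery = split_one("discovery"),
                validation = split_one("validation"),
                independent = split_one("independent"),
                taxonomy = tax)
    if (is.null(out$discovery)) abort("no samples labeled cohort 'discovery'")
    out
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full marker-discovery pipeline
#'
#' Executes, in order: cohort load/generation, rarefaction, alpha and beta
#' diversity with ordination and group-overlap accounting, Wilcoxon
#' differential-abundance screening, Kruskal-Wallis + LDA effect-size
#' scoring (and per-rank aggregation when a taxonomy is supplied), marker
#' discovery on the discovery cohort, POD-model training and ROC evaluation
#' on discovery (resubstitution), validation and independent cohorts, and
#' Spearman correlation of marker abundances with clinical indicators.
#' Every stage writes TSV/JSON outputs to `out_dir`; a `manifest.json`
#' records the effective configuration, the derived stage seeds, input
#' hashes and the completion status of every stage.  All randomness derives
#' from `config$seed`, so two runs of the same config produce byte-identical
#' outputs.  If a stage fails, previously written outputs are retained, the
#' manifest records the failure point, and the error is re-raised.
#'
#' @param config A `pipeline_config`, a named list, or a config file path.
#' @param out_dir Output directory (created; overrides `config$out_dir`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) abort("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)

  manifest <- list(package = "podmarker",
                   version = as.character(utils::packageVersion("podmarker")),
                   config = unclass(cfg),
                   stage_seeds = list(
                     cohorts = c(discovery = derive_seed(cfg$seed, 11),
                                 validation = derive_seed(cfg$seed, 12),
                                 independent = derive_seed(cfg$seed, 13)),
                     rarefaction = derive_seed(cfg$seed, 21),
                     lda = derive_seed(cfg$seed, 31),
                     markers = cfg$seed,
                     pod = derive_seed(cfg$seed, 41)),
                   stages = list(), input_hashes = list())
  flush_manifest <- function() {
    jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      flush_manifest()
      stop(res)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }
  state <- new.env(parent = emptyenv())

  run_stage("load", {
    state$cohorts <- pipeline_cohorts(cfg)
    disc <- state$cohorts$discovery
    write_otu_table(disc$table, path("discovery_otu_table.tsv"))
    write_sample_metadata(disc$metadata, path("discovery_metadata.tsv"))
    for (nm in c("validation", "independent")) {
      co <- state$cohorts[[nm]]
      if (!is.null(co)) {
        write_otu_table(co$table, path(sprintf("%s_otu_table.tsv", nm)))
        write_sample_metadata(co$metadata, path(sprintf("%s_metadata.tsv", nm)))
      }
    }
    if (!is.null(disc$truth) && length(disc$truth$diff_otu_ids) > 0) {
      jsonlite::write_json(disc$truth, path("ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    hashes <- as.list(tools::md5sum(
      list.files(out_dir, pattern = "_(otu_table|metadata)\\.tsv$",
                 full.names = TRUE)))
    names(hashes) <- basename(names(hashes))
    manifest$input_hashes <- hashes
    # cross-cohort leakage guard, before anything is trained
    ids <- lapply(Filter(Negate(is.null),
                         state$cohorts[c("discovery", "validation",
                                         "independent")]),
                  function(co) co$table$sample_ids)
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j && length(intersect(ids[[i]], ids[[j]])) > 0L) {
        abort("cohorts '%s' and '%s' share sample ids (leakage)",
              names(ids)[i], names(ids)[j])
      }
    }
  })
  disc <- state$cohorts$discovery
  groups <- disc$metadata$group

  run_stage("diversity", {
    tab <- disc$table
    if (cfg$rarefy_for_diversity) {
      tab <- rarefy(tab, depth = cfg$rarefy_depth,
                    seed = derive_seed(cfg$seed, 21))
    }
    g <- align_metadata(tab, disc$metadata)$group
    alpha <- alpha_diversity(tab)
    alpha$group <- g
    write_tsv_file(alpha, path("alpha_diversity.tsv"))
    apv <- vapply(c("observed_otus", "shannon", "chao1", "ace"),
                  function(ix) wilcoxon_p(alpha[[ix]][g == g[1]],
                                          alpha[[ix]][g != g[1]]),
                  numeric(1))
    write_tsv_file(data.frame(index = names(apv), p_value = apv,
                              row.names = NULL), path("alpha_group_tests.tsv"))
    d <- bray_curtis(tab)
    dm <- as.matrix(d)
    write_tsv_file(data.frame(sample_id = rownames(dm), dm,
                              check.names = FALSE),
                   path("bray_curtis.tsv"))
    ord <- pcoa(d, n_axes = 2)
    co <- data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates, group = g, check.names = FALSE)
    write_tsv_file(co, path("pcoa_coordinates.tsv"))
    ov <- group_overlap(disc$table, groups)
    jsonlite::write_json(ov, path("group_overlap.json"), auto_unbox = TRUE,
                         digits = NA)
  })

  run_stage("differential", {
    rel <- relative_abundance(disc$table)
    screen <- wilcoxon_screen(rel, groups, alpha = cfg$screen_alpha,
                              case_level = cfg$case_level)
    write_tsv_file(as.data.frame(screen), path("wilcoxon_screen.tsv"))
    lefse <- lda_effect_size(rel, groups, kw_alpha = cfg$screen_alpha,
                             lda_threshold = cfg$lda_threshold,
                             n_boot = cfg$lda_boot,
                             seed = derive_seed(cfg$seed, 31),
                             case_level = cfg$case_level)
    write_tsv_file(as.data.frame(lefse), path("lda_effect_size.tsv"))
    if (!is.null(state$cohorts$taxonomy)) {
      agg <- aggregate_taxa(disc$table, state$cohorts$taxonomy,
                            cfg$taxonomy_rank)
      taxa_screen <- wilcoxon_screen(relative_abundance(agg), groups,
                                     alpha = cfg$screen_alpha,
                                     case_level = cfg$case_level)
      write_tsv_file(as.data.frame(taxa_screen),
                     path(sprintf("wilcoxon_screen_%s.tsv",
                                  cfg$taxonomy_rank)))
    }
  })

  markers <- run_stage("discover", {
    ms <- discover_markers(disc$table, disc$metadata,
                           screen_alpha = cfg$screen_alpha,
                           n_trees = cfg$n_trees, cv_trials = cfg$cv_trials,
                           cv_folds = cfg$cv_folds, cv_trees = cfg$cv_trees,
                           seed = cfg$seed, case_level = cfg$case_level)
    curve_df <- data.frame(feature_count = ms$curve$feature_counts,
                           t(ms$curve$errors),
                           mean_error = ms$curve$mean_error,
                           sd_error = ms$curve$sd_error, check.names = FALSE,
                           row.names = NULL)
    write_tsv_file(curve_df, path("cv_error_curve.tsv"))
    jsonlite::write_json(list(markers = ms$ranked_features,
                              chosen_size = ms$chosen_size,
                              min_error = ms$min_error,
                              sd_at_min = ms$sd_at_min, cutoff = ms$cutoff,
                              candidate_sizes = ms$candidate_sizes,
                              full_ranking = ms$full_ranking),
                         path("marker_set.json"), auto_unbox = TRUE,
                         digits = NA)
    ms
  })

  run_stage("evaluate", {
    model <- train_pod_model(disc$table, groups, markers,
                             n_trees = cfg$n_trees,
                             seed = derive_seed(cfg$seed, 41),
                             case_level = cfg$case_level)
    save_pod_model(model, path("pod_model.rds"))
    disc_scores <- pod_index(model, disc$table)
    evals <- list(discovery = list(
      pod = disc_scores,
      roc = roc_auc(disc_scores, groups, case_level = model$case_level)))
    held_out <- Filter(Negate(is.null),
                       state$cohorts[c("validation", "independent")])
    if (length(held_out) > 0L) {
      evals <- c(evals, evaluate_cohorts(
        model, lapply(held_out, function(co) {
          list(table = co$table, metadata = co$metadata)
        })))
    }
    roc_tab <- do.call(rbind, lapply(names(evals), function(nm) {
      r <- evals[[nm]]$roc
      data.frame(cohort = nm, auc = r$auc, ci_low = r$ci_low,
                 ci_high = r$ci_high, n_case = r$n_case,
                 n_control = r$n_control, stringsAsFactors = FALSE)
    }))
    write_tsv_file(roc_tab, path("roc_summary.tsv"))
    for (nm in names(evals)) {
      sc <- evals[[nm]]$pod
      co <- state$cohorts[[nm]]
      sc$group <- align_metadata(co$table, co$metadata)$group
      sc$cohort <- nm
      write_tsv_file(sc, path(sprintf("pod_scores_%s.tsv", nm)))
    }
    state$evals <- evals
  })

  run_stage("correlate", {
    clin_cols <- setdiff(names(disc$metadata),
                         c("sample_id", "group", "cohort"))
    if (length(clin_cols) > 0L && length(markers$ranked_features) > 0L) {
      rel <- relative_abundance(disc$table)
      cm <- spearman_matrix(rel[, markers$ranked_features, drop = FALSE],
                            disc$metadata)
      write_tsv_file(as.data.frame(cm), path("marker_clinical_spearman.tsv"))
    }
  })

  flush_manifest()
  invisible(manifest)
}
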