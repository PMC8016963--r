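default_run_options <- function() {
  list(alpha_same_target = 0.05, alpha_concordance = 0.05, alpha_success = 0.05,
       k = 50, diffsen_mode = "zscore", tanimoto_threshold = 0.35,
       top_n_cells = 10, split_fraction = 0.7, min_drugs_per_target = 3,
       families = c("lasso", "ridge", "random_forest"),
       integrate_all_models = FALSE, seed = 1L, out_dir = NULL)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list.  All problems are reported at once.
#' A configuration either declares `simulate:` (fields of [sim_config()])
#' or `datasets:` (a list of `name`/`sensitivity`/`silencing`/`features`/
#' `orientation` entries with file paths) plus `drugs:` and `catalog:`
#' paths; analysis options default to [the values documented in
#' `run_pipeline()`].
#'
#' @param x Path to a YAML config or a named list.
#' @return List with `config` (defaults filled in) and `errors`
#'   (character vector; empty when valid).
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  errors <- character(0)
  err <- function(msg) errors <<- c(errors, msg)
  opts <- default_run_options()
  for (nm in names(opts)) if (is.null(cfg[[nm]])) cfg[[nm]] <- opts[[nm]]
  for (a in c("alpha_same_target", "alpha_concordance", "alpha_success")) {
    v <- cfg[[a]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1) err(paste0("`", a, "` must lie in (0, 1)"))
  }
  if (!is.numeric(cfg$k) || cfg$k < 2) err("`k` must be an integer >= 2")
  if (!cfg$diffsen_mode %in% c("zscore", "raw", "rank")) err("`diffsen_mode` must be zscore, raw or rank")
  if (!is.numeric(cfg$tanimoto_threshold) || cfg$tanimoto_threshold <= 0 || cfg$tanimoto_threshold > 1) {
    err("`tanimoto_threshold` must lie in (0, 1]")
  }
  has_sim <- !is.null(cfg$simulate)
  has_data <- !is.null(cfg$datasets)
  if (!has_sim && !has_data) err("config needs either `simulate` or `datasets`")
  if (has_sim) {
    ok <- tryCatch({do.call(sim_config, cfg$simulate); TRUE},
                   error = function(e) {err(conditionMessage(e)); FALSE})
  }
  if (has_data) {
    for (i in seq_along(cfg$datasets)) {
      ds <- cfg$datasets[[i]]
      if (is.null(ds$name)) err(paste0("datasets[", i, "]: missing `name`"))
      for (f in c("sensitivity", "silencing", "features")) {
        if (is.null(ds[[f]])) err(paste0("datasets[", i, "]: missing `", f, "`"))
        else if (!file.exists(ds[[f]])) err(paste0("datasets[", i, "]$", f, ": file not found: ", ds[[f]]))
      }
      if (!is.null(ds$orientation) &&
          !ds$orientation %in% c("viability_high_resistant", "sensitivity_high_sensitive")) {
        err(paste0("datasets[", i, "]: unknown orientation '", ds$orientation, "'"))
      }
    }
    for (f in c("drugs", "catalog")) {
      if (is.null(cfg[[f]])) err(paste0("config missing `", f, "` path"))
      else if (!file.exists(cfg[[f]])) err(paste0("`", f, "`: file not found: ", cfg[[f]]))
    }
  }
  list(config = cfg, errors = errors)
}

load_cohort_from_config <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    cohort <- simulate_cohort(do.call(sim_config, cfg$simulate))
    cohort$fingerprints <- simulate_fingerprints(
      cohort$drugs, cohort$truth$structure_groups,
      seed = derive_seed(cfg$seed, "fingerprints"))
    return(cohort)
  }
  datasets <- list()
  for (ds in cfg$datasets) {
    datasets[[ds$name]] <- list(
      sensitivity = orient_sensitivity(read_matrix(ds$sensitivity),
                                       ds$orientation %||% "viability_high_resistant"),
      silencing = orient_sensitivity(read_matrix(ds$silencing),
                                     ds$orientation %||% "viability_high_resistant"),
      features = read_matrix(ds$features),
      lineages = if (!is.null(ds$lineages)) {
        utils::read.delim(ds$lineages, colClasses = "character")
      }
    )
  }
  drugs <- read_drug_annotations(cfg$drugs)
  catalog <- read_transporter_catalog(cfg$catalog)
  fingerprints <- NULL
  if (!is.null(cfg$fingerprints)) {
    fp <- jsonlite::read_json(cfg$fingerprints, simplifyVector = TRUE)
    fingerprints <- lapply(fp, function(b) sort(unlist(b)))
  } else if (any(!is.na(drugs$smiles) & nzchar(drugs$smiles))) {
    ok <- !is.na(drugs$smiles) & nzchar(drugs$smiles)
    fingerprints <- lapply(setNames(drugs$smiles[ok], drugs$drug_id[ok]),
                           fingerprint_from_smiles)
  }
  structure(list(datasets = datasets, drugs = drugs, truth = NULL,
                 fingerprints = fingerprints, catalog = catalog, config = cfg),
            class = "cohort")
}

cohort_catalog <- function(cohort) {
  if (!is.null(cohort$catalog)) return(cohort$catalog)
  if (!is.null(cohort$truth)) {
    return(new_transporter_catalog(
      all_transporters = sort_c(grep("^TR", rownames(cohort$datasets[[1]]$features), value = TRUE)),
      annotated = Filter(length, cohort$truth$planted_transporters)))
  }
  new_transporter_catalog(character(0), list())
}

#' Run the full resistance-prediction pipeline
#'
#' Orchestrates: cohort acquisition (simulation or harmonized files) →
#' harmonization → the drug filtering cascade (target count, same-target
#' concordance, drug-vs-silencing concordance, applied per dataset) →
#' DiffSen → within-dataset models → cross-dataset transfers → rank
#' aggregation over successful models (per drug and per structure group) →
#' transporter enrichment and importance scores.  Deterministic given the
#' config and seed; every excluded drug carries a reason in the report.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @param seed Optional master seed overriding `config$seed`.
#' @return An object of class `resistance_report`; see [write_report()].
#' @export
run_pipeline <- function(config, seed = NULL) {
  val <- validate_config(config)
  if (length(val$errors)) {
    abort(paste0("invalid config:\n", paste("-", val$errors, collapse = "\n")))
  }
  cfg <- val$config
  if (!is.null(seed)) cfg$seed <- seed
  cohort <- load_cohort_from_config(cfg)
  catalog <- cohort_catalog(cohort)
  harm <- harmonize(cohort$datasets)
  flow <- list()
  note <- function(dataset, drug_id, stage, status, reason = NA_character_) {
    flow[[length(flow) + 1]] <<- tibble::tibble(dataset = dataset, drug_id = drug_id,
                                                stage = stage, status = status,
                                                reason = reason)
  }

  drugs1 <- filter_by_target_count(cohort$drugs)
  rm1 <- attr(drugs1, "removed")
  for (i in seq_len(nrow(rm1))) note("*", rm1$drug_id[i], "target_count", "removed", rm1$reason[i])

  survivors <- list(); concordance <- list()
  for (nm in names(harm$datasets)) {
    ds <- harm$datasets[[nm]]
    in_ds <- drugs1[drugs1$drug_id %in% rownames(ds$sensitivity), , drop = FALSE]
    rep1 <- same_target_concordance(ds$sensitivity, in_ds,
                                    alpha = cfg$alpha_same_target,
                                    min_drugs_per_target = cfg$min_drugs_per_target)
    for (i in seq_len(nrow(rep1$drugs))) {
      if (!rep1$drugs$surviving[i]) note(nm, rep1$drugs$drug_id[i], "same_target_concordance",
                                         "removed", rep1$drugs$reason[i])
    }
    surv1 <- in_ds[in_ds$drug_id %in% rep1$drugs$drug_id[rep1$drugs$surviving], , drop = FALSE]
    rep2 <- drug_target_concordance(ds$sensitivity, ds$silencing, surv1,
                                    alpha = cfg$alpha_concordance)
    for (i in seq_len(nrow(rep2$drugs))) {
      if (!rep2$drugs$surviving[i]) note(nm, rep2$drugs$drug_id[i], "drug_target_concordance",
                                         "removed", rep2$drugs$reason[i])
    }
    surv2 <- surv1[surv1$drug_id %in% rep2$drugs$drug_id[rep2$drugs$surviving], , drop = FALSE]
    for (d in surv2$drug_id) note(nm, d, "filters", "surviving")
    survivors[[nm]] <- surv2
    concordance[[nm]] <- list(same_target = rep1, drug_target = rep2)
  }

  # within-dataset models
  models <- list(); selections <- list(); model_objs <- list()
  for (nm in names(harm$datasets)) {
    ds <- harm$datasets[[nm]]
    for (i in seq_len(nrow(survivors[[nm]]))) {
      drug <- survivors[[nm]][i, ]
      res <- tryCatch(
        fit_drug_model(drug, ds, k = cfg$k, seed = derive_seed(cfg$seed, "within", nm),
                       alpha = cfg$alpha_success, split_fraction = cfg$split_fraction,
                       mode = cfg$diffsen_mode, families = cfg$families),
        error = function(e) structure(list(drug_id = drug$drug_id,
                                           reason = conditionMessage(e)),
                                      class = "model_refusal"))
      if (inherits(res, "model_refusal")) {
        note(nm, drug$drug_id, "within_model", "refused", res$reason)
        next
      }
      key <- paste0(drug$drug_id, "|", nm, "|", nm)
      model_objs[[key]] <- res
      models[[key]] <- tibble::tibble(
        drug_id = drug$drug_id, train_dataset = nm, test_dataset = nm,
        model_family = res$model_family, cv_score = res$cv_score,
        test_r = res$test_r, test_p = res$test_p,
        n_train = res$n_train, n_test = res$n_test, successful = res$successful)
    }
  }
  # cross-dataset transfers
  nms <- names(harm$datasets)
  if (length(nms) >= 2) {
    for (a in nms) for (b in setdiff(nms, a)) {
      both <- intersect(survivors[[a]]$drug_id, survivors[[b]]$drug_id)
      for (d in both) {
        drug <- survivors[[a]][survivors[[a]]$drug_id == d, ]
        res <- cross_dataset_run(drug, harm$datasets[[a]], harm$datasets[[b]],
                                 train_name = a, test_name = b,
                                 k = cfg$k, seed = cfg$seed, alpha = cfg$alpha_success,
                                 mode = cfg$diffsen_mode, families = cfg$families)
        if (inherits(res, "model_refusal")) {
          note(paste0(a, "->", b), d, "transfer", "refused", res$reason)
          next
        }
        key <- paste0(d, "|", a, "|", b)
        model_objs[[key]] <- res
        models[[key]] <- tibble::tibble(
          drug_id = d, train_dataset = a, test_dataset = b,
          model_family = res$model_family, cv_score = res$cv_score,
          test_r = res$test_r, test_p = res$test_p,
          n_train = res$n_train, n_test = res$n_test, successful = res$successful)
      }
    }
  }
  models <- if (length(models)) dplyr::bind_rows(models) else
    tibble::tibble(drug_id = character(), train_dataset = character(),
                   test_dataset = character(), model_family = character(),
                   cv_score = double(), test_r = double(), test_p = double(),
                   n_train = integer(), n_test = integer(), successful = logical())
  models <- dplyr::arrange(models, .data$drug_id, .data$train_dataset, .data$test_dataset)

  success_summary <- models |>
    dplyr::group_by(.data$train_dataset, .data$test_dataset) |>
    dplyr::summarise(n_models = dplyr::n(), n_successful = sum(.data$successful),
                     success_fraction = mean(.data$successful), .groups = "drop")

  # rank aggregation over successful models (optionally all models, for
  # null-calibration studies)
  use_keys <- if (length(model_objs)) {
    names(model_objs)[vapply(model_objs, function(m) {
      isTRUE(cfg$integrate_all_models) || isTRUE(m$successful)
    }, logical(1))]
  } else character(0)
  key_drug <- vapply(strsplit(use_keys, "|", fixed = TRUE), `[[`, character(1), 1)
  by_drug <- split(use_keys, key_drug)
  ranked_lists <- lapply(by_drug, function(keys) {
    aggregate_ranks(lapply(model_objs[keys], function(m) rank_features_per_model(m$selection)),
                    scope = strsplit(keys[1], "|", fixed = TRUE)[[1]][1])
  })
  enrichment <- if (length(ranked_lists)) {
    purrr::map_dfr(names(ranked_lists), function(d) {
      transporter_enrichment(ranked_lists[[d]], catalog$annotated[[d]] %||% character(0))
    })
  } else {
    tibble::tibble(scope = character(), n_universe = integer(), n_annotated = integer(),
                   statistic = double(), p = double(), direction = character(),
                   testable = logical())
  }

  # structure groups and group-level aggregation
  groups <- NULL; group_enrichment <- tibble::tibble(); group_lists <- list()
  if (!is.null(cohort$fingerprints)) {
    groups <- structure_groups(cohort$fingerprints, threshold = cfg$tanimoto_threshold)
    gmap <- setNames(groups$group, groups$drug_id)
    by_group <- split(use_keys, unname(gmap[key_drug]))
    group_lists <- lapply(names(by_group), function(g) {
      aggregate_ranks(lapply(model_objs[by_group[[g]]],
                             function(m) rank_features_per_model(m$selection)), scope = g)
    })
    names(group_lists) <- names(by_group)
    group_enrichment <- purrr::map_dfr(names(group_lists), function(g) {
      members <- groups$drug_id[groups$group == g]
      purrr::map_dfr(intersect(members, names(by_drug)), function(d) {
        res <- transporter_enrichment(group_lists[[g]], catalog$annotated[[d]] %||% character(0))
        res$scope <- paste0(g, ":", d)
        res
      })
    })
  }

  # per-drug importance from the group-integrated list when available
  top_candidates <- if (length(ranked_lists) == 0) {
    tibble::tibble(drug_id = character(), feature_id = character(),
                   mean_rank = double(), importance = double(), annotated = logical())
  } else purrr::map_dfr(names(ranked_lists), function(d) {
    lst <- ranked_lists[[d]]
    if (!is.null(groups)) {
      g <- groups$group[groups$drug_id == d]
      if (length(g) == 1 && !is.null(group_lists[[g]])) lst <- group_lists[[g]]
    }
    imp <- importance_scores(lst)
    top <- head(imp, 10)
    tibble::tibble(drug_id = d, feature_id = top$feature_id,
                   mean_rank = top$mean_rank, importance = top$importance,
                   annotated = top$feature_id %in% (catalog$annotated[[d]] %||% character(0)))
  })

  lineage <- lapply(harm$datasets, function(ds) {
    if (is.null(ds$lineages)) return(NULL)
    tryCatch(lineage_anova(ds$features, ds$lineages), error = function(e) NULL)
  })

  drug_flow <- if (length(flow)) dplyr::bind_rows(flow) else
    tibble::tibble(dataset = character(), drug_id = character(), stage = character(),
                   status = character(), reason = character())
  hash_cfg <- cfg; hash_cfg$out_dir <- NULL
  report <- structure(list(
    models = models, success_summary = success_summary,
    enrichment = enrichment, group_enrichment = group_enrichment,
    top_candidates = top_candidates, drug_flow = drug_flow,
    ranked_lists = ranked_lists, group_lists = group_lists,
    structure_groups = groups, concordance = concordance, lineage = lineage,
    truth = cohort$truth, catalog = catalog,
    counts = list(n_drugs_input = nrow(cohort$drugs),
                  n_datasets = length(harm$datasets),
                  n_models = nrow(models),
                  n_successful = sum(models$successful)),
    seed = cfg$seed, config_hash = rlang::hash(hash_cfg)
  ), class = "resistance_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.resistance_report <- function(x, ...) {
  cat("<resistance_report>\n")
  cat("  drugs in: ", x$counts$n_drugs_input, ", datasets: ", x$counts$n_datasets, "\n", sep = "")
  cat("  models: ", x$counts$n_models, " (", x$counts$n_successful, " successful)\n", sep = "")
  if (nrow(x$enrichment)) {
    cat("  enrichment p < 0.05 for ", sum(x$enrichment$p < 0.05, na.rm = TRUE), "/",
        sum(x$enrichment$testable), " testable drugs\n", sep = "")
  }
  cat("  config hash: ", x$config_hash, "\n", sep = "")
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes the summary tables as TSV plus a JSON header with counts, seed
#' and the config hash.  Output is byte-deterministic for a given report.
#'
#' @param report A `resistance_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
    path <- file.path(dir, name)
    # header comment so any output file is traceable to its configuration
    writeLines(paste0("# diffsen config_hash=", report$config_hash,
                      " seed=", report$seed), path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, na = "", append = TRUE))
  }
  wt(report$models, "models.tsv")
  wt(report$success_summary, "success_summary.tsv")
  wt(report$enrichment, "enrichment.tsv")
  if (nrow(report$group_enrichment)) wt(report$group_enrichment, "group_enrichment.tsv")
  wt(report$top_candidates, "top_candidates.tsv")
  wt(report$drug_flow, "drug_flow.tsv")
  jsonlite::write_json(c(report$counts, list(seed = report$seed, config_hash = report$config_hash)),
                       file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
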