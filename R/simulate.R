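#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' Defaults describe the cohort used throughout the package's validation:
#' two partially overlapping panels of 200 cell lines, 300 transporter
#' expression features, drugs in target families of four, three planted
#' resistance transporters per drug with effect size 2 against unit noise.
#'
#' @param n_datasets Number of datasets (screening panels) to emulate.
#' @param n_cells_per_dataset Cell lines per dataset.
#' @param overlap_fraction Fraction of each dataset's cell lines drawn from
#'   a core shared by all datasets, in `[0, 1]`.
#' @param n_transporters Number of transporter expression features.
#' @param n_genetic_features Number of binary genetic features.
#' @param n_targets Number of distinct primary target genes.
#' @param drugs_per_target Drugs per target family (>= 3 so the
#'   fewer-than-three-drugs filter is satisfiable by construction).
#' @param planted_per_drug Number of transporters planted as resistance
#'   drivers for each drug.
#' @param effect_size_beta Contribution of each planted transporter's
#'   z-scored expression to drug viability (0 disables the effect).
#' @param dependency_weight_alpha Contribution of the target's latent
#'   dependency to drug viability.
#' @param noise_sd SD of the additive Gaussian noise on drug viability.
#' @param silencing_noise_sd SD of measurement noise on silencing viability.
#' @param dataset_scale List of `c(gain, offset)` per dataset, the affine
#'   transform emulating AUC-vs-viability scale differences between panels;
#'   default gain `1, 1.5, 2, ...` and offset `0, 2, 4, ...`.
#' @param lineages Named numeric vector: lineage labels with per-lineage
#'   expression-shift magnitudes (each gene's lineage response is the shift
#'   times a gene-specific standard-normal loading).
#' @param two_target_fraction Fraction of drugs given a second primary
#'   target (whose latent dependencies are averaged).
#' @param share_planted_within_family If `TRUE` (default), drugs with the
#'   same primary target share one planted transporter set — the generative
#'   counterpart of the working hypothesis that structurally similar,
#'   same-target drugs are exported by the same transporters.  It also
#'   makes the same-target concordance filter satisfiable when
#'   `effect_size_beta` dominates the dependency signal.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 2,
                       n_cells_per_dataset = 200,
                       overlap_fraction = 0.5,
                       n_transporters = 300,
                       n_genetic_features = 10,
                       n_targets = 5,
                       drugs_per_target = 4,
                       planted_per_drug = 3,
                       effect_size_beta = 2,
                       dependency_weight_alpha = 1,
                       noise_sd = 1,
                       silencing_noise_sd = 0.5,
                       dataset_scale = NULL,
                       lineages = c(LUNG = 0.6, BREAST = 0.4, SKIN = 0.5, COLON = 0.3),
                       two_target_fraction = 0,
                       share_planted_within_family = TRUE,
                       seed = 1L) {
  cfg <- list(n_datasets = n_datasets, n_cells_per_dataset = n_cells_per_dataset,
              overlap_fraction = overlap_fraction, n_transporters = n_transporters,
              n_genetic_features = n_genetic_features, n_targets = n_targets,
              drugs_per_target = drugs_per_target, planted_per_drug = planted_per_drug,
              effect_size_beta = effect_size_beta,
              share_planted_within_family = share_planted_within_family,
              dependency_weight_alpha = dependency_weight_alpha,
              noise_sd = noise_sd, silencing_noise_sd = silencing_noise_sd,
              dataset_scale = dataset_scale, lineages = lineages,
              two_target_fraction = two_target_fraction, seed = seed)
  bad <- function(field, why) abort(paste0("sim_config field `", field, "`: ", why))
  pos_int <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) bad(field, "must be a positive integer")
  }
  for (f in c("n_datasets", "n_cells_per_dataset", "n_transporters", "n_targets")) pos_int(f)
  if (!is.numeric(cfg$n_genetic_features) || cfg$n_genetic_features < 0) bad("n_genetic_features", "must be non-negative")
  if (!is.numeric(cfg$overlap_fraction) || cfg$overlap_fraction < 0 || cfg$overlap_fraction > 1) bad("overlap_fraction", "must lie in [0, 1]")
  if (!is.numeric(cfg$drugs_per_target) || cfg$drugs_per_target < 3) bad("drugs_per_target", "must be an integer >= 3")
  if (!is.numeric(cfg$planted_per_drug) || cfg$planted_per_drug < 0) bad("planted_per_drug", "must be >= 0")
  if (cfg$planted_per_drug > cfg$n_transporters) bad("planted_per_drug", "cannot exceed n_transporters")
  if (!is.numeric(cfg$effect_size_beta) || cfg$effect_size_beta < 0) bad("effect_size_beta", "must be non-negative")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) bad("noise_sd", "must be positive")
  if (!is.numeric(cfg$silencing_noise_sd) || cfg$silencing_noise_sd < 0) bad("silencing_noise_sd", "must be non-negative")
  if (!is.numeric(cfg$two_target_fraction) || cfg$two_target_fraction < 0 || cfg$two_target_fraction > 1) bad("two_target_fraction", "must lie in [0, 1]")
  if (is.null(cfg$dataset_scale)) {
    cfg$dataset_scale <- lapply(seq_len(n_datasets), function(i) c(gain = 1 + 0.5 * (i - 1), offset = 2 * (i - 1)))
  }
  if (length(cfg$dataset_scale) != n_datasets) bad("dataset_scale", "needs one (gain, offset) pair per dataset")
  if (any(vapply(cfg$dataset_scale, function(g) g[[1]] <= 0, logical(1)))) bad("dataset_scale", "gains must be positive")
  if (length(cfg$lineages) < 2 || is.null(names(cfg$lineages))) bad("lineages", "must be a named vector with >= 2 lineages")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) bad("seed", "must be a single integer")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-dataset cohort with planted transporter effects
#'
#' Generates 2–3 emulated screening panels over partially overlapping cell
#' lines.  Per cell line, transporter expression is lognormal-like with
#' lineage-specific shifts, and each target gene carries a latent dependency
#' shared by all datasets.  The silencing screen observes that dependency
#' plus measurement noise.  Drug viability follows the linear resistance
#' law: \deqn{s(d, c) = gain \cdot [\alpha\, dep(target(d), c) + \beta
#' \sum_{t \in planted(d)} w_t\, z(E(t, c)) + \varepsilon] + offset,} with
#' higher values meaning more viable, i.e. more resistant.  Two-target
#' drugs average the two latent dependencies.
#'
#' @param config A [sim_config()].
#' @return A list of class `cohort`: `datasets` (named list of
#'   sensitivity/silencing/features matrices plus lineage labels), `drugs`
#'   (drug annotation tibble), `truth` (planted transporters, weights,
#'   per-drug alpha/beta, structure groups), `fingerprints` (filled by
#'   [simulate_fingerprints()]), `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, {
    n_ds <- config$n_datasets
    n <- config$n_cells_per_dataset
    n_core <- round(config$overlap_fraction * n)
    n_unique <- n - n_core
    n_cells_total <- n_core + n_ds * n_unique
    cell_ids <- sprintf("CL%04d", seq_len(n_cells_total))
    core_cells <- cell_ids[seq_len(n_core)]
    rest_cells <- setdiff(cell_ids, core_cells)
    unique_cells <- split(rest_cells, rep(seq_len(n_ds), each = n_unique))
    ds_cells <- lapply(seq_len(n_ds), function(i) {
      sort_c(c(core_cells, if (n_unique > 0) unique_cells[[i]]))
    })

    lineage_labels <- sample(names(config$lineages), n_cells_total, replace = TRUE)
    names(lineage_labels) <- cell_ids

    # transporter expression: lognormal-like with lineage shifts
    tr_ids <- sprintf("TR%03d", seq_len(config$n_transporters))
    base <- rnorm(config$n_transporters, mean = 2, sd = 0.5)
    loading <- matrix(rnorm(config$n_transporters * length(config$lineages)),
                      nrow = config$n_transporters,
                      dimnames = list(tr_ids, names(config$lineages)))
    shift <- sweep(loading, 2, config$lineages, `*`)
    log_expr <- base + shift[, lineage_labels, drop = FALSE] +
      matrix(rnorm(config$n_transporters * n_cells_total, sd = 0.5),
             nrow = config$n_transporters)
    expr <- exp(log_expr)
    dimnames(expr) <- list(tr_ids, cell_ids)

    gen_ids <- character(0)
    genetic <- NULL
    if (config$n_genetic_features > 0) {
      gen_ids <- sprintf("MUT%03d", seq_len(config$n_genetic_features))
      genetic <- matrix(rbinom(config$n_genetic_features * n_cells_total, 1, 0.2),
                        nrow = config$n_genetic_features,
                        dimnames = list(gen_ids, cell_ids))
    }
    features_all <- rbind(expr, genetic)

    # latent dependencies of target genes, shared across datasets
    tg_ids <- sprintf("TG%02d", seq_len(config$n_targets))
    dep <- matrix(rnorm(config$n_targets * n_cells_total),
                  nrow = config$n_targets, dimnames = list(tg_ids, cell_ids))

    # drug table
    n_drugs <- config$n_targets * config$drugs_per_target
    drug_ids <- sprintf("D%03d", seq_len(n_drugs))
    primary <- rep(tg_ids, each = config$drugs_per_target)
    second <- rep(NA_character_, n_drugs)
    n_two <- round(config$two_target_fraction * n_drugs)
    if (n_two > 0 && config$n_targets >= 2) {
      two_idx <- sample(n_drugs, n_two)
      second[two_idx] <- vapply(primary[two_idx], function(p) sample(setdiff(tg_ids, p), 1), character(1))
    }
    targets <- lapply(seq_len(n_drugs), function(i) {
      if (is.na(second[i])) primary[i] else c(primary[i], second[i])
    })
    if (isTRUE(config$share_planted_within_family)) {
      family_planted <- lapply(setNames(tg_ids, tg_ids), function(t) {
        if (config$planted_per_drug == 0) character(0) else sort_c(sample(tr_ids, config$planted_per_drug))
      })
      planted <- family_planted[primary]
    } else {
      planted <- lapply(drug_ids, function(d) {
        if (config$planted_per_drug == 0) character(0) else sort_c(sample(tr_ids, config$planted_per_drug))
      })
    }
    names(planted) <- drug_ids
    weights <- lapply(planted, function(p) setNames(rep(1, length(p)), p))

    # per-dataset matrices
    datasets <- lapply(seq_len(n_ds), function(i) {
      cells <- ds_cells[[i]]
      gain <- config$dataset_scale[[i]][[1]]
      offset <- config$dataset_scale[[i]][[2]]
      sil <- dep[, cells, drop = FALSE] +
        matrix(rnorm(config$n_targets * length(cells), sd = config$silencing_noise_sd),
               nrow = config$n_targets)
      zexpr <- zscore_rows(expr[, cells, drop = FALSE])
      sens <- matrix(NA_real_, nrow = n_drugs, ncol = length(cells),
                     dimnames = list(drug_ids, cells))
      for (j in seq_len(n_drugs)) {
        tg <- targets[[j]]
        dpart <- if (length(tg) == 1) dep[tg, cells] else colMeans(dep[tg, cells, drop = FALSE])
        ppart <- if (length(planted[[j]]) > 0) {
          colSums(zexpr[planted[[j]], , drop = FALSE] * weights[[j]][rownames(zexpr[planted[[j]], , drop = FALSE])])
        } else 0
        lin <- config$dependency_weight_alpha * dpart +
          config$effect_size_beta * ppart +
          rnorm(length(cells), sd = config$noise_sd)
        sens[j, ] <- gain * lin + offset
      }
      list(sensitivity = sens,
           silencing = sil,
           features = features_all[, cells, drop = FALSE],
           lineages = tibble::tibble(cell_id = cells, lineage = unname(lineage_labels[cells])))
    })
    names(datasets) <- paste0("ds", seq_len(n_ds))

    drugs <- tibble::tibble(
      drug_id = drug_ids,
      name = paste0("drug_", tolower(drug_ids)),
      targets = targets,
      n_targets = lengths(targets),
      smiles = NA_character_,
      datasets = rep(list(names(datasets)), n_drugs)
    )
    truth <- list(
      planted_transporters = planted,
      weights = weights,
      true_alpha = setNames(rep(config$dependency_weight_alpha, n_drugs), drug_ids),
      true_beta = setNames(rep(config$effect_size_beta, n_drugs), drug_ids),
      structure_groups = split(drug_ids, primary),
      shared_core_cells = core_cells
    )
    structure(list(datasets = datasets, drugs = drugs, truth = truth,
                   fingerprints = NULL, config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$datasets), " datasets, ", nrow(x$drugs), " drugs, ",
      nrow(x$datasets[[1]]$features), " features\n", sep = "")
  invisible(x)
}

#' Simulate structure fingerprints for drug groups
#'
#' Builds bit-set fingerprints whose pairwise Tanimoto coefficients hit
#' prescribed within-group and between-group targets.  Each drug's set is
#' the union of a global block (shared by all drugs), a group core and a
#' drug-private block; block sizes are solved from the two similarity
#' targets and rounded, so realized coefficients match the targets up to
#' integer rounding.
#'
#' @param drugs Drug tibble (only `drug_id` is used).
#' @param groups Named list partitioning drug ids into structure groups.
#' @param within_sim Target Tanimoto coefficient inside a group.
#' @param between_sim Target Tanimoto coefficient between groups
#'   (`between_sim <= within_sim`).
#' @param size Nominal fingerprint size in bits.
#' @param seed Integer seed (bit identities are arbitrary but fixed).
#' @return Named list mapping drug id to a sorted integer bit set.
#' @export
simulate_fingerprints <- function(drugs, groups, within_sim = 0.7, between_sim = 0.1,
                                  size = 64, seed = 1L) {
  if (length(groups) == 0 || any(lengths(groups) == 0)) abort("`groups` must be non-empty")
  if (within_sim <= 0 || within_sim > 1 || between_sim < 0 || between_sim > within_sim) {
    abort("need 0 < within_sim <= 1 and 0 <= between_sim <= within_sim")
  }
  all_drugs <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_drugs)) abort("`groups` must be a partition (drug appears twice)")
  # block sizes: within J = (g + c) / (g + c + 2p); between J = g / (2s - g)
  shared <- round(2 * within_sim * size / (1 + within_sim))   # g + c
  p_priv <- size - shared
  g_glob <- min(round(2 * size * between_sim / (1 + between_sim)), shared)
  c_core <- shared - g_glob
  nxt <- 1L
  take <- function(k) {
    if (k <= 0) return(integer(0))
    out <- seq.int(nxt, nxt + k - 1L)
    nxt <<- nxt + as.integer(k)
    out
  }
  glob <- take(g_glob)
  fps <- list()
  for (gname in sort_c(names(groups))) {
    core <- take(c_core)
    for (d in sort_c(groups[[gname]])) {
      fps[[d]] <- sort(c(glob, core, take(p_priv)))
    }
  }
  fps[sort_c(all_drugs)]
}

#' Write a cohort to the harmonized TSV contract
#'
#' Writes, per dataset, `*_sensitivity.tsv`, `*_silencing.tsv`,
#' `*_features.tsv` and `*_lineages.tsv`, plus `drugs.tsv`, `catalog.tsv`
#' (planted transporters as the annotated sets), `truth.json`,
#' `fingerprints.json` (when present) and `manifest.json`.  The matrices
#' round-trip losslessly through [read_matrix()].
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a named list, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create output directory: ", out_dir))
  manifest <- list(datasets = list())
  for (nm in names(cohort$datasets)) {
    ds <- cohort$datasets[[nm]]
    paths <- list(
      sensitivity = file.path(out_dir, paste0(nm, "_sensitivity.tsv")),
      silencing = file.path(out_dir, paste0(nm, "_silencing.tsv")),
      features = file.path(out_dir, paste0(nm, "_features.tsv")),
      lineages = file.path(out_dir, paste0(nm, "_lineages.tsv"))
    )
    write_matrix(ds$sensitivity, paths$sensitivity, id_column = "drug_id")
    write_matrix(ds$silencing, paths$silencing, id_column = "gene_id")
    write_matrix(ds$features, paths$features, id_column = "feature_id")
    utils::write.table(ds$lineages, paths$lineages, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$datasets[[nm]] <- lapply(paths, basename)
  }
  write_drug_annotations(cohort$drugs, file.path(out_dir, "drugs.tsv"))
  catalog <- new_transporter_catalog(
    all_transporters = sort_c(grep("^TR", rownames(cohort$datasets[[1]]$features), value = TRUE)),
    annotated = Filter(length, cohort$truth$planted_transporters)
  )
  write_transporter_catalog(catalog, file.path(out_dir, "catalog.tsv"))
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$drugs <- "drugs.tsv"
  manifest$catalog <- "catalog.tsv"
  manifest$truth <- "truth.json"
  if (!is.null(cohort$fingerprints)) {
    jsonlite::write_json(cohort$fingerprints, file.path(out_dir, "fingerprints.json"),
                         auto_unbox = FALSE)
    manifest$fingerprints <- "fingerprints.json"
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
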