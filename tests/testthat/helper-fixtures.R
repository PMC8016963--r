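# Fixtures are generated in code; nothing is read from disk.

# A small two-dataset cohort configuration for fast end-to-end tests.
small_sim_cfg <- function(seed = 1L, ...) {
  args <- list(n_datasets = 2, n_cells_per_dataset = 60, overlap_fraction = 0.5,
               n_transporters = 50, n_genetic_features = 5, n_targets = 3,
               drugs_per_target = 3, planted_per_drug = 2, effect_size_beta = 2,
               noise_sd = 1, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(diffsen::sim_config, args)
}

# labeled matrix literal
lm_mat <- function(values, row_ids, col_ids) {
  matrix(values, nrow = length(row_ids), byrow = TRUE,
         dimnames = list(row_ids, col_ids))
}

# drug tibble literal
drug_tbl <- function(ids, targets) {
  tibble::tibble(drug_id = ids, name = ids, targets = targets,
                 n_targets = lengths(targets), smiles = NA_character_,
                 datasets = rep(list(character(0)), length(ids)))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
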