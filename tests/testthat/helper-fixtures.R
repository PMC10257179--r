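# Builders for small in-memory trial datasets used across the suite.

# One experiment with given per-arm outcome vectors; arms is a named list,
# "control" must be present for a valid dataset.
make_experiment <- function(experiment_id, arms, litter_id = paste0(experiment_id, "_L1")) {
  rows <- lapply(names(arms), function(a) {
    y <- arms[[a]]
    data.frame(animal_id = sprintf("%s_%s_%02d", experiment_id, a, seq_along(y)),
               experiment_id = experiment_id,
               litter_id = litter_id,
               treatment = a,
               sex = rep_len(c("male", "female"), length(y)),
               area_loss_pct = y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

make_dataset <- function(...) {
  trial_dataset(do.call(rbind, list(...)))
}

# Two-arm single-experiment dataset for conjugate-mode checks.
make_two_group <- function(control, treated, treatment = "drugA") {
  make_dataset(make_experiment("E1", stats::setNames(list(control, treated),
                                                     c("control", treatment))))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
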