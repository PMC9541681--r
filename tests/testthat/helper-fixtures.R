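# Shared builders for small populations and scenario configs.

make_pop <- function(x, genotype) {
  list(generation = 0L, x = as.numeric(x),
       genotype = drivewave:::genotype_code(genotype))
}

make_snapshot <- function(x, genotype) list(x = as.numeric(x), genotype = genotype)

small_config <- function(...) {
  args <- list(
    drive_system = "X_SHREDDER", R = 6, sigma = 5,
    landscape_length = 1000, wt_init_range = c(100, 500),
    intro_position = 100, max_generations = 40, seed = 1
  )
  args[names(list(...))] <- list(...)
  do.call(scenario_config, args)
}

# brute-force AUC by exhaustive concordant-pair counting (ties count 1/2)
auc_by_pairs <- function(outcome, score) {
  y <- as.logical(outcome)
  pos <- score[y]; neg <- score[!y]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
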