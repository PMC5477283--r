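# Expensive study runs shared across acceptance test blocks: each
# setting's replicate set is computed once per test session and reused,
# with all methods of a setting fitted on the same replicate data so
# method contrasts are paired.

study_cache <- new.env(parent = emptyenv())

study_cells <- function(setting, methods, replicates = 100, seed = 42) {
  key <- paste(setting, paste(sort(methods), collapse = "+"), replicates,
               seed, sep = "|")
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- run_auc_study(setting, methods,
                                        replicates = replicates, seed = seed)
  }
  study_cache[[key]]
}

consistency_runs <- function(n, replicates = 1000, seed = 1) {
  key <- paste("consistency", n, replicates, seed, sep = "|")
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- run_consistency_study(n = n, replicates = replicates,
                                                seed = seed)
  }
  study_cache[[key]]
}

cell_mean <- function(res, method) {
  mean(res$auc[res$method == method], na.rm = TRUE)
}

paired_diff <- function(res, method_a, method_b) {
  a <- res[res$method == method_a, c("replicate", "auc")]
  b <- res[res$method == method_b, c("replicate", "auc")]
  m <- merge(a, b, by = "replicate")
  mean(m$auc.x - m$auc.y, na.rm = TRUE)
}
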