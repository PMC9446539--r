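# Shared setup for the numbered analysis scripts: output locations and a tiny
# cache so later scripts can reuse the expensive intermediates (cohorts, DAE
# models) computed by earlier ones. Run the scripts in order from the
# repository root, e.g.:  Rscript analysis/01_simulate_cohorts.R

library(ehrlatent)

RESULTS_DIR <- "results"
CACHE_DIR <- file.path(RESULTS_DIR, "cache")
dir.create(CACHE_DIR, recursive = TRUE, showWarnings = FALSE)

MASTER_SEED <- 20220905L   # one master seed for the whole analysis

cache_path <- function(name) file.path(CACHE_DIR, paste0(name, ".rds"))

cache_get <- function(name) {
  p <- cache_path(name)
  if (!file.exists(p)) {
    stop("missing intermediate '", name,
         "': run the earlier analysis scripts first", call. = FALSE)
  }
  readRDS(p)
}

cache_put <- function(object, name) {
  saveRDS(object, cache_path(name))
  invisible(object)
}

write_result <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.csv(df, path, row.names = FALSE)
  message("wrote ", path)
}
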