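# Shared helpers of the analysis drivers. Run every driver from the
# repository root: Rscript analysis/<nn>_<name>.R
library(swimcpg)

results_dir <- "results"
if (!dir.exists(results_dir)) dir.create(results_dir, recursive = TRUE)

save_json <- function(x, name) {
  path <- file.path(results_dir, paste0(name, ".json"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat("wrote", path, "\n")
}

save_rows <- function(rows, name) {
  path <- file.path(results_dir, paste0(name, ".tsv"))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("wrote", path, "\n")
}
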