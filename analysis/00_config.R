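# Shared setup for the numbered analysis scripts: load the package,
# read the run configuration, and point everything at results/.
library(radpopgen)

config_path <- Sys.getenv("RADPOPGEN_CONFIG",
                          system.file("extdata", "example-config.yml",
                                      package = "radpopgen"))
rc <- read_run_config(config_path)
res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)
path <- function(...) file.path(res_dir, ...)
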