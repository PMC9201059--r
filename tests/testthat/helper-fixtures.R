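table1_path <- function() {
  system.file("extdata", "table1.yaml", package = "mbcea")
}

base_config <- function() {
  load_config(table1_path())
}

# Raw list mirror of the bundled fixture, for building perturbed configs
base_config_list <- function() {
  yaml::read_yaml(table1_path())
}
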