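# Shared fixture builders.  Everything is generated in code from fixed
# seeds; the "small" family keeps per-file runtime low while the default
# family is reserved for the end-to-end recovery suite.

small_family <- function(seed = 11L) {
  cfg <- family_config(
    seed = seed,
    architectures = list(R1 = "a-b-c-d'", R2 = "m-b-e-d'"),
    n_copies = 2L)
  generate_family(cfg)
}

small_model <- function(fam, seed = 12L) {
  build_domain_model(synthetic_reference(fam$prototypes, seed = seed))
}

tmp_path <- function(ext = ".tmp") {
  tempfile(fileext = ext)
}

AA_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
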