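# Shared fixtures, built in code. Expensive ones are memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

make_compounds <- function(smiles, prefix = "c") {
  data.frame(id = if (length(smiles)) paste0(prefix, seq_along(smiles))
             else character(0),
             smiles = smiles,
             provenance = rep("test", length(smiles)),
             stringsAsFactors = FALSE)
}

tiny_schema <- function() condition_schema(buffer = c("K100", "Na100"),
                                           lgr = c("5", "10"))

# A small in-memory dataset: explicit structures, conditions and endpoints.
tiny_dataset <- function(smiles, buffer, lgr, value, endpoint = "dTm") {
  n <- length(smiles)
  ids <- paste0("t", formatC(seq_len(n), width = 3, flag = "0"))
  new_qsar_dataset(
    data.frame(id = ids, smiles = smiles, provenance = "test",
               stringsAsFactors = FALSE),
    data.frame(compound_id = ids, buffer = buffer, lgr = lgr,
               endpoint_name = endpoint, value = value,
               class_label = NA_integer_, stringsAsFactors = FALSE),
    tiny_schema())
}

write_tiny_csv <- function(path, rows) {
  writeLines(c("smiles,buffer,lgr,dTm", rows), path)
  path
}

# Default synthetic study conditions, shared by the heavier tests.
default_synth <- function() {
  memo("default_synth", {
    spec <- synth_spec()  # n = 600, 10% label noise, seed 42
    gen <- generate_synth(spec)
    cur <- curate_dataset(gen$dataset)
    list(spec = spec, gen = gen, curated = cur$dataset, report = cur$report)
  })
}

default_recovery <- function() {
  memo("default_recovery", recovery_benchmark(synth_spec(), seed = 7L))
}

# Internal accessor used by tests that need the non-exported constructor.
new_qsar_dataset <- mtqsar:::new_qsar_dataset
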