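test_that("bundled grids enumerate the deployed condition counts", {
  grids <- default_condition_grids()
  expect_setequal(names(grids), c("selectivity", "interaction",
                                  "stabilization", "cytotoxicity"))
  sizes <- vapply(grids, function(g) nrow(enumerate_conditions(g)), 0L)
  expect_equal(unname(sizes[c("selectivity", "interaction",
                              "stabilization", "cytotoxicity")]),
               c(18L, 24L, 24L, 10L))
  # deterministic ordering: fields in schema order, values in config order
  sel <- enumerate_conditions(grids$selectivity)
  expect_equal(sel$sequence[1:3], rep(grids$selectivity$fields$sequence[1], 3))
  expect_equal(sel$buffer[1:3], grids$selectivity$fields$buffer)
  # derived oncogene column fills by sequence lookup, not as a factor
  expect_true("oncogene" %in% names(sel))
  expect_equal(sel$oncogene[1], "hTel")
  expect_equal(unique(sel$oncogene[sel$sequence ==
    "TGAGGGTGGGTAGGGTGGGTAA"]), "cMYC")
  # grid/schema agreement check
  expect_error(enumerate_conditions(grids$selectivity, schema = tiny_schema()),
               "not in the model schema")
})

test_that("row counts obey the grid-size product for arbitrary grids", {
  g <- structure(list(model = "toy",
                      fields = list(a = c("x", "y", "z"), b = c("1", "2"),
                                    c = c("u")),
                      derived = NULL, sequence_targets = NULL),
                 class = "condition_grid")
  expect_equal(nrow(enumerate_conditions(g)), 6L)
})

test_that("rule-of-5 filter passes ethanol and fails a C40 alkane on MW and logP", {
  cmp <- make_compounds(c("CCO", paste(rep("C", 40), collapse = "")))
  out <- lipinski_filter(cmp)
  expect_equal(out$pass$id, "c1")
  expect_equal(out$fail$id, "c2")
  expect_match(out$fail$violations, "MW>500")
  expect_match(out$fail$violations, "logP>5")
  # one-violation allowance is configurable
  out1 <- lipinski_filter(cmp, max_violations = 2)
  expect_setequal(out1$pass$id, c("c1", "c2"))
  empty <- lipinski_filter(make_compounds(character(0)))
  expect_equal(nrow(empty$pass), 0L)
  expect_equal(nrow(empty$fail), 0L)
})

random_prediction_matrix <- function(seed) {
  set.seed(seed)
  smiles <- paste0("mol", 1:6)
  res <- lapply(c(a = "a", b = "b", c = "c", d = "d"), function(m) {
    data.frame(smiles = rep(smiles, each = 3),
               cond = rep(1:3, 6),
               prediction = rbinom(18, 1, 0.6),
               in_ad = TRUE)
  })
  structure(list(results = res), class = "prediction_matrix")
}

test_that("all_conditions consensus is always a subset of any_condition", {
  for (seed in 1:20) {
    pm <- random_prediction_matrix(seed)
    strict <- consensus_positive(pm, "all_conditions")
    loose <- consensus_positive(pm, "any_condition")
    expect_true(all(strict %in% loose))
  }
  pm <- random_prediction_matrix(1)
  expect_error(consensus_positive(pm, required_models = c("a", "e")),
               "missing model")
})

test_that("consensus rules behave on explicit patterns", {
  mk <- function(p1, p2) {
    structure(list(results = list(
      m1 = data.frame(smiles = "x", cond = 1:2, prediction = p1, in_ad = TRUE),
      m2 = data.frame(smiles = "x", cond = 1:2, prediction = p2, in_ad = TRUE))),
      class = "prediction_matrix")
  }
  # positive somewhere in each model -> retained under any_condition
  expect_equal(consensus_positive(mk(c(1L, 0L), c(0L, 1L))), "x")
  expect_length(consensus_positive(mk(c(1L, 0L), c(0L, 1L)),
                                   "all_conditions"), 0L)
  # negative everywhere in one model -> excluded under both rules
  expect_length(consensus_positive(mk(c(1L, 1L), c(0L, 0L))), 0L)
  # positive everywhere -> retained under both
  expect_equal(consensus_positive(mk(c(1L, 1L), c(1L, 1L)), "all_conditions"),
               "x")
})

# End-to-end screen over the cytotoxicity grid with a model trained on
# builtin descriptors: class planted as a molecular-weight rule.
cytotox_model <- function() {
  memo("cytotox_model", {
    grid <- default_condition_grids()$cytotoxicity
    schema <- grid_schema(grid)
    lib <- mtqsar:::.fragment_library(60)
    set.seed(6)
    n <- 60
    ids <- paste0("trn", seq_len(n))
    cmp <- data.frame(id = ids, smiles = lib[seq_len(n)], provenance = "t",
                      stringsAsFactors = FALSE)
    recs <- data.frame(compound_id = ids,
                       cell_line = sample(schema$fields$cell_line, n, TRUE),
                       exposure_time = sample(schema$fields$exposure_time, n, TRUE),
                       assay = "MTT",
                       endpoint_name = "IC50", value = NA_real_,
                       class_label = NA_integer_, stringsAsFactors = FALSE)
    ds <- new_qsar_dataset(cmp, recs, schema)
    desc <- compute_descriptors(cmp)
    # small molecules potent, large ones not; back-compute IC50 from the rule
    mw <- desc$values[ids, "MW"]
    ds$records$value <- ifelse(mw < stats::median(mw), 2, 30)
    ds <- label_dataset(ds)
    fit <- mtqsar(ds, descriptors = desc, n_features = 2,
                  ga = list(pop_size = 20, generations = 10),
                  rf_params = NULL, method = "lda", seed = 11)
    fit
  })
}

test_that("screening produces grid-sized blocks with AD verdicts", {
  model <- cytotox_model()
  lib <- mtqsar:::.fragment_library(70)
  queries <- data.frame(id = c("q1", "q2"), smiles = lib[61:62],
                        provenance = "q", stringsAsFactors = FALSE)
  pm <- screen_compounds(queries, list(cytotoxicity = model))
  df <- pm$results$cytotoxicity
  expect_equal(nrow(df), 2L * 10L)          # grid size per compound
  expect_true(all(df$prediction %in% c(0L, 1L)))
  expect_true(all(df$in_ad %in% c(TRUE, FALSE)))
  expect_true(all(c("cell_line", "exposure_time", "assay") %in% names(df)))
  # order independence: permuting input permutes but never changes rows
  pm2 <- screen_compounds(queries[2:1, ], list(cytotoxicity = model))
  df2 <- pm2$results$cytotoxicity
  for (s in queries$smiles) {
    expect_equal(df[df$smiles == s, , drop = FALSE][, -1],
                 df2[df2$smiles == s, , drop = FALSE][, -1],
                 ignore_attr = TRUE)
  }
})

test_that("screening refuses a descriptor-backend mismatch", {
  model <- cytotox_model()
  model$backend <- "synthetic"
  queries <- make_compounds("CCO")
  expect_error(screen_compounds(queries, list(cytotoxicity = model)),
               "backend mismatch")
})
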