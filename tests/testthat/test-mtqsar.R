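# Front-end fit on a small synthetic study; shared across blocks.
small_fit <- function(method = "lda") {
  memo(paste0("small_fit_", method), {
    gen <- memo("small_gen", generate_synth(synth_spec(n_compounds = 150,
                                                       seed = 42)))
    cur <- memo("small_cur", curate_dataset(gen$dataset))
    mtqsar(cur$dataset, descriptors = gen$descriptors, method = method,
           n_features = 2, ga = list(pop_size = 30, generations = 15),
           seed = 7)
  })
}

test_that("mtqsar returns a classed fit with the expected components", {
  fit <- small_fit()
  expect_s3_class(fit, "mtqsar")
  expect_length(fit$selected_columns, 2L)
  expect_s3_class(fit$condition_means, "condition_means")
  expect_s3_class(fit$ad_reference, "ad_reference")
  expect_named(fit$validation,
               c("train", "cv", "test", "external", "external_in_ad"))
  expect_output(print(fit), "Multi-tasking QSAR")
  s <- summary(fit)
  expect_s3_class(s, "summary.mtqsar")
  expect_equal(dim(s$table), c(6L, 6L))
  expect_output(print(s), "Validation metrics")
  expect_length(coef(fit), 3L)  # two weights + intercept
  expect_silent(grDevices::pdf(NULL))
  plot(fit); grDevices::dev.off()
})

test_that("mtqsar refuses unlabeled data and unknown descriptors backends", {
  gen <- generate_synth(synth_spec(n_compounds = 30, seed = 2))
  expect_error(mtqsar(gen$dataset, descriptors = gen$descriptors),
               "unset class labels")
  fit <- small_fit()
  cur <- memo("small_cur", curate_dataset(
    memo("small_gen", generate_synth(synth_spec(n_compounds = 150,
                                                seed = 42)))$dataset))
  builtin <- compute_descriptors(cur$dataset$compounds[1:3, ])
  expect_error(predict(fit, cur$dataset$records[1:3, ], builtin),
               "backend mismatch")
})

test_that("predict on records reproduces the stored external evaluation", {
  fit <- small_fit()
  gen <- memo("small_gen", generate_synth(synth_spec(n_compounds = 150,
                                                     seed = 42)))
  cur <- memo("small_cur", curate_dataset(gen$dataset))
  recs <- cur$dataset$records
  rownames(recs) <- NULL
  ext <- recs[fit$splits$external$external, , drop = FALSE]
  pred <- predict(fit, ext, gen$descriptors)
  acc <- 100 * mean(pred == ext$class_label)
  expect_equal(acc, unname(fit$validation$external$metrics["accuracy"]))
  # LDA scores are available and monotone with the class call
  sc <- predict(fit, ext, gen$descriptors, type = "score")
  expect_equal(as.integer(sc > 0), pred)
})

test_that("model bundles round-trip bit-for-bit and detect tampering", {
  for (method in c("lda", "rf")) {
    fit <- small_fit(method)
    gen <- memo("small_gen", generate_synth(synth_spec(n_compounds = 150,
                                                       seed = 42)))
    cur <- memo("small_cur", curate_dataset(gen$dataset))
    recs <- cur$dataset$records
    rownames(recs) <- NULL
    ext <- recs[fit$splits$external$external, , drop = FALSE]
    dir <- withr::local_tempdir()
    save_model(fit, dir)
    back <- load_model(dir)
    expect_identical(predict(back, ext, gen$descriptors),
                     predict(fit, ext, gen$descriptors))
    expect_identical(back$selected_columns, fit$selected_columns)
  }
  # tampering with the stored parameters trips the checksum
  fit <- small_fit()
  dir <- withr::local_tempdir()
  save_model(fit, dir)
  cj <- file.path(dir, "classifier.json")
  writeLines(sub("\\[", "[9,", readLines(cj)), cj)
  expect_error(load_model(dir), "checksum")
  # a bundle without condition means cannot load
  dir2 <- withr::local_tempdir()
  save_model(fit, dir2)
  unlink(file.path(dir2, "condition_means.json"))
  expect_error(load_model(dir2), "condition_means|missing")
})

test_that("euclidean train/test division is wired through the front end", {
  gen <- memo("small_gen", generate_synth(synth_spec(n_compounds = 150,
                                                     seed = 42)))
  cur <- memo("small_cur", curate_dataset(gen$dataset))
  fit <- mtqsar(cur$dataset, descriptors = gen$descriptors, method = "lda",
                n_features = 2, test_method = "euclidean",
                ga = list(pop_size = 20, generations = 8), seed = 7)
  expect_equal(fit$splits$train_test$method, "euclidean")
  n_mod <- length(fit$splits$external$modeling)
  expect_equal(length(fit$splits$train_test$test), floor(n_mod / 5))
})
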