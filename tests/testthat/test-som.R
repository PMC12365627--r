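test_that("initialization is reproducible and class weights start uniform", {
  p <- som_params(rows = 10, cols = 10)
  m <- som_init(p, n_vars = 1001, classes = letters[1:4], seed = 3)
  expect_equal(dim(m$W), c(100, 1001))
  expect_equal(dim(m$C), c(100, 4))
  expect_true(all(abs(rowSums(m$C) - 1) < 1e-12))
  m2 <- som_init(p, 1001, letters[1:4], seed = 3)
  expect_identical(m$W, m2$W)
  expect_false(m$trained)
})

test_that("BMU matching agrees with an exhaustive scan and breaks ties low", {
  set.seed(6)
  p <- som_params(rows = 5, cols = 4)
  m <- som_init(p, n_vars = 12, classes = c("a", "b"), seed = 2)
  # exact-match query
  expect_equal(som_bmu(m, m$W[17, ]), 17)
  # tie: duplicate neuron weights, query equidistant
  m$W[9, ] <- m$W[3, ]
  expect_equal(som_bmu(m, m$W[3, ]), 3)
  # oracle equivalence on random queries, single and batched
  queries <- matrix(rnorm(100 * 12), 100)
  got <- evraman:::som_bmu_matrix(m, queries)
  for (i in 1:100) {
    expect_equal(som_bmu(m, queries[i, ]), oracle_bmu(m$W, queries[i, ]))
    expect_equal(got[i], oracle_bmu(m$W, queries[i, ]))
  }
  expect_error(som_bmu(m, rnorm(5)), "does not match")
})

test_that("a single neuron converges to the training mean", {
  set.seed(12)
  X <- matrix(rnorm(40, 10, 1), 20, 2)
  ds <- ev_dataset(X, 1:2, tibble::tibble(sample_id = sprintf("x%02d", 1:20),
                                          class = "a"))
  fit <- som_fit(ds, "class", som_params(rows = 1, cols = 1, epochs = 300,
                                         eta0 = 0.1, sigma0 = 0.5), seed = 1)
  target <- colMeans(X)
  expect_lt(max(abs(fit$W[1, ] - target) / abs(target)), 0.01)
})

test_that("two separated clusters occupy different neurons with their own class", {
  ds <- toy_blobs(n_per = 10, d = 2, sep = 8, seed = 3)
  fit <- som_fit(ds, "class", som_params(rows = 2, cols = 1, epochs = 50), seed = 2)
  mc <- som_modal_classes(fit, ds)
  expect_setequal(mc$modal_class, c("A", "B"))

  fit2 <- som_fit(ds, "class", som_params(rows = 2, cols = 1, epochs = 50), seed = 2)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$C, fit2$C)
})

test_that("quantization error does not increase across epochs", {
  ds <- ev_simulate_spectra(tibble::tibble(fraction = "small",
                                           state = c("healthy", "cvd"), n = 20),
                            seed = 4)
  fit <- som_fit(ev_preprocess(ds), "state",
                 som_params(rows = 5, cols = 5, epochs = 4), seed = 4)
  expect_equal(length(fit$qe), 4)
  expect_true(all(diff(fit$qe) <= 1e-6))
})

test_that("classification returns normalized scores and recovers separable labels", {
  ds <- toy_blobs(n_per = 15, d = 4, sep = 7, seed = 5)
  fit <- som_fit(ds, "class", som_params(rows = 3, cols = 3, epochs = 30), seed = 5)
  pred <- predict(fit, ds)
  expect_equal(pred$.pred_class, ds$class)
  scores <- as.matrix(pred[, c(".score_A", ".score_B")])
  expect_true(all(abs(rowSums(scores) - 1) < 1e-12))

  # single-class training: everything classified as that class
  one <- ds[ds$class == "A", ]
  fit1 <- som_fit(one, "class", som_params(rows = 2, cols = 2, epochs = 10), seed = 1)
  expect_true(all(predict(fit1, ds)$.pred_class == "A"))
})

test_that("neuron modal classes follow majority with ties and silence as none", {
  p <- som_params(rows = 3, cols = 1, epochs = 1)
  m <- som_init(p, 2, c("A", "B"), seed = 1)
  m$W <- rbind(c(0, 0), c(10, 10), c(100, 100))
  m$trained <- TRUE
  m$label <- "class"
  X <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(0.2, 0),   # 3 A, 1 B at neuron 1
             c(10, 10), c(10.1, 10))                      # A/B tie at neuron 2
  ds <- ev_dataset(X, 1:2, tibble::tibble(
    sample_id = sprintf("m%d", 1:6), class = c("A", "A", "A", "B", "A", "B")))
  mc <- som_modal_classes(m, ds)
  expect_equal(mc$modal_class, c("A", "none", "none"))
  expect_equal(mc$n_hits, c(4L, 2L, 0L))
})

test_that("SOMDI highlights the band that separates two classes", {
  # two classes differing only at variable 30 of 100
  set.seed(7)
  n <- 30
  base <- matrix(rnorm(2 * n * 100, 0, 0.05), 2 * n, 100)
  base[1:n, 30] <- base[1:n, 30] + 2
  ds <- ev_dataset(base, 1:100, tibble::tibble(
    sample_id = sprintf("b%03d", 1:(2 * n)),
    class = rep(c("hi", "lo"), each = n)))
  fit <- som_fit(ds, "class", som_params(rows = 3, cols = 3, epochs = 20), seed = 7)
  sd_ <- ev_somdi(fit)
  pk <- somdi_peaks(sd_, n = 1)
  expect_equal(pk$wavenumber[pk$class == "hi"], 30)
  # normalization: max exactly 1 for non-degenerate classes
  expect_equal(max(sd_$somdi[sd_$class == "hi"]), 1)
  expect_true(all(sd_$somdi >= 0))

  # identical classes: SOMDI carries no structure above noise at the marker
  base2 <- matrix(rnorm(2 * n * 100, 0, 0.05), 2 * n, 100)
  ds2 <- ev_dataset(base2, 1:100, tibble::tibble(
    sample_id = sprintf("c%03d", 1:(2 * n)),
    class = rep(c("hi", "lo"), each = n)))
  fit2 <- som_fit(ds2, "class", som_params(rows = 3, cols = 3, epochs = 20), seed = 8)
  raw2 <- t(sweep(fit2$W, 2, colMeans(fit2$W))) %*% fit2$C
  expect_lt(max(abs(raw2)), 0.1)  # pre-normalization discriminant is near zero
})

test_that("cross-validation is stratified and finds separable toys easy", {
  ds <- toy_blobs(n_per = 20, d = 3, sep = 6, seed = 9)
  cv <- som_cv(ds, "class", grid = tibble::tibble(rows = 2, cols = 2, epochs = 10),
               folds = 4, seed = 9)
  expect_equal(nrow(cv), 1)
  expect_equal(cv$mean_accuracy, 1.0)
  fold_id <- attr(cv, "fold_id")
  tab <- table(fold_id, ds$class)
  expect_true(all(abs(tab - mean(tab)) <= 1))

  expect_error(som_cv(ds, "class", folds = 30), "infeasible stratification")
})

test_that("hold-out evaluation reports coherent confusion counts", {
  ds <- toy_blobs(n_per = 20, d = 3, sep = 6, seed = 10, k = 4)
  ev <- som_evaluate(ds, "class", som_params(rows = 4, cols = 4, epochs = 20),
                     seed = 10)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(nrow(ev$confusion), 4)
  # one-vs-rest counts: each class row sums to the test size
  expect_true(all(rowSums(ev$confusion[, c("TP", "TN", "FP", "FN")]) == ev$n_test))
  expect_equal(sum(ev$confusion$TP + ev$confusion$FN), ev$n_test * 1L * 4L / 4L * 1L)

  g <- glance(ev)
  expect_equal(g$accuracy, 1.0)
  t <- tidy(ev)
  expect_true(all(t$sensitivity == 1))
})

test_that("tidiers expose the model as tibbles", {
  ds <- toy_blobs(n_per = 8, d = 3, sep = 6, seed = 11)
  fit <- som_fit(ds, "class", som_params(rows = 2, cols = 3, epochs = 10), seed = 11)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_true(all(c("weight_A", "weight_B") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$rows, 2)
  expect_true(g$trained)
})
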