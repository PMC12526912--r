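test_that("closed-form layer counts reproduce the published tables", {
  seq256 <- lstm_sequential_spec(9, 256)
  expect_equal(tidy(seq256)$param_count[-1], c(264192, 32896, 645))
  bi <- bilstm_spec(9, 256)
  expect_equal(tidy(bi)$param_count[-1], c(528384, 131328, 1285))
  fcn <- lstm_fcn_spec(100, 8)
  counts <- tidy(fcn)
  expect_equal(counts$param_count[counts$layer == "conv1d_1"], 102528)
  expect_equal(counts$param_count[counts$layer == "conv1d_2"], 164096)
  expect_equal(counts$param_count[counts$layer == "conv1d_3"], 98432)
  expect_equal(counts$param_count[counts$layer == "bn_2"], 1024)
  expect_equal(sum(counts$param_count[grepl("bn_[13]", counts$layer)]), 1024)
  expect_equal(counts$param_count[counts$layer == "lstm"], 320)
  expect_equal(counts$param_count[counts$layer == "dense"], 685)
  # smallest cases pin the closed forms themselves
  expect_equal(tidy(lstm_sequential_spec(9, 1))$param_count[2], 12)
  expect_equal(tidy(bilstm_spec(9, 1))$param_count[2], 24)
})

test_that("instantiated weight arrays match the closed-form totals", {
  for (spec in list(lstm_sequential_spec(9, 256),
                    lstm_sequential_spec(9, 512),
                    bilstm_spec(9, 256), bilstm_spec(9, 512),
                    lstm_fcn_spec(100, 8))) {
    net <- ecgbeat:::nn_init(spec, seed = 1)
    expect_equal(ecgbeat:::nn_count_params(net), parameter_count(spec))
  }
})

test_that("softmax outputs are probability vectors for all architectures", {
  set.seed(12)
  for (spec in list(lstm_sequential_spec(7, 5), bilstm_spec(7, 4),
                    lstm_fcn_spec(12, 3))) {
    net <- ecgbeat:::nn_init(spec, seed = 2)
    X <- matrix(rnorm(6 * spec$input_length), 6)
    P <- ecgbeat:::nn_forward(net, X, training = FALSE)$prob
    expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
    expect_true(all(P >= 0))
  }
})

test_that("confusion-matrix metrics equal hand-computed values", {
  C <- matrix(c(50, 2, 1, 0, 0,
                 3, 20, 1, 0, 0,
                 2, 1, 30, 1, 0,
                 0, 0, 2, 8, 0,
                 0, 0, 0, 0, 0), 5, 5, byrow = TRUE,
              dimnames = list(aami_classes(), aami_classes()))
  rep <- eval_report(C)
  total <- sum(C)
  expect_equal(rep$accuracy, sum(diag(C)) / total)
  support <- rowSums(C); predicted <- colSums(C)
  prec <- ifelse(predicted > 0, diag(C) / predicted, 0)
  rec <- diag(C) / support
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / total
  expect_equal(rep$precision, sum(prec * w))
  expect_equal(rep$recall, sum(rec * w, na.rm = TRUE))
  expect_equal(rep$f1, sum(f1 * w, na.rm = TRUE))
  # weighted recall equals accuracy for any confusion matrix
  expect_equal(rep$recall, rep$accuracy)
  # per-class accuracy is per-class recall
  expect_equal(unname(rep$per_class$class_accuracy[1]), C[1, 1] / support[[1]])
  # perfect and single-class predictions
  perfect <- diag(c(5, 5, 5, 5, 5)); dimnames(perfect) <- dimnames(C)
  expect_equal(eval_report(perfect)$accuracy, 1)
  allN <- matrix(0, 5, 5, dimnames = dimnames(C)); allN[, 1] <- 10
  expect_equal(eval_report(allN)$accuracy, 0.2)
})

test_that("splits are stratified, deterministic and guarded", {
  feats <- synth_separable_features(600, input_length = 9, seed = 5)
  s1 <- ecgbeat:::stratified_split(feats$label, 0.7, seed = 9)
  s2 <- ecgbeat:::stratified_split(feats$label, 0.7, seed = 9)
  expect_identical(s1$train, s2$train)
  tab_all <- table(feats$label)
  tab_train <- table(feats$label[s1$train])
  expect_true(all(abs(tab_train - 0.7 * tab_all) <= 1))
  # degenerate single-class input is rejected
  one <- feats[feats$label == "N", ]
  expect_error(fit_beat_classifier(one, lstm_sequential_spec(9, 4)),
               class = "ecgbeat_validation_error")
})

test_that("a small network learns a separable problem end to end", {
  feats <- synth_separable_features(1200, input_length = 9, seed = 6)
  m <- fit_beat_classifier(feats, lstm_sequential_spec(9, 24),
                           train_config(epochs = 20, batch_size = 64,
                                        seed = 2, dropout = 0))
  rep <- evaluate_classifier(m)
  expect_gte(rep$accuracy, 0.9)
  expect_identical(dim(rep$confusion), c(5L, 5L))
  expect_equal(sum(rep$confusion), length(m$test_y))
  # broom-style accessors
  expect_s3_class(tidy(m), "tbl_df")
  g <- glance(rep)
  expect_equal(g$accuracy, rep$accuracy)
  # prediction shape
  p <- predict(m, feats[1:5, ], type = "prob")
  expect_identical(nrow(p), 5L)
  expect_lt(max(abs(rowSums(as.matrix(p[, -1])) - 1)), 1e-6)
  # evaluation on an empty set is an error
  expect_error(evaluate_classifier(m, feats[0, ]),
               class = "ecgbeat_validation_error")
})
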