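# Architecture builders: parameter accounting, shape traces, and the
# structural behaviors of the layer graph.

test_that("parameter counting handles single layers correctly", {
  # dense 10 -> 1 with bias
  m <- build_fnn(10, hidden = c(5, 3))
  expect_equal(unname(epiholdout:::trace_layer(epiholdout:::layer_dense(1), 10)$trainable), 11)
  # conv1d: kernel 40, 4 channels, 300 filters, bias
  tl <- epiholdout:::trace_layer(
    epiholdout:::layer_conv1d(40, 300, pad = "same"), c(3000, 4))
  expect_equal(unname(tl$trainable), 40 * 4 * 300 + 300)
  # batch norm: 2 trainable + 2 moving per channel
  bn <- epiholdout:::trace_layer(epiholdout:::layer_batchnorm(), c(100, 64))
  expect_equal(unname(bn$trainable), 128)
  expect_equal(unname(bn$total), 256)
})

test_that("builders reproduce the published parameter counts where arithmetic allows", {
  # the five models whose printed figures are reachable, each exact
  expect_equal(count_parameters(build_sequence_basic_cnn())[["trainable"]], 60100402)
  expect_equal(count_parameters(build_sequence_attention_cnn())[["trainable"]], 51345538)
  expect_equal(count_parameters(build_epi_basic_cnn(TRUE))[["total"]], 8838145)
  expect_equal(count_parameters(build_epi_resnet(TRUE))[["trainable"]], 5915841)
  expect_equal(count_parameters(build_epi_resnet(FALSE))[["total"]], 1625985)
})

test_that("the two arithmetically unreachable published counts are documented", {
  # sequence ResNet and one-branch epigenomics CNN: the builders implement
  # the faithful topologies and record the published figures they cannot
  # reach (see the methods vignette for the residue arguments)
  m5 <- build_sequence_resnet()
  expect_equal(count_parameters(m5)[["trainable"]], 796225)
  expect_equal(m5$metadata$published_count, 605452)
  m7 <- build_epi_basic_cnn(FALSE)
  expect_equal(count_parameters(m7)[["total"]], 8482817)
  expect_equal(m7$metadata$published_count, 12244481)
})

test_that("builders are pure: repeated construction gives identical graphs", {
  a <- build_epi_resnet(TRUE); b <- build_epi_resnet(TRUE)
  expect_identical(a, b)
  expect_identical(count_parameters(a), count_parameters(b))
})

test_that("shape traces match the published input/output dimensions", {
  tr <- epiholdout:::trace_model(build_epi_basic_cnn(TRUE))
  # valid conv-16 / pool-2 cascade: 296 -> 23 windows, 196 -> 11
  expect_equal(tr$enhancer[[length(tr$enhancer)]], c(23, 256))
  expect_equal(tr$promoter[[length(tr$promoter)]], c(11, 256))
  tr1 <- epiholdout:::trace_model(build_epi_basic_cnn(FALSE))
  expect_equal(epiholdout:::trace_layer(
    epiholdout:::layer_flatten(), c(492, 22))$shape, 492 * 22)
  expect_equal(tr1$input[[length(tr1$input)]], c(48, 256))
  # epigenomics ResNet stems: stride 2 on the enhancer, 1 on the promoter
  tr8 <- epiholdout:::trace_model(build_epi_resnet(TRUE))
  expect_equal(tr8$enhancer[[1]], c(148, 64))
  expect_equal(tr8$promoter[[1]], c(196, 64))
  expect_equal(tr8$enhancer[[length(tr8$enhancer)]], c(6, 256))
  expect_equal(tr8$promoter[[length(tr8$promoter)]], c(8, 256))
  # sequence ResNet: concatenated temporal length is 7 + 4 = 11
  tr5 <- epiholdout:::trace_model(build_sequence_resnet())
  expect_equal(tr5$enhancer[[length(tr5$enhancer)]], c(7, 64))
  expect_equal(tr5$promoter[[length(tr5$promoter)]], c(4, 64))
})

test_that("the attention model rejects uncropped inputs", {
  expect_error(build_sequence_attention_cnn(enhancer_len = 3000,
                                            promoter_len = 2000),
               "centrally cropped")
})

test_that("forward passes give one probability per sample", {
  set.seed(1)
  m <- build_epi_basic_cnn(TRUE, filters = 8, dense_units = 8)
  m <- init_model_weights(m)
  for (n in c(1, 3)) {
    x <- list(enhancer = array(0, c(n, 296, 22)), promoter = array(0, c(n, 196, 22)))
    p <- predict_model(m, x)
    expect_length(p, n)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("an attention gate saturated at one leaves activations unchanged", {
  set.seed(2)
  gate <- epiholdout:::init_layer(epiholdout:::layer_attention_gate(), 6L)
  gate$W[] <- 0
  gate$b[] <- 50                       # sigmoid(50) ~ 1
  X <- matrix(stats::rnorm(30), 5, 6)
  out <- epiholdout:::layer_forward(gate, X, training = FALSE)$out
  expect_equal(out, X, tolerance = 1e-12)
})

test_that("zeroing the residual branch reduces a unit to a gated identity", {
  set.seed(3)
  unit <- epiholdout:::init_layer(
    epiholdout:::layer_residual_unit(3, 8), c(20L, 8L))
  unit$g2[] <- 0                       # batch norm scale of the second conv
  unit$be2[] <- 0
  X <- array(stats::rnorm(5 * 20 * 8), c(5, 20, 8))
  out <- epiholdout:::layer_forward(unit, X, training = TRUE)$out
  expect_equal(out, pmax(X, 0), tolerance = 1e-12)
})

test_that("combined models concatenate penultimate features and freeze feeders", {
  set.seed(4)
  seq_m <- init_model_weights(build_fnn(10, hidden = c(8, 6)))
  epi_m <- init_model_weights(build_fnn(12, hidden = c(8, 4)))
  cmb <- build_combined_model(seq_m, epi_m, n_hidden_layers = 1, hidden_units = 5)
  expect_equal(cmb$head_input_dim, 6 + 4)
  n <- 40
  x <- list(seq = matrix(stats::rnorm(n * 10), n), epi = matrix(stats::rnorm(n * 12), n))
  y <- rep(c(0, 1), n / 2)
  before <- epiholdout:::model_weights(cmb$feeders$seq)
  ts <- train_model(cmb, x, y, x, y,
                    config = list(lr = 1e-2, batch_size = 10, l2_conv = 0),
                    max_epochs = 3, seed = 1)
  after <- epiholdout:::model_weights(ts$model$feeders$seq)
  expect_identical(before, after)
  expect_length(predict_model(ts$model, x), n)
  # feeders without a hidden dense layer are rejected by name
  bad <- build_sequence_resnet()
  expect_error(build_combined_model(bad, epi_m), "sequence_resnet")
})

test_that("an uninformative feeder does not drag the combined model below its informative feeder", {
  set.seed(9)
  n <- 400
  x_epi <- matrix(stats::rnorm(n * 8), n)
  y <- as.integer(x_epi[, 1] + 0.7 * x_epi[, 2] + stats::rnorm(n, 0, 0.4) > 0)
  x_seq <- matrix(stats::rnorm(n * 6), n)      # pure noise
  tr <- 1:300; te <- 301:400
  epi_ts <- train_model(build_fnn(8, hidden = c(16, 8), dropout = 0.1),
                        x_epi[tr, ], y[tr], x_epi[tr, ], y[tr],
                        config = list(lr = 5e-3, batch_size = 50, l2_conv = 0),
                        max_epochs = 25, seed = 1)
  seq_ts <- train_model(build_fnn(6, hidden = c(8, 4), dropout = 0.1),
                        x_seq[tr, ], y[tr], x_seq[tr, ], y[tr],
                        config = list(lr = 5e-3, batch_size = 50, l2_conv = 0),
                        max_epochs = 10, seed = 1)
  cmb <- build_combined_model(seq_ts$model, epi_ts$model, hidden_units = 16)
  xc <- list(seq = x_seq, epi = x_epi)
  cmb_ts <- train_model(cmb, epiholdout:::subset_x(xc, tr), y[tr],
                        epiholdout:::subset_x(xc, tr), y[tr],
                        config = list(lr = 5e-3, batch_size = 50, l2_conv = 0),
                        max_epochs = 25, seed = 1)
  a_epi <- auroc(predict_model(epi_ts$model, x_epi[te, ]), y[te])
  a_cmb <- auroc(predict_model(cmb_ts$model, epiholdout:::subset_x(xc, te)), y[te])
  expect_gt(a_epi, 0.85)
  expect_gt(a_cmb, a_epi - 0.1)
})

test_that("sweep results serialize to TSV and JSON and plot to SVG", {
  sw <- list(per_chrom = data.frame(chrom = c("chr1", "chr2"), n = c(30, 20),
                                    n_pos = c(3, 2), auroc = c(0.8, 0.6)),
             summary = weighted_auroc_summary(
               data.frame(auroc = c(0.8, 0.6), n = c(30, 20))),
             excluded = character(0), model_name = "fnn",
             feature_format = "epi_mean")
  dir <- withr::local_tempdir()
  write_sweep_results(sw, dir)
  back <- utils::read.table(file.path(dir, "per_chromosome.tsv"), header = TRUE,
                            sep = "\t")
  expect_equal(back$auroc, c(0.8, 0.6))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$weighted_mean, 0.72)
  svg_path <- file.path(dir, "aurocs.svg")
  plot_sweep_auroc(list(fnn = sw), svg_path)
  expect_true(file.exists(svg_path) && file.size(svg_path) > 0)
})

test_that("gradient boosting separates a 1-D threshold and respects the grid", {
  x <- matrix(c(seq(0, 1, length.out = 100)), ncol = 1)
  y <- as.integer(x[, 1] > 0.5)
  gb <- build_gradient_boosting(x, y, x, y, n_trees_grid = c(5, 20), seed = 1)
  expect_true(gb$n_trees %in% c(5, 20))
  expect_equal(auroc(predict_gradient_boosting(gb, x), y), 1)
  expect_error(build_gradient_boosting(x, y, x, y, n_trees_grid = integer(0)),
               "empty")
})
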