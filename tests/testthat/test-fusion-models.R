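test_that("fused width is the sum of enabled projection widths", {
  expect_identical(fused_width(model_spec("MLP")), 3584L)
  expect_identical(fused_width(model_spec("LIT")), 3584L)
  expect_identical(fused_width(model_spec("S_MLP")), 1792L)
  expect_identical(fused_width(model_spec("MLP", modalities = "PPG")), 256L)
  expect_identical(fused_width(model_spec("LIT", modalities = c("GSR", "ET"))),
                   256L + 1024L)
  # removing fNIRS from the full LIT drops exactly its projection
  expect_identical(fused_width(model_spec("LIT")) -
                     fused_width(model_spec("LIT",
                                            modalities = c("PPG", "GSR", "ET"))),
                   2048L)
  expect_error(model_spec("MLP", modalities = character()),
               class = "mwlfuse_invalid_argument")
})

test_that("S_ variants halve every layer width of their full counterpart", {
  for (m in c("PPG", "GSR", "ET", "fNIRS")) {
    for (fam in c("MLP", "LIT")) {
      full <- build_mnet(m, fam)
      small <- build_mnet(m, paste0("S_", fam))
      expect_identical(length(full), length(small))
      for (j in seq_along(full)) {
        expect_identical(full[[j]]$kind, small[[j]]$kind)
        if (!is.null(full[[j]]$width)) {
          expect_identical(small[[j]]$width, full[[j]]$width %/% 2L)
        }
      }
    }
  }
  # the ET literature MNet is four conv blocks plus a 1024-wide projection
  et <- build_mnet("ET", "LIT")
  kinds <- vapply(et, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "conv_block"), 4L)
  expect_true(all(vapply(et[kinds == "conv_block"], `[[`, integer(1),
                         "width") == 256L))
  expect_identical(et[[which(kinds == "dense_proj")]]$width, 1024L)
  expect_error(build_mnet("EMG", "MLP"), class = "mwlfuse_invalid_argument")
})

test_that("parameter counts are analytic, positive and monotone in width", {
  p_mlp <- count_parameters(model_spec("MLP"))
  p_smlp <- count_parameters(model_spec("S_MLP"))
  expect_lt(p_smlp, p_mlp)
  expect_lt(count_parameters(model_spec("S_LIT")),
            count_parameters(model_spec("LIT")))
  # oracle: count the instantiated weights of a small model
  spec <- model_spec("S_LIT", dropout_rate = 0, input_shapes = tiny_shapes,
                     width_scale = 0.1)
  net <- build_model(spec, seed = 1)
  counted <- 0
  for (layers in c(net$mnets, list(net$head))) {
    for (ly in layers) {
      for (p in mwlfuse:::layer_param_names(ly)) {
        counted <- counted + length(ly[[p]])
      }
    }
  }
  expect_equal(counted, count_parameters(spec))
})

test_that("built models emit deterministic sigmoid predictions per sample", {
  spec <- model_spec("S_MLP", dropout_rate = 0.2, input_shapes = tiny_shapes,
                     width_scale = 0.1)
  net <- build_model(spec, seed = 2)
  set.seed(3)
  batch <- lapply(tiny_shapes, function(s) {
    array(stats::rnorm(5 * s[1] * s[2]), c(5, s[1], s[2]))
  })
  p1 <- mwlfuse:::forward_network(net, batch, training = FALSE)$pred
  expect_length(p1, 5)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # inference is deterministic (dropout off)
  p2 <- mwlfuse:::forward_network(net, batch, training = FALSE)$pred
  expect_identical(p1, p2)
  # batch-of-n equals n single predictions (loop oracle)
  singles <- vapply(1:5, function(b) {
    one <- lapply(batch, function(a) a[b, , , drop = FALSE])
    mwlfuse:::forward_network(net, one, training = FALSE)$pred
  }, numeric(1))
  expect_equal(singles, p1, tolerance = 1e-12)
  # shape mismatches are reported with the modality named
  bad <- batch
  bad$ET <- bad$ET[, 1:8, , drop = FALSE]
  expect_error(mwlfuse:::forward_network(net, bad, training = FALSE),
               class = "mwlfuse_shape_error", regexp = "ET")
  expect_error(mwlfuse:::forward_network(net, batch[c("PPG", "GSR", "ET")],
                                         training = FALSE),
               class = "mwlfuse_shape_error", regexp = "fNIRS")
})

test_that("all four variants build and predict on tiny shapes", {
  set.seed(4)
  batch <- lapply(tiny_shapes, function(s) {
    array(stats::rnorm(3 * s[1] * s[2]), c(3, s[1], s[2]))
  })
  for (v in c("MLP", "S_MLP", "LIT", "S_LIT")) {
    spec <- model_spec(v, dropout_rate = 0.1, input_shapes = tiny_shapes,
                       width_scale = 0.05)
    net <- build_model(spec, seed = 5)
    p <- mwlfuse:::forward_network(net, batch, training = FALSE)$pred
    expect_true(all(is.finite(p) & p >= 0 & p <= 1), info = v)
  }
})
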