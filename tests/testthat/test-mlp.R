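test_that("the variance feature is the population variance", {
  expect_equal(rfu_variance(c(0.2, 0.2, 0.2)), 0)
  expect_equal(rfu_variance(c(0, 1)), 0.25)
  x <- c(0.1, 0.4, 0.45, 0.9, 0.2)
  expect_equal(rfu_variance(x), mean((x - mean(x))^2))
  expect_equal(rfu_variance(rev(x)), rfu_variance(x))
  expect_error(rfu_variance(0.3), class = "hdx_insufficient_data_error")
})

test_that("relu and mse behave as defined", {
  expect_equal(relu(-3.2), 0)
  expect_equal(relu(2.0), 2.0)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-1, 0.5)), c(0, 0.5))
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  a <- runif(5); b <- runif(5)
  expect_equal(mse(a, b), mse(b, a))
  expect_error(mse(1:3, 1:4), class = "hdx_shape_error")
})

test_that("backprop gradients match central finite differences", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      widths <- sample(2:6, sample(2:3, 1), replace = TRUE)
      spec <- mlp_spec(hidden = widths, seed = sample.int(1000, 1))
      p <- hdxamend:::mlp_init(spec)
      x <- matrix(rnorm(6), ncol = 1)
      y <- matrix(runif(12), ncol = 2)
      g <- hdxamend:::mlp_gradients(p, x, y)
      eps <- 1e-6
      for (probe in 1:4) {
        l <- sample(seq_along(p), 1)
        i <- sample(nrow(p[[l]]$W), 1)
        j <- sample(ncol(p[[l]]$W), 1)
        pp <- p; pm <- p
        pp[[l]]$W[i, j] <- pp[[l]]$W[i, j] + eps
        pm[[l]]$W[i, j] <- pm[[l]]$W[i, j] - eps
        num <- (mse(hdxamend:::mlp_forward(pp, x)$output, y) -
                  mse(hdxamend:::mlp_forward(pm, x)$output, y)) / (2 * eps)
        expect_equal(g[[l]]$W[i, j], num, tolerance = 1e-5)
      }
    }
  })
})

test_that("training is deterministic and a no-op at zero epochs", {
  d <- functional_training_set(120)
  tr <- dplyr::filter(d, protein == "trainA")
  va <- dplyr::filter(d, protein == "trainB") |>
    dplyr::mutate(protein = "val")
  spec0 <- mlp_spec(hidden = c(8, 8), epochs = 0, seed = 5)
  m0 <- train_mlp(tr, va, spec0)
  expect_equal(m0$params, hdxamend:::mlp_init(spec0))
  expect_length(m0$train_loss, 0)
  pred <- suppressWarnings(predict_controls(m0, tiny_uptake()))
  expect_true(all(is.finite(c(pred$rfu_back, pred$rfu_fwd))))

  spec <- mlp_spec(hidden = c(10, 8), epochs = 50, seed = 6,
                   learning_rate = 0.01)
  m1 <- train_mlp(tr, va, spec)
  m2 <- train_mlp(tr, va, spec)
  expect_identical(m1$params, m2$params)
  expect_error(train_mlp(tr, dplyr::mutate(va, protein = "trainA"), spec),
               class = "hdx_structural_error")
})

test_that("loss is nonincreasing on a linear network with small steps", {
  d <- functional_training_set(150, seed = 103)
  tr <- dplyr::filter(d, protein == "trainA")
  va <- dplyr::filter(d, protein == "trainB")
  m <- train_mlp(tr, va, mlp_spec(hidden = integer(0), epochs = 200,
                                  learning_rate = 0.05, seed = 7))
  expect_true(all(diff(m$train_loss) <= 1e-12))
})

test_that("the network learns a smooth variance-to-controls map", {
  d <- functional_training_set(400, seed = 104,
                               proteins = c("trainA", "trainA", "trainB"))
  tr <- dplyr::filter(d, protein == "trainA")
  va <- dplyr::filter(d, protein == "trainB")
  m <- train_mlp(tr, va, mlp_spec(epochs = 400, seed = 8))
  expect_lt(dplyr::last(m$train_loss), 0.1 * m$train_loss[1])
  expect_lt(dplyr::last(m$val_loss), 0.01)

  # held-out prediction error under 0.05 RFU on average
  pred <- hdxamend:::mlp_forward(
    m$params, matrix((va$variance - m$standardization[["mean"]]) /
                       m$standardization[["sd"]], ncol = 1))$output
  mae <- mean(abs(pred - cbind(va$rfu_back, va$rfu_fwd)))
  expect_lt(mae, 0.05)
  expect_equal(nrow(tidy(m)), 400)
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("predicted controls are valid and identical inputs map identically", {
  d <- functional_training_set(200, seed = 105)
  m <- train_mlp(dplyr::filter(d, protein == "trainA"),
                 dplyr::filter(d, protein == "trainB"),
                 mlp_spec(hidden = c(16, 8), epochs = 200, seed = 9))
  u <- tiny_uptake()
  u2 <- dplyr::bind_rows(u, dplyr::mutate(u[1:3, ], peptide = "GSTR",
                                          start = 7L, end = 10L))
  ctl <- predict_controls(m, u2)
  expect_silent(validate_controls(ctl))
  expect_identical(unique(ctl$provenance), "predicted_ai")
  # peptides 1 and 3 share a time course -> identical predictions
  expect_equal(unlist(ctl[ctl$peptide == "AKLV", c("rfu_back", "rfu_fwd")]),
               unlist(ctl[ctl$peptide == "GSTR", c("rfu_back", "rfu_fwd")]))
})

test_that("an oracle model restores corrupted data exactly", {
  u <- tiny_uptake()
  oracle <- constant_control_model(back = 0.8, fwd = 0.1)
  ctl <- tiny_controls(back = c(0.8, 0.8), fwd = c(0.1, 0.1))
  corrupted <- apply_controls(u, ctl, "corrupt")
  fixed <- correct_with_model(corrupted, oracle)
  expect_equal(fixed$rfu, u$rfu, tolerance = 1e-12)
  expect_equal(peptide_map(fixed), peptide_map(u), ignore_attr = TRUE)
})

test_that("model correction halves the corruption error end to end", {
  sys <- make_system(n_res = 60, n_pep = 30, seed = 106)
  bl <- sample_control_library(2000, "back", seed = 107)
  fl <- sample_control_library(2000, "fwd", seed = 108)
  ctl <- assign_controls(sys$map, bl, fl, seed = 109)
  corrupted <- apply_controls(sys$uptake, ctl, "corrupt")
  rmse_corrupted <- uptake_rmse(corrupted, sys$uptake)

  # train on two other synthetic proteins with their own sampled controls
  train_sets <- purrr::map(1:2, function(i) {
    s <- make_system(n_res = 60, n_pep = 40, seed = 110 + i)
    cc <- assign_controls(s$map, bl, fl, seed = 120 + i)
    control_training_set(apply_controls(s$uptake, cc, "corrupt"), cc) |>
      dplyr::mutate(protein = paste0("train_", i))
  })
  m <- train_mlp(dplyr::bind_rows(train_sets[[1]]),
                 dplyr::mutate(train_sets[[2]], protein = "val"),
                 mlp_spec(epochs = 300, seed = 130, learning_rate = 0.02))
  fixed <- correct_with_model(corrupted, m)
  rmse_fixed <- uptake_rmse(fixed, sys$uptake)
  expect_gt(rmse_corrupted, rmse_fixed)
  expect_lt(rmse_fixed, 0.5 * rmse_corrupted)
})
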