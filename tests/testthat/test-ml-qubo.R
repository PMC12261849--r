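test_that("initialisation is seeded, member-distinct and shape-correct", {
  cfg <- mlTrainConfig(ensembleSize = 5, seed = 3)
  m1 <- mlQuboModel(5, cfg)
  m2 <- mlQuboModel(5, cfg)
  expect_equal(length(mlMembers(m1)), 5)
  expect_true(all(vapply(mlMembers(m1), function(q)
    all(dim(q) == c(5, 5)), logical(1))))
  expect_identical(mlMembers(m1), mlMembers(m2))
  expect_false(identical(mlMembers(m1)[[1]], mlMembers(m1)[[2]]))
  expect_error(mlQuboModel(0), ">= 1")
})

test_that("prediction is the denormalised ensemble-mean bilinear form", {
  cfg <- mlTrainConfig(ensembleSize = 1, seed = 1)
  m <- mlQuboModel(3, cfg)
  m@members[[1]] <- matrix(0, 3, 3)
  m@targetMean <- 0.42; m@targetStd <- 2
  expect_equal(unname(predict(m, c(1, 0, 1))), 0.42)
  # single set bit collapses to the diagonal entry
  Q <- matrix(0, 3, 3); Q[2, 2] <- 0.5
  m@members[[1]] <- Q
  expect_equal(unname(predict(m, c(0, 1, 0))), 0.5 * 2 + 0.42)
  # ensemble of identical members equals a single member
  m2 <- m; m2@members <- list(Q, Q, Q)
  expect_equal(predict(m2, diag(3)), predict(m, diag(3)))
  expect_error(predict(m, c(1, 0)), "dimension")
})

test_that("triangular export preserves the bilinear form for all assignments", {
  cfg <- mlTrainConfig(ensembleSize = 1, seed = 2)
  m <- mlQuboModel(2, cfg)
  m@members[[1]] <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-wise
  tri <- exportTriangular(m, member = 1)
  tt <- quboTerms(tri)
  expect_equal(tt$value[tt$i == 1 & tt$j == 1], 1)
  expect_equal(tt$value[tt$i == 1 & tt$j == 2], 5)
  expect_equal(tt$value[tt$i == 2 & tt$j == 2], 4)
  # enumeration oracle on a random member
  mR <- mlQuboModel(4, mlTrainConfig(ensembleSize = 1, seed = 8))
  Q <- matrix(rnorm(16), 4, 4)
  mR@members[[1]] <- Q
  triR <- exportTriangular(mR, member = 1)
  for (s in 0:15) {
    x <- stateBits(s, 4)[1, ]
    expect_equal(quboEnergy(triR, x), drop(t(x) %*% Q %*% x))
  }
  # zero member exports an empty-term matrix
  mZ <- m; mZ@members[[1]] <- matrix(0, 2, 2)
  expect_equal(nrow(quboTerms(exportTriangular(mZ, member = 1))), 0L)
})

test_that("training recovers a planted one-hot quadratic surface", {
  spec <- unclippedGridSpec(c(ligand = 5, base = 4, additive = 5), seed = 13)
  g <- generateGrid(spec)
  expect_true(all(g$data$yield > 0 & g$data$yield < 1))  # clip inactive
  enc <- encodeConditionTable(g$data, names(spec$slots))
  cfg <- mlTrainConfig(epochs = 1200, learningRate = 0.01, lrDecay = 1e-3,
                       ensembleSize = 1, seed = 5)
  m <- trainMlQubo(mlQuboModel(ncol(enc$features), cfg),
                   enc$features, g$data$yield, segments = enc$segments)
  h <- mlHistory(m)
  sdy <- sd(g$data$yield)
  # noiseless, in-class surface: training error collapses well below 1% of
  # the target spread
  expect_lt(tail(h$train, 1), 0.01)
  # denormalisation inverts normalisation: training inputs reproduce targets
  expect_lt(mean(abs(predict(m, enc$features) - g$data$yield)), 0.01 * sdy)
})

test_that("checkpoint selection returns the best-validation epoch", {
  spec <- unclippedGridSpec(c(a = 4, b = 3), seed = 17, sigma = 0.05)
  g <- generateGrid(spec)
  enc <- encodeConditionTable(g$data, names(spec$slots))
  cfg <- mlTrainConfig(epochs = 150, learningRate = 0.01, ensembleSize = 2,
                       seed = 6)
  m <- trainMlQubo(mlQuboModel(ncol(enc$features), cfg),
                   enc$features, g$data$yield)
  h <- mlHistory(m)
  for (mem in unique(h$member)) {
    hm <- h[h$member == mem, ]
    expect_lte(min(hm$validation), tail(hm$validation, 1))
  }
})

test_that("constant targets engage the std floor and predict the constant", {
  X <- matrix(rbinom(60, 1, 0.5), 20, 3)
  cfg <- mlTrainConfig(epochs = 50, ensembleSize = 1, seed = 4)
  m <- trainMlQubo(mlQuboModel(3, cfg), X, rep(0.37, 20))
  expect_equal(m@targetStd, 1)
  expect_equal(unname(predict(m, X)), rep(0.37, 20), tolerance = 0.02)
})

test_that("model JSON round-trips predictions exactly", {
  spec <- unclippedGridSpec(c(a = 3, b = 3), seed = 23)
  g <- generateGrid(spec)
  enc <- encodeConditionTable(g$data, names(spec$slots))
  cfg <- mlTrainConfig(epochs = 30, ensembleSize = 2, seed = 2)
  m <- trainMlQubo(mlQuboModel(ncol(enc$features), cfg),
                   enc$features, g$data$yield, segments = enc$segments)
  f <- tempfile(fileext = ".json")
  writeMlModel(m, f)
  m2 <- readMlModel(f)
  expect_equal(predict(m2, enc$features), predict(m, enc$features))
})
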