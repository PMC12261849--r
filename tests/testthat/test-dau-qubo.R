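test_that("coefficient codes decode per the signed base-2 convention", {
  b <- integer(10); b[c(7, 9)] <- 1L          # bits 6 and 8
  expect_equal(decodeCoefficient(b), -192)    # 2^6 + 2^8 - 512
  b2 <- integer(10); b2[c(9, 10)] <- 1L       # bits 8 and 9
  expect_equal(decodeCoefficient(b2), 256)
  b3 <- integer(10); b3[c(5, 10)] <- 1L       # bits 4 and 9
  expect_equal(decodeCoefficient(b3), 16)
  expect_equal(decodeCoefficient(integer(10)), -512)
  expect_equal(decodeCoefficient(rep(1L, 10)), 511)
  expect_error(decodeCoefficient(integer(8)), "expected 10 bits")
  # encode/decode round trip on a sample of the range
  for (v in c(-512, -200, -1, 0, 1, 255, 511))
    expect_equal(decodeCoefficient(encodeCoefficient(v)), v)
})

test_that("term enumeration counts singletons and observed pairs only", {
  d1 <- data.frame(substrate = "s1", additive = "a1")
  t1 <- enumerateTerms(d1, c("substrate", "additive"))
  expect_equal(nrow(termTable(t1)), 3)
  expect_equal(termBits(t1), 30)
  d2 <- data.frame(substrate = c("s1", "s1", "s2", "s2"),
                   additive = c("a1", "a2", "a1", "a2"))
  t2 <- enumerateTerms(d2, c("substrate", "additive"))
  expect_equal(nrow(termTable(t2)), 8)
  expect_equal(termBits(t2), 80)
  d3 <- d2[c(1, 4), ]  # only two combinations observed
  t3 <- enumerateTerms(d3, c("substrate", "additive"))
  expect_equal(nrow(termTable(t3)), 6)
  expect_error(enumerateTerms(d1[0, ], "substrate"), "empty")
})

test_that("the 2-bit toy least-squares QUBO has its minimum at the exact fit", {
  d <- data.frame(slot = "v1")
  tab <- enumerateTerms(d, "slot", width = 2)   # weights 1, 2, offset -2
  built <- buildLsqQubo(d, yields = 1, table = tab, scale = 1)
  sol <- bruteForceMinimize(built$qubo)
  expect_equal(sol$bits, c(1L, 1L))             # decodes to 1 + 2 - 2 = 1
  expect_equal(sol$energy + built$constant, 0)
  expect_error(buildLsqQubo(d[0, , drop = FALSE], numeric(0), tab), "empty")
})

test_that("QUBO energy plus constant equals the directly computed SSE", {
  set.seed(91)
  for (rep_ in 1:12) {
    width <- sample(2:4, 1)
    nv <- sample(2:3, 1)
    d <- data.frame(s = paste0("u", sample(nv, 4, replace = TRUE)),
                    t = paste0("w", sample(2, 4, replace = TRUE)))
    tab <- enumerateTerms(d, c("s", "t"), width = width)
    if (termBits(tab) > 16) next
    y <- round(runif(4), 3)
    built <- buildLsqQubo(d, y, tab, scale = 10)
    e <- quboStateEnergies(built$qubo)
    for (st in sample(0:(2^termBits(tab) - 1), 25)) {
      bits <- stateBits(st, termBits(tab))[1, ]
      expect_equal(e[st + 1] + built$constant,
                   directSSE(bits, d, y, tab, scale = 10))
    }
  }
})

test_that("exact fitting recovers planted integer coefficients", {
  d <- data.frame(solvent = rep(c("v1", "v2"), each = 3))
  y <- rep(c(0.120, 0.350), each = 3)          # planted 120 and 350 permille
  tab <- enumerateTerms(d, "solvent")
  m <- fitDau(d, y, tab)                        # 20 bits: exact solver
  expect_equal(m@sse, 0)
  expect_equal(unname(dauCoefficients(m)), c(120, 350))
  # annealer reaches the same fit
  mA <- fitDau(d, y, tab, exact = FALSE, seed = 4, sweeps = 3000,
               restarts = 10)
  expect_equal(mA@coefficients, m@coefficients)
  # determinism
  mA2 <- fitDau(d, y, tab, exact = FALSE, seed = 4, sweeps = 3000,
                restarts = 10)
  expect_identical(mA@coefficients, mA2@coefficients)
})

test_that("prediction sums singleton and table-present pair contributions", {
  tt <- data.frame(kind = c("single", "single", "pair"),
                   slotA = c("substrate", "additive", "substrate"),
                   valueA = c("s1", "a1", "s1"),
                   slotB = c(NA, NA, "additive"),
                   valueB = c(NA, NA, "a1"),
                   start = c(1L, 11L, 21L), stringsAsFactors = FALSE)
  tab <- new("TermTable", terms = tt, width = 10L,
             slotNames = c("substrate", "additive"))
  m <- new("DauModel", table = tab, coefficients = c(-192, 256, 16),
           sse = 0, scale = 1000)
  expect_equal(dauPredict(m, c(substrate = "s1", additive = "a1")), 80)
  expect_equal(dauPredict(m, c(substrate = "s1", additive = "a1"),
                          unit = "fraction"), 0.08)
  expect_error(dauPredict(m, c(substrate = "s9", additive = "a1")),
               "unknown value")
  # a pair absent from the table contributes zero, with a warning
  tabNoPair <- new("TermTable", terms = tt[1:2, ], width = 10L,
                   slotNames = c("substrate", "additive"))
  mNoPair <- new("DauModel", table = tabNoPair, coefficients = c(-192, 256),
                 sse = 0, scale = 1000)
  expect_warning(p <- dauPredict(mNoPair, c(substrate = "s1",
                                            additive = "a1")), "unobserved")
  expect_equal(p, 64)
  # single-term model reports raw negative predictions
  tab1 <- new("TermTable", terms = tt[1, ], width = 10L,
              slotNames = "substrate")
  m1 <- new("DauModel", table = tab1, coefficients = -512, sse = 0,
            scale = 1000)
  expect_equal(dauPredict(m1, c(substrate = "s1")), -512)
})

test_that("the fitted model assembles into the expected Q matrix", {
  tt <- data.frame(kind = c("single", "single", "pair"),
                   slotA = c("substrate", "additive", "substrate"),
                   valueA = c("s1", "a1", "s1"),
                   slotB = c(NA, NA, "additive"),
                   valueB = c(NA, NA, "a1"),
                   start = c(1L, 11L, 21L), stringsAsFactors = FALSE)
  tab <- new("TermTable", terms = tt, width = 10L,
             slotNames = c("substrate", "additive"))
  m <- new("DauModel", table = tab, coefficients = c(-192, 256, 16),
           sse = 0, scale = 1000)
  q <- dauToQmatrix(m)
  expect_equal(unname(symmetricMatrix(q)),
               matrix(c(-192, 16, 16, 256), 2, 2))
  # energy at the all-active assignment equals the prediction
  expect_equal(quboEnergy(q, c(1, 1)),
               dauPredict(m, c(substrate = "s1", additive = "a1")))
  # empty pair set: diagonal-only matrix
  tabNoPair <- new("TermTable", terms = tt[1:2, ], width = 10L,
                   slotNames = c("substrate", "additive"))
  mNoPair <- new("DauModel", table = tabNoPair, coefficients = c(-192, 256),
                 sse = 0, scale = 1000)
  qq <- dauToQmatrix(mNoPair)
  expect_true(all(quboTerms(qq)$i == quboTerms(qq)$j))
})

test_that("DauModel JSON round-trips predictions", {
  d <- data.frame(s = c("u1", "u1", "u2", "u2"), t = c("w1", "w2", "w1", "w2"))
  m <- fitDau(d, c(0.1, 0.2, 0.3, 0.4), enumerateTerms(d, c("s", "t")),
              exact = FALSE, seed = 2, sweeps = 1500, restarts = 8)
  f <- tempfile(fileext = ".json")
  writeDauModel(m, f)
  m2 <- readDauModel(f)
  expect_equal(dauPredict(m2, c(s = "u1", t = "w2")),
               dauPredict(m, c(s = "u1", t = "w2")))
  expect_equal(m2@sse, m@sse)
})
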