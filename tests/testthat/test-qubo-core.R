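test_that("triangular energy counts each pair coefficient once", {
  q <- QuboMatrix(2, c(1, 1, 2), c(1, 2, 2), c(-192, 16, 256))
  expect_equal(quboEnergy(q, c(0, 0)), 0)
  expect_equal(quboEnergy(q, c(1, 1)), 80)   # -192 + 256 + 16
  expect_equal(quboEnergy(q, c(1, 0)), -192)
  expect_equal(quboEnergy(QuboMatrix(3, offset = 4.5), c(0, 0, 0)), 4.5)
  expect_error(quboEnergy(q, c(1, 0, 0)), "length")
})

test_that("brute force enumerates exactly and breaks ties lexicographically", {
  q <- QuboMatrix(2, c(1, 1, 2), c(1, 2, 2), c(-192, 16, 256))
  sol <- bruteForceMinimize(q)
  expect_equal(sol$bits, c(1L, 0L))
  expect_equal(sol$energy, -192)
  expect_equal(sort(quboStateEnergies(q)), c(-192, 0, 80, 256))
  # all-positive diagonal, no couplings: all-zero optimum
  qd <- QuboMatrix(4, 1:4, 1:4, c(2, 1, 5, 3), offset = 7)
  expect_equal(bruteForceMinimize(qd)$bits, rep(0L, 4))
  expect_equal(bruteForceMinimize(qd)$energy, 7)
  # feasibility filter: at least one set bit
  solF <- bruteForceMinimize(q, filter = function(b) sum(b) >= 1)
  expect_equal(solF$bits, c(1L, 0L))
  # degenerate ties: zero matrix -> lexicographically smallest is all-zero
  expect_equal(bruteForceMinimize(QuboMatrix(3))$bits, rep(0L, 3))
  expect_error(bruteForceMinimize(QuboMatrix(30)), "cap")
})

test_that("annealer agrees with the exact oracle on small instances", {
  ok <- 0
  for (s in 1:100) {
    q <- randomQubo(10, seed = s)
    bf <- bruteForceMinimize(q)
    an <- annealQubo(q, sweeps = 500, restarts = 5, seed = s)[[1]]
    expect_gte(an$energy, bf$energy - 1e-9)
    if (abs(an$energy - bf$energy) < 1e-9) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("annealer is deterministic and returns distinct sorted solutions", {
  q <- randomQubo(12, seed = 5)
  a <- annealQubo(q, sweeps = 300, restarts = 4, seed = 9, topM = 3)
  b <- annealQubo(q, sweeps = 300, restarts = 4, seed = 9, topM = 3)
  expect_identical(a, b)
  expect_equal(length(a), 3)
  keys <- vapply(a, function(s) paste(s$bits, collapse = ""), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  en <- vapply(a, `[[`, numeric(1), "energy")
  expect_true(all(diff(en) >= 0))
  # reported energies satisfy the Solution invariant
  for (s in a) expect_equal(s$energy, quboEnergy(q, s$bits))
})

test_that("exactly-one penalty vanishes on feasible assignments only", {
  p <- addPenalty(QuboMatrix(3), "exactly_one", 1:3, lambda = 10)
  expect_equal(quboEnergy(p, c(1, 0, 0)), 0)
  expect_equal(quboEnergy(p, c(1, 1, 0)), 10)
  expect_equal(quboEnergy(p, c(0, 0, 0)), 10)
  expect_equal(quboEnergy(p, c(1, 1, 1)), 40)
})

test_that("cardinality penalties with slack bits are sound", {
  # at_most_k: every assignment with <= k set bits reaches penalty 0 for
  # some slack setting; > k set bits cannot
  p <- addPenalty(QuboMatrix(4), "at_most_k", 1:4, k = 2, lambda = 5)
  e <- quboStateEnergies(p)
  nSlack <- quboDim(p) - 4
  for (s in 0:(2^4 - 1)) {
    bits <- stateBits(s, 4)[1, ]
    minOver <- min(vapply(0:(2^nSlack - 1), function(sl) {
      full <- c(bits, stateBits(sl, nSlack)[1, ])
      quboEnergy(p, full)
    }, numeric(1)))
    if (sum(bits) <= 2) expect_equal(minOver, 0) else expect_gt(minOver, 0)
  }
  # at_least_one
  p2 <- addPenalty(QuboMatrix(3), "at_least_one", 1:3, lambda = 3)
  nS2 <- quboDim(p2) - 3
  for (s in 0:7) {
    bits <- stateBits(s, 3)[1, ]
    minOver <- min(vapply(0:(2^nS2 - 1), function(sl)
      quboEnergy(p2, c(bits, stateBits(sl, nS2)[1, ])), numeric(1)))
    if (sum(bits) >= 1) expect_equal(minOver, 0) else expect_gt(minOver, 0)
  }
})

test_that("penalised minima are feasible once lambda dominates the span", {
  for (s in 1:10) {
    q <- randomQubo(6, seed = 100 + s)
    e <- quboStateEnergies(q)
    lam <- (max(e) - min(e)) + 1
    p <- addPenalty(q, "exactly_one", 1:6, lambda = lam)
    sol <- bruteForceMinimize(p)
    expect_equal(sum(sol$bits[1:6]), 1)
  }
})

test_that("conditional reduction preserves energies exactly", {
  # worked example: fix x1 = -1 (coefficients verified by enumeration)
  q <- QuboMatrix(3, c(1, 1, 1, 2, 2, 3), c(1, 2, 3, 2, 3, 3),
                  c(2, 3, -1, 4, 5, -2))
  red <- reduceConditional(q, c(-1, NA, NA))
  expect_equal(red$offsetDelta, 2)
  tt <- quboTerms(red$qubo)
  expect_equal(tt$value[tt$i == 1 & tt$j == 1], 1)   # 4 + (-1)*3
  expect_equal(tt$value[tt$i == 1 & tt$j == 2], 5)
  expect_equal(tt$value[tt$i == 2 & tt$j == 2], -1)  # -2 + (-1)*(-1)
  for (x1 in 0:1) for (x2 in 0:1)
    expect_equal(quboEnergy(red$qubo, c(x1, x2)) + red$offsetDelta,
                 quboEnergy(q, c(-1, x1, x2)))
  # fix everything / fix nothing
  all_ <- reduceConditional(q, c(1, 0, 1))
  expect_equal(quboDim(all_$qubo), 0L)
  expect_equal(all_$offsetDelta, quboEnergy(q, c(1, 0, 1)))
  none <- reduceConditional(q, rep(NA_real_, 3))
  expect_equal(quboTerms(none$qubo), quboTerms(q))
  expect_equal(none$offsetDelta, 0)
  expect_error(reduceConditional(q, c(2, NA, NA)), "fixed values")
})

test_that("reduction exactness holds for random matrices and ternary fixings", {
  set.seed(11)
  for (rep_ in 1:20) {
    n <- sample(4:8, 1)
    q <- randomQubo(n, seed = 200 + rep_)
    fixed <- rep(NA_real_, n)
    nf <- sample(0:n, 1)
    if (nf > 0) fixed[sample(n, nf)] <- sample(c(-1, 0, 1), nf, replace = TRUE)
    red <- reduceConditional(q, fixed)
    nFree <- sum(is.na(fixed))
    for (s in 0:(2^nFree - 1)) {
      xf <- if (nFree) stateBits(s, nFree)[1, ] else integer(0)
      merged <- fixed
      merged[is.na(fixed)] <- xf
      expect_equal(quboEnergy(red$qubo, xf) + red$offsetDelta,
                   quboEnergy(q, merged))
      if (s > 2) break  # a few assignments per fixing suffice
    }
  }
})

test_that("energy is invariant under consistent variable relabeling", {
  q <- randomQubo(7, seed = 31)
  set.seed(32)
  perm <- sample(7)
  qp <- QuboMatrix(7, perm[q@i], perm[q@j], q@v, offset = quboOffset(q))
  for (s in c(0, 17, 93, 127)) {
    x <- stateBits(s, 7)[1, ]
    xp <- integer(7); xp[perm] <- x
    expect_equal(quboEnergy(q, x), quboEnergy(qp, xp))
  }
})

test_that("symmetric display duplicates off-diagonals without halving", {
  q <- QuboMatrix(2, c(1, 1, 2), c(1, 2, 2), c(-192, 16, 256))
  expect_equal(symmetricMatrix(q),
               matrix(c(-192, 16, 16, 256), 2, 2))
})

test_that("JSON round trip is bit-exact", {
  q <- randomQubo(9, seed = 77)
  q2 <- QuboMatrix(quboDim(q), q@i, q@j, q@v, offset = quboOffset(q),
                   labels = paste0("v", 1:9))
  f <- tempfile(fileext = ".json")
  writeQubo(q2, f)
  r <- readQubo(f)
  expect_identical(quboTerms(r), quboTerms(q2))
  expect_identical(quboOffset(r), quboOffset(q2))
  expect_identical(quboLabels(r), quboLabels(q2))
})
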