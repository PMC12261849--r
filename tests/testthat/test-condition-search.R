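test_that("condition-space counting follows the binomial product formula", {
  big <- conditionSpace(
    list(reagent = paste0("rg", 1:111), solvent = paste0("sv", 1:24)),
    bounds = list(reagent = c(1, 4), solvent = c(0, 2)))
  # (C(111,1)+C(111,2)+C(111,3)+C(111,4)) * (C(24,0)+C(24,1)+C(24,2))
  expect_equal(countSpace(big), 1871327836)
  small <- conditionSpace(list(r = c("a", "b"), s = "w"),
                          bounds = list(r = c(1, 2), s = c(0, 1)))
  expect_equal(countSpace(small), 6)
  expect_equal(countSpace(conditionSpace(list(r = "a"))), 1)
  expect_error(conditionSpace(list(r = "a"), bounds = list(r = c(1, 5))),
               "exceed")
})

test_that("counting equals explicit enumeration for small vocabularies", {
  for (s in 1:5) {
    set.seed(s)
    sp <- conditionSpace(
      list(a = paste0("a", 1:sample(2:5, 1)), b = paste0("b", 1:sample(2:4, 1))),
      bounds = list(a = c(1, sample(1:2, 1)), b = c(0, 1)))
    expect_equal(nrow(enumerateConditions(sp)), countSpace(sp))
    # and every enumerated row is feasible
    feas <- apply(enumerateConditions(sp), 1, quboyield:::.checkFeasible,
                  space = sp)
    expect_true(all(feas))
  }
})

test_that("search-QUBO minimum matches the enumeration argmax of yield", {
  set.seed(21)
  sp <- conditionSpace(
    list(reagent = paste0("rg", 1:4), solvent = paste0("sv", 1:2)),
    bounds = list(reagent = c(1, 4), solvent = c(0, 2)))
  qc <- randomQubo(sp$n, seed = 33)
  qs <- buildSearchQubo(qc, sp)
  sol <- bruteForceMinimize(qs)
  condBits <- sol$bits[seq_len(sp$n)]
  all_ <- enumerateConditions(sp)
  yields <- apply(all_, 1, function(b) quboEnergy(qc, b))
  expect_equal(condBits, unname(all_[which.max(yields), ]))
  # the empty selection violates the reagent minimum and is penalised
  nSlack <- quboDim(qs) - sp$n
  expect_gt(quboEnergy(qs, rep(0, quboDim(qs))), 0)
  # a dominated lambda triggers a warning
  expect_warning(buildSearchQubo(qc, sp, lambda = 1e-6), "span")
})

test_that("top-k search equals exhaustive prediction ranking (exact path)", {
  sp <- conditionSpace(list(ligand = paste0("L", 1:4),
                            base = paste0("B", 1:3),
                            additive = paste0("A", 1:4)))
  qc <- randomQubo(sp$n, seed = 55)
  res <- searchTopK(qc, sp, k = 3, scale = 0.01, shift = 0.2)
  all_ <- enumerateConditions(sp)
  yields <- apply(all_, 1, function(b) 0.01 * quboEnergy(qc, b) + 0.2)
  ord <- order(-yields)
  expect_equal(res$yield, yields[ord[1:3]])
  expect_equal(unname(attr(res, "bits")),
               unname(all_[ord[1:3], , drop = FALSE]))
  # k larger than the feasible space returns everything, ranked
  resAll <- searchTopK(qc, sp, k = 999)
  expect_equal(nrow(resAll), countSpace(sp))
  expect_true(all(diff(resAll$yield) <= 0))
})

test_that("annealer-solved search agrees with the exact path and is seeded", {
  sp <- conditionSpace(list(ligand = paste0("L", 1:4),
                            base = paste0("B", 1:3)))
  qc <- randomQubo(sp$n, seed = 71)
  ex <- searchTopK(qc, sp, k = 3, solver = "exact")
  an <- searchTopK(qc, sp, k = 3, solver = "anneal", seed = 5,
                   sweeps = 2000, restarts = 10)
  expect_equal(an$assignment, ex$assignment)
  expect_equal(an$yield, ex$yield)
  an2 <- searchTopK(qc, sp, k = 3, solver = "anneal", seed = 5,
                    sweeps = 2000, restarts = 10)
  expect_identical(an, an2)
})

test_that("random baseline samples feasibly, deterministically, and is beaten
           by the exact search optimum", {
  sp <- conditionSpace(
    list(reagent = paste0("rg", 1:5), solvent = paste0("sv", 1:3)),
    bounds = list(reagent = c(1, 3), solvent = c(0, 2)))
  qc <- randomQubo(sp$n, seed = 12)
  rb <- randomBaseline(qc, sp, nSamples = 200, seed = 3)
  expect_equal(length(rb$yields), 200)
  rb2 <- randomBaseline(qc, sp, nSamples = 200, seed = 3)
  expect_identical(rb$yields, rb2$yields)
  # single sample is its own best
  rb1 <- randomBaseline(qc, sp, nSamples = 1, seed = 9)
  expect_equal(rb1$bestYield, rb1$yields[1])
  # exact top-1 dominates every sampled point
  top <- searchTopK(qc, sp, k = 1)
  expect_gte(top$yield[1], rb$bestYield)
})
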