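test_that("packaged fixtures reproduce the published parameter values", {
  expect_equal(set1[c("kCa_plus", "kCa_minus", "kSP_plus", "kSP_minus",
                      "kIP_plus", "kIP_minus", "kMD_plus", "kMD_minus",
                      "kref_BC", "K_BC", "f_XY", "delta", "lam", "eta",
                      "mu", "gamma")],
               list(kCa_plus = 350, kCa_minus = 1000, kSP_plus = 180,
                    kSP_minus = 292, kIP_plus = 700, kIP_minus = 225,
                    kMD_plus = 590, kMD_minus = 225, kref_BC = 675,
                    K_BC = 2.3, f_XY = 225, delta = 0.48, lam = 0.008,
                    eta = 9, mu = 9, gamma = 3570))
  expect_equal(set2[c("kCa_plus", "kCa_minus", "kSP_plus", "kSP_minus",
                      "kIP_plus", "kIP_minus", "kMD_plus", "kMD_minus",
                      "kref_BC", "K_BC", "f_XY", "delta", "lam", "eta",
                      "mu", "gamma")],
               list(kCa_plus = 310, kCa_minus = 1800, kSP_plus = 225,
                    kSP_minus = 350, kIP_plus = 1900, kIP_minus = 225,
                    kMD_plus = 1650, kMD_minus = 225, kref_BC = 875,
                    K_BC = 2.0, f_XY = 25, delta = 0.4, lam = 0.0001,
                    eta = 18, mu = 18, gamma = 2550))
  expect_identical(set1$n_units, 26L)
})

test_that("parameter validation rejects out-of-range values", {
  bad <- function(field, value) {
    p <- unclass(set1)
    p[[field]] <- value
    do.call(param_set, p[setdiff(names(p), character(0))])
  }
  expect_error(bad("kCa_plus", -1), "kCa_plus")
  expect_error(bad("K_BC", 0), "K_BC")
  expect_error(bad("delta", 1.2), "delta")
  expect_error(bad("lam", 0), "lam")
  expect_error(bad("eta", 0.5), "eta")
  expect_error(bad("n_units", 0), "n_units")
})

test_that("mutation scaling interpolates linearly with expression", {
  # identity at zero expression
  expect_equal(apply_mutation(set1, mutation_spec(0.5, 0.74, 0)),
               set1)
  # full expression reproduces the published mutant K_BC of ~1.70
  m <- apply_mutation(set1, mutation_spec(0.5, 0.74, 1))
  expect_equal(m$K_BC, 2.3 * 0.74)
  expect_equal(round(m$K_BC, 2), 1.70)
  expect_equal(m$gamma, 3570 * 0.5)
  # linear midpoint
  h <- apply_mutation(set1, mutation_spec(0.5, 0.74, 0.5))
  expect_equal(h$gamma, 3570 * 0.75)
  expect_equal(h$K_BC, 2.3 * 0.87)
  # all other fields untouched
  other <- setdiff(names(set1), c("gamma", "K_BC"))
  expect_identical(m[other], set1[other])
})

test_that("mutation scaling is continuous and monotone in expression", {
  es <- seq(0, 1, by = 0.05)
  gs <- vapply(es, function(e)
    apply_mutation(set1, mutation_spec(0.5, 0.74, e))$gamma, numeric(1))
  ks <- vapply(es, function(e)
    apply_mutation(set1, mutation_spec(0.5, 0.74, e))$K_BC, numeric(1))
  expect_true(all(diff(gs) < 0))
  expect_true(all(diff(ks) < 0))
  # exactly linear in expression
  expect_equal(gs, 3570 * (1 - 0.5 * es))
  expect_equal(ks, 2.3 * (1 - 0.26 * es))
})

test_that("invalid mutation specs are rejected", {
  expect_error(mutation_spec(expression = 1.5), "expression")
  expect_error(mutation_spec(expression = -0.1), "expression")
  expect_error(mutation_spec(gamma_scale = 0), "gamma_scale")
  expect_error(mutation_spec(kbc_scale = -1), "kbc_scale")
})
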