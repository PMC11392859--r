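# Neighbor configurations used in property loops: all pairs of
# {B, C, M, chain end}
NBR_CONFIGS <- expand.grid(left = c("B", "C", "M", NA),
                           right = c("B", "C", "M", NA),
                           stringsAsFactors = FALSE)

test_that("the B-to-C rate matches its closed-form value", {
  # switched-and-released troponin (sp docked, ip off), no neighbors:
  # the bare forward rate 675 * 2.3^0.48
  b <- ru_state(0, 1, 0, "B")
  cc <- ru_state(0, 1, 0, "C")
  expect_equal(transition_rate(b, cc, set1, ca = 0.1), 675 * 2.3^0.48,
               tolerance = 1e-12)
  expect_equal(transition_rate(b, cc, set1, ca = 0.1), 1006.777,
               tolerance = 1e-4)
})

test_that("only single-component transitions have nonzero rate", {
  for (from in ALL_STATES) {
    f <- as.list(ru_states()[from, ])
    for (to in ALL_STATES) {
      if (to == from) next
      t <- as.list(ru_states()[to, ])
      ndiff <- (f$ca != t$ca) + (f$sp != t$sp) + (f$ip != t$ip) +
        (f$tpm != t$tpm)
      r <- transition_rate(from, to, set1, ca = 1, left = "C", right = "M")
      if (ndiff > 1L) {
        expect_identical(r, 0)
      } else if (f$tpm != t$tpm && abs(f$x - t$x) == 2L) {
        expect_identical(r, 0)  # direct B<->M jump forbidden
      } else {
        expect_gt(r, 0)
      }
    }
  }
})

test_that("B/C rate ratio follows K_BC times the coupling imbalance", {
  b <- ru_state(0, 1, 0, "B")
  cc <- ru_state(0, 1, 0, "C")
  g <- set1$gamma / set1$rt
  x_of <- function(v) if (is.na(v)) NULL else match(v, c("B", "C", "M")) - 1
  for (k in seq_len(nrow(NBR_CONFIGS))) {
    nbr <- c(x_of(NBR_CONFIGS$left[k]), x_of(NBR_CONFIGS$right[k]))
    d <- sum(abs(1 - nbr)) - sum(abs(0 - nbr))  # B->C distance change
    fwd <- transition_rate(b, cc, set1, 1, NBR_CONFIGS$left[k],
                           NBR_CONFIGS$right[k])
    bwd <- transition_rate(cc, b, set1, 1, NBR_CONFIGS$left[k],
                           NBR_CONFIGS$right[k])
    expect_equal(fwd / bwd, set1$K_BC * exp(-2 * g * d), tolerance = 1e-12)
  }
  # the ratio is exactly K_BC wherever the coupling terms cancel
  for (nb in list(c(NA, NA), c("B", "C"), c("C", "B"), c("B", "M"),
                  c("M", "B"))) {
    fwd <- transition_rate(b, cc, set1, 1, nb[1], nb[2])
    bwd <- transition_rate(cc, b, set1, 1, nb[1], nb[2])
    expect_equal(fwd / bwd, set1$K_BC, tolerance = 1e-12)
  }
})

test_that("troponin gates both forward shifts by lam", {
  # full rate only when the switch peptide is docked and the inhibitory
  # peptide is off actin; every other troponin configuration carries lam
  for (p in list(set1, set2)) {
    bc_open <- transition_rate(ru_state(0, 1, 0, "B"), ru_state(0, 1, 0, "C"),
                               p, 1)
    cm_open <- transition_rate(ru_state(0, 1, 0, "C"), ru_state(0, 1, 0, "M"),
                               p, 1)
    for (cfg in list(c(0, 0), c(0, 1), c(1, 1))) {
      bc <- transition_rate(ru_state(0, cfg[1], cfg[2], "B"),
                            ru_state(0, cfg[1], cfg[2], "C"), p, 1)
      cm <- transition_rate(ru_state(0, cfg[1], cfg[2], "C"),
                            ru_state(0, cfg[1], cfg[2], "M"), p, 1)
      expect_equal(bc / bc_open, p$lam, tolerance = 1e-12)
      expect_equal(cm / cm_open, p$lam, tolerance = 1e-12)
    }
    # reverse shifts are not gated
    expect_equal(
      transition_rate(ru_state(0, 0, 1, "C"), ru_state(0, 0, 1, "B"), p, 1),
      transition_rate(ru_state(0, 1, 0, "C"), ru_state(0, 1, 0, "B"), p, 1))
  }
})

test_that("M-state neighbors promote opening and retard closing", {
  cc <- ru_state(1, 1, 0, "C")
  m <- ru_state(1, 1, 0, "M")
  g <- set1$gamma / set1$rt
  for (n_m in 0:2) {
    nbrs <- list(c(NA, NA), c("M", "B"), c("M", "M"))[[n_m + 1L]]
    expect_equal(transition_rate(cc, m, set1, 1, nbrs[1], nbrs[2]),
                 set1$kMD_plus + set1$f_XY * n_m, tolerance = 1e-12)
    expect_equal(transition_rate(m, cc, set1, 1, nbrs[1], nbrs[2]),
                 set1$kMD_minus * exp(-g * n_m), tolerance = 1e-12)
  }
  # zero chain stiffness removes every neighbor coupling factor
  p0 <- set1
  p0$gamma <- 0
  expect_equal(transition_rate(m, cc, p0, 1, "M", "M"), set1$kMD_minus)
  b <- ru_state(0, 1, 0, "B"); c2 <- ru_state(0, 1, 0, "C")
  expect_equal(transition_rate(b, c2, p0, 1, "B", "B"),
               transition_rate(b, c2, p0, 1, "M", "M"))
})

test_that("troponin 4-cycles satisfy detailed balance at machine precision", {
  # every Ca-SP and SP-IP square, in every context of the remaining binary
  # component and tropomyosin position
  cycle_ratio <- function(p, states) {
    fwd <- bwd <- 1
    for (i in seq_along(states)) {
      a <- states[i]
      b <- states[if (i == length(states)) 1L else i + 1L]
      fwd <- fwd * transition_rate(a, b, p, ca = 1)
      bwd <- bwd * transition_rate(b, a, p, ca = 1)
    }
    fwd / bwd
  }
  for (p in list(set1, set2)) {
    for (tpm in c("B", "C", "M")) {
      for (ip in 0:1) {  # Ca-SP square at fixed (ip, tpm)
        sq <- c(ru_state(0, 0, ip, tpm), ru_state(1, 0, ip, tpm),
                ru_state(1, 1, ip, tpm), ru_state(0, 1, ip, tpm))
        expect_equal(cycle_ratio(p, sq), 1, tolerance = 1e-12)
      }
      for (ca in 0:1) {  # SP-IP square at fixed (ca, tpm)
        sq <- c(ru_state(ca, 0, 0, tpm), ru_state(ca, 1, 0, tpm),
                ru_state(ca, 1, 1, tpm), ru_state(ca, 0, 1, tpm))
        expect_equal(cycle_ratio(p, sq), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("invalid rate queries are rejected", {
  expect_error(transition_rate(1, 2, set1, ca = -1), "ca")
  expect_error(transition_rate(1, 1, set1, ca = 1), "differ")
  expect_error(transition_rate(0, 2, set1, ca = 1), "range")
  expect_error(transition_rate(1, 25, set1, ca = 1), "range")
  expect_error(transition_rate(1, 2, set1, ca = 1, left = "Z"), "neighbor")
})
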