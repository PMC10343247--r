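test_that("bridging matrix entries match their closed forms", {
  f <- kevlar(); m <- pcu()
  A <- bridging_matrix(f, m, bridging_params(Vf = 0.7, alpha = 0.3, beta = 0.3))
  expect_equal(A[1, 1], 57 / 128700)                       # Em / E11f
  expect_equal(A[2, 2], 0.3 + 0.7 * 57 / 12870)            # beta form
  expect_equal(A[2, 2], A[3, 3])
  expect_equal(A[2, 2], A[4, 4])
  expect_equal(A[5, 5], 0.3 + 0.7 * m$G / 12870)           # alpha form
  expect_equal(A[5, 5], A[6, 6])
  # coupling from the compliance-difference formula, computed independently
  S11f <- 1 / f$E11; S12f <- -f$v12 / f$E11
  S11m <- 1 / m$E; S12m <- -m$v / m$E
  a12 <- (S12f - S12m) / (S11f - S11m) * (A[1, 1] - A[2, 2])
  expect_equal(A[1, 2], a12)
  expect_equal(A[1, 3], a12)
  expect_equal(A[2, 1], 0); expect_equal(A[3, 1], 0)
  expect_equal(A[2, 3], 0); expect_equal(A[3, 2], 0)
})

test_that("identical constituents give a unit bridging matrix", {
  m <- pcu()
  iso_as_ti <- trans_iso_material(E11 = m$E, E22 = m$E, v12 = m$v, v23 = m$v,
                                  G12 = m$G, G23 = m$G)
  for (ab in list(c(0.3, 0.3), c(0.45, 0.6))) {
    A <- bridging_matrix(iso_as_ti, m, bridging_params(0.5, ab[1], ab[2]))
    expect_equal(unclass(A), diag(6), tolerance = 1e-12)
  }
})

test_that("bundle constants reproduce the Kevlar/PCU bundle", {
  b <- bundle_constants(kevlar(), pcu(), bridging_params(0.70, 0.30, 0.30))
  # frozen from independent closed-form evaluation of the bridging formulas
  expect_equal(b$E11, 90107.1, tolerance = 1e-6)           # rule of mixtures
  expect_equal(b$E22, 479.452, tolerance = 1e-6)
  expect_equal(b$G12, 172.3157, tolerance = 1e-6)
  expect_equal(b$G23, 171.3139, tolerance = 1e-6)
  expect_equal(b$v12, 0.339, tolerance = 1e-3)
  # transverse-isotropy identity holds on the returned bundle
  expect_equal(b$G23, b$E22 / (2 + 2 * b$v23))
})

test_that("bundle constants approach constituents in the Vf limits", {
  f <- kevlar(); m <- pcu()
  hi <- bundle_constants(f, m, bridging_params(1 - 1e-9))
  expect_equal(hi$E11, f$E11, tolerance = 1e-6)
  expect_equal(hi$E22, f$E22, tolerance = 1e-4)
  expect_equal(hi$G12, f$G12, tolerance = 1e-4)
  lo <- bundle_constants(f, m, bridging_params(1e-9))
  expect_equal(lo$E11, m$E, tolerance = 1e-4)
  expect_equal(lo$E22, m$E, tolerance = 1e-4)
  expect_equal(lo$G12, m$G, tolerance = 1e-4)
})

test_that("bundle moduli grow monotonically with Vf and stay in constituent bounds", {
  f <- kevlar(); m <- pcu()
  vfs <- seq(0.05, 0.95, by = 0.05)
  prev <- NULL
  for (vf in vfs) {
    b <- bundle_constants(f, m, bridging_params(vf))
    expect_gte(b$E11, m$E); expect_lte(b$E11, f$E11)
    expect_gte(b$E22, m$E); expect_lte(b$E22, f$E22)
    expect_gte(b$G12, m$G); expect_lte(b$G12, f$G12)
    if (!is.null(prev)) {
      expect_gt(b$E11, prev$E11)
      expect_gt(b$E22, prev$E22)
      expect_gt(b$G12, prev$G12)
    }
    prev <- b
  }
})

test_that("full bridging compliance product is symmetric and ROM-consistent", {
  f <- kevlar(); m <- pcu()
  S <- bridging_compliance(f, m, bridging_params(0.7))
  expect_equal(S, t(S))
  expect_equal(1 / S[1, 1], 0.7 * f$E11 + 0.3 * m$E, tolerance = 1e-4)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # the coupled product stiffens the transverse response relative to the
  # per-constant extraction (the published tables follow the latter)
  b <- bundle_constants(f, m, bridging_params(0.7))
  expect_gt(1 / S[2, 2], b$E22)
})

test_that("back-solved parameters recover Vf, alpha, beta and round-trip", {
  f <- kevlar(); m <- pcu()
  target <- bundle_constants(f, m, bridging_params(0.70, 0.30, 0.30))
  p <- backsolve_params(target, f, m)
  expect_equal(p$Vf, 0.700, tolerance = 1e-6)
  expect_equal(p$alpha, 0.30, tolerance = 1e-6)
  expect_equal(p$beta, 0.30, tolerance = 1e-6)
  # round trip at other parameter sets
  for (truth in list(c(0.5, 0.45, 0.55), c(0.8, 0.35, 0.4))) {
    t2 <- bundle_constants(f, m, bridging_params(truth[1], truth[2], truth[3]))
    p2 <- backsolve_params(t2, f, m)
    b2 <- bundle_constants(f, m, p2)
    expect_equal(b2$E11 / t2$E11, 1, tolerance = 5e-3)
    expect_equal(b2$E22 / t2$E22, 1, tolerance = 5e-3)
    expect_equal(b2$G12 / t2$G12, 1, tolerance = 5e-3)
  }
  # unattainable target reported with range
  bad <- trans_iso_material(E11 = 2 * f$E11, E22 = 100, v12 = 0.3, v23 = 0.3,
                            G12 = 50)
  expect_error(backsolve_params(bad, f, m), "outside constituent range")
})
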