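test_that("parallel theta vanishes on homopolymers", {
  s <- make_seqs("AAAAAAAA", "DNA")
  th <- parallel_theta(s, structural6(), lambda = 3)
  expect_equal(unname(as.matrix(th[, -1])[1, ]), c(0, 0, 0))
})

test_that("theta_1 matches hand-summed squared differences for one property", {
  s <- make_seqs("ACGT", "DNA")
  p <- normalize_index(structural6()[1, ])
  z <- prop_values(p)[1, ]
  track <- z[c("AC", "CG", "GT")]
  by_hand <- mean((track[-3] - track[-1])^2)
  th <- parallel_theta(s, p, lambda = 1)
  expect_equal(th$theta1, unname(by_hand), tolerance = 1e-12)
})

test_that("duplicating a property leaves every theta unchanged", {
  seqs <- random_sequences("DNA", 4, 20, 30, seed = 21)
  p <- structural6()[1:2, ]
  doubled <- p[c(1, 2, 1, 2), ]
  doubled$property <- c("a", "b", "a2", "b2")
  t1 <- as.matrix(parallel_theta(seqs, p, 5)[, -1])
  t2 <- as.matrix(parallel_theta(seqs, doubled, 5)[, -1])
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("series tau has lag-major ordering and matches constant-track algebra", {
  # single property: count reduces to lambda
  s <- make_seqs("ACGTACGT", "DNA")
  p1 <- structural6()[1, ]
  expect_equal(ncol(series_tau(s, p1, 4)) - 1, 4)

  # homopolymer: every window is AA, the standardized value c gives tau = c^2
  homo <- make_seqs("AAAAAAA", "DNA")
  z <- prop_values(normalize_index(p1))[1, "AA"]
  tau <- as.matrix(series_tau(homo, p1, 3)[, -1])
  expect_equal(unname(tau[1, ]), rep(z^2, 3), tolerance = 1e-12)

  p2 <- structural6()[1:2, ]
  tt <- series_tau(s, p2, 2)
  expect_equal(
    setdiff(names(tt), "id"),
    c("tau.lag1.Twist", "tau.lag1.Tilt", "tau.lag2.Twist", "tau.lag2.Tilt")
  )
})

test_that("pseudo components are a weighted blend that sums to one", {
  seqs <- random_sequences("DNA", 6, 25, 60, seed = 55)
  p <- structural6()
  for (kind in c("parallel", "series")) {
    v <- feature_matrix(
      pseudo_composition(seqs, p, k = 2, lambda = 4, w = 0.1, kind = kind)
    )
    expect_true(all(abs(rowSums(v) - 1) < 1e-12))
    if (kind == "parallel") expect_true(all(v >= 0))
  }
})

test_that("w = 0 reduces to the bare composition", {
  seqs <- random_sequences("DNA", 3, 30, 40, seed = 2)
  v <- feature_matrix(pseudo_composition(seqs, structural6(), k = 2, lambda = 5, w = 0))
  f <- feature_matrix(kmer_vector(seqs, 2))
  expect_equal(v[, 1:16], f, tolerance = 0)
  expect_true(all(v[, 17:21] == 0))
  expect_error(pseudo_composition(seqs, structural6(), k = 2, lambda = 5, w = -1), "w")
})

test_that("lambda = 0 yields the bare composition vector", {
  seqs <- random_sequences("DNA", 3, 30, 40, seed = 3)
  v <- pseudo_composition(seqs, structural6(), k = 2, lambda = 0, w = 0.05)
  expect_equal(ncol(v) - 1, 16)
  expect_equal(feature_matrix(v), feature_matrix(kmer_vector(seqs, 2)), tolerance = 0)
})

test_that("pseudo-component mass is strictly increasing in w", {
  seqs <- random_sequences("DNA", 1, 50, 50, seed = 8)
  p <- structural6()
  th <- as.matrix(parallel_theta(seqs, p, 6)[, -1])
  phi <- sum(th)
  expect_gt(phi, 0)
  masses <- vapply(c(0.01, 0.05, 0.2, 1), function(w) {
    v <- feature_matrix(pseudo_composition(seqs, p, k = 2, lambda = 6, w = w))
    sum(v[1, 17:22])
  }, numeric(1))
  expect_true(all(diff(masses) > 0))
  expect_equal(masses[2], 0.05 * phi / (1 + 0.05 * phi), tolerance = 1e-12)
})

test_that("full vectors match the end-to-end naive oracle to 1e-12", {
  p <- structural6()
  aa3 <- select_props(
    load_builtin("PROTEIN", 1),
    c("Hydrophobicity", "Hydrophilicity", "SideChainMass")
  )
  n_checked <- 0
  for (seed in 1:5) {
    dna <- random_sequences("DNA", 10, 20, 60, seed = 300 + seed)
    lam <- 1 + seed %% 4
    eng <- feature_matrix(extract_features(dna, "PseDNC", lambda = lam, w = 0.05))
    ora <- oracle_matrix(oracle_features(dna, "PseDNC", lambda = lam, w = 0.05, props = p))
    expect_identical(colnames(eng), colnames(ora))
    expect_lt(max(abs(eng - ora)), 1e-12)

    eng_s <- feature_matrix(
      extract_features(dna, "SC-PseDNC-General", lambda = lam, w = 0.1, props = p)
    )
    ora_s <- oracle_matrix(
      oracle_features(dna, "SC-PseDNC-General", lambda = lam, w = 0.1, props = p)
    )
    expect_lt(max(abs(eng_s - ora_s)), 1e-12)

    prot <- random_sequences("PROTEIN", 10, 20, 60, seed = 400 + seed)
    eng_a <- feature_matrix(extract_features(prot, "PC-PseAAC", lambda = lam))
    ora_a <- oracle_matrix(
      oracle_features(prot, "PC-PseAAC", lambda = lam, w = 0.05, props = aa3)
    )
    expect_lt(max(abs(eng_a - ora_a)), 1e-12)
    n_checked <- n_checked + 3 * nrow(dna)
  }
  expect_gte(n_checked, 100)
})

test_that("mode algebra: published dimension formulas hold", {
  dna <- random_sequences("DNA", 1, 80, 80, seed = 91)
  rna <- random_sequences("RNA", 1, 80, 80, seed = 92)
  prot <- random_sequences("PROTEIN", 1, 80, 80, seed = 93)
  lam <- 5
  expect_equal(ncol(extract_features(dna, "PseDNC", lambda = lam)) - 1, 16 + lam)
  expect_equal(ncol(extract_features(dna, "PseKNC", k = 3, lambda = lam)) - 1, 64 + lam)
  expect_equal(ncol(extract_features(dna, "PC-PseTNC-General", lambda = lam)) - 1, 64 + lam)
  expect_equal(
    ncol(extract_features(dna, "SC-PseDNC-General", lambda = lam)) - 1,
    16 + lam * 6
  )
  expect_equal(
    ncol(extract_features(rna, "PC-PseDNC-General", lambda = lam)) - 1,
    16 + lam
  )
  expect_equal(ncol(extract_features(prot, "PC-PseAAC", lambda = lam)) - 1, 20 + lam)
  # series PseAAC uses hydrophobicity + hydrophilicity: 20 + 2 * lambda
  expect_equal(ncol(extract_features(prot, "SC-PseAAC", lambda = lam)) - 1, 20 + 2 * lam)
})

test_that("PseKNC correlates dinucleotides regardless of composition k", {
  dna <- random_sequences("DNA", 2, 40, 50, seed = 17)
  v3 <- extract_features(dna, "PseKNC", k = 3, lambda = 4)
  v2 <- extract_features(dna, "PseDNC", lambda = 4)
  m3 <- feature_matrix(v3)
  m2 <- feature_matrix(v2)
  # identical theta tiers feed both, so the pseudo blocks agree up to the
  # (1 + w * Phi) denominator being equal
  expect_equal(unname(m3[, 65:68]), unname(m2[, 17:20]), tolerance = 1e-12)
})

test_that("excessive lambda is rejected naming the maximum", {
  s <- make_seqs("ACGTAC", "DNA") # T = 5 windows, max lambda 4
  expect_error(parallel_theta(s, structural6(), 5), "max lambda = 4")
  expect_error(parallel_theta(s, structural6(), 4), NA)
})

test_that("the protein General modes share engines with the classic modes", {
  prot <- random_sequences("PROTEIN", 3, 30, 40, seed = 44)
  a <- feature_matrix(extract_features(prot, "PC-PseAAC", lambda = 3))
  b <- feature_matrix(extract_features(prot, "PC-PseAAC-General", lambda = 3))
  expect_equal(a, b, tolerance = 0)
  # but the General mode accepts the full 547-property universe
  big <- load_builtin("PROTEIN", 1)[1:10, ]
  v <- extract_features(prot, "PC-PseAAC-General", lambda = 3, props = big)
  expect_equal(ncol(v) - 1, 23)
})
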