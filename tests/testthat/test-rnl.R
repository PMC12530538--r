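test_that("quantum catches are normalized, linear, and logged correctly", {
  vs <- toy_tetra_vs()
  ones <- make_spectra(a = rep(1, 401))
  halves <- make_spectra(a = rep(0.5, 401))
  ill <- flat_illuminant()
  expect_equal(unname(quantum_catches(ones, vs, ill)$Q[1, ]), rep(1, 4),
               tolerance = 1e-12)
  expect_equal(unname(quantum_catches(halves, vs, ill)$Q[1, ]), rep(0.5, 4),
               tolerance = 1e-12)

  # doubling the illuminant doubles catches and shifts log catches by ln 2
  sp <- make_spectra(a = sigmoid_spectrum(540))
  c1 <- quantum_catches(sp, vs, flat_illuminant(value = 1))
  c2 <- quantum_catches(sp, vs, flat_illuminant(value = 2))
  expect_equal(c2$Q, 2 * c1$Q, tolerance = 1e-12)
  expect_equal(c2$f, c1$f + log(2), tolerance = 1e-12)
  expect_equal(unname(rowSums(c1$qrel)), 1)

  dark <- make_spectra(a = rep(0, 401))
  expect_error(quantum_catches(dark, vs, ill), "zero quantum catch")
})

test_that("chromatic distance identities: zero self-distance and symmetry", {
  vs <- toy_tetra_vs()
  f <- log(c(0.3, 0.5, 0.7, 0.9))
  g <- log(c(0.35, 0.45, 0.72, 0.88))
  expect_equal(chromatic_distance(f, f, vs), 0)
  expect_equal(chromatic_distance(f, g, vs), chromatic_distance(g, f, vs))
  expect_gte(chromatic_distance(f, g, vs), 0)
  # uniform shift of all log catches (pure intensity change) is achromatic
  expect_equal(chromatic_distance(f, f + 0.4, vs), 0, tolerance = 1e-12)
})

test_that("dichromat reduction matches the closed form", {
  e <- c(0.05, 0.05)
  expect_equal(chromatic_distance(c(0.05, 0), c(0, 0), e), 0.7071068,
               tolerance = 1e-7)
  # independent closed form |df1 - df2|/sqrt(e1^2 + e2^2) on random inputs
  set.seed(7)
  for (i in 1:20) {
    fa <- rnorm(2); fb <- rnorm(2); ee <- runif(2, 0.02, 0.3)
    df <- fa - fb
    expect_equal(chromatic_distance(fa, fb, ee),
                 abs(df[1] - df[2]) / sqrt(sum(ee^2)), tolerance = 1e-12)
  }
})

test_that("tetrachromat closed form agrees with the generic evaluator", {
  set.seed(11)
  for (i in 1:50) {
    fa <- rnorm(4); fb <- rnorm(4); e <- runif(4, 0.02, 0.3)
    expect_equal(chromatic_distance(fa, fb, e, method = "closed"),
                 chromatic_distance(fa, fb, e, method = "generic"),
                 tolerance = 1e-10)
  }
})

test_that("achromatic distance is the log ratio over the Weber fraction", {
  expect_equal(achromatic_distance(log(2), log(2), 0.05), 0)
  expect_equal(achromatic_distance(0.05, 0, 0.05), 1)     # Qa/Qb = e^0.05
  expect_equal(achromatic_distance(0.30, 0, 0.10), 3)     # bird, e^0.30
  expect_equal(achromatic_distance(0, 0.2, 0.05),
               achromatic_distance(0.2, 0, 0.05))
})

test_that("distances are invariant to illuminant scale and receptor gain", {
  vs <- toy_tetra_vs()
  ds <- make_spectra(a = sigmoid_spectrum(540), b = sigmoid_spectrum(430),
                     c = ramp_spectrum() + 2)
  base <- quantum_catches(ds, vs, flat_illuminant(value = 1))
  d0 <- chromatic_distance(base$f[1, ], base$f[2, ], vs)
  l0 <- achromatic_distance(base$achro_f[1], base$achro_f[2], vs)
  for (cc in c(0.1, 10)) {
    ct <- quantum_catches(ds, vs, flat_illuminant(value = cc))
    expect_equal(chromatic_distance(ct$f[1, ], ct$f[2, ], vs), d0,
                 tolerance = 1e-10)
    expect_equal(achromatic_distance(ct$achro_f[1], ct$achro_f[2], vs), l0,
                 tolerance = 1e-10)
  }
  # per-receptor gain: scaling channel i's sensitivity scales both stimuli's
  # Q_i, shifting both f_i by the same constant
  set.seed(3)
  gains <- log(runif(4, 0.2, 5))
  expect_equal(chromatic_distance(base$f[1, ] + gains, base$f[2, ] + gains,
                                  vs), d0, tolerance = 1e-12)
})

test_that("chromatic distance satisfies the triangle inequality", {
  set.seed(23)
  for (i in 1:30) {
    e <- runif(4, 0.02, 0.3)
    fa <- rnorm(4); fb <- rnorm(4); fc <- rnorm(4)
    expect_lte(chromatic_distance(fa, fc, e),
               chromatic_distance(fa, fb, e) +
                 chromatic_distance(fb, fc, e) + 1e-12)
  }
})

test_that("pairwise matrices are symmetric, zero-diagonal, consistent", {
  # three identical individuals give all-zero matrices
  f0 <- matrix(log(c(0.4, 0.5, 0.6, 0.7)), 3, 4, byrow = TRUE)
  ct0 <- make_catch_table(f0, rep(log(0.5), 3), e = c(0.1, 0.1, 0.1, 0.05))
  m0 <- pairwise_distance_matrices(ct0)
  expect_equal(max(abs(m0$dS)), 0)
  expect_equal(max(abs(m0$dL)), 0)

  set.seed(4)
  f <- matrix(rnorm(5 * 4), 5, 4)
  ct <- make_catch_table(f, rnorm(5), e = c(0.1, 0.1, 0.1, 0.05))
  m <- pairwise_distance_matrices(ct)
  expect_equal(m$dS, t(m$dS))
  expect_equal(unname(diag(m$dS)), rep(0, 5))
  expect_equal(m$dS[2, 4],
               chromatic_distance(f[2, ], f[4, ], ct$e), tolerance = 1e-10)
  expect_equal(m$dL[1, 3],
               achromatic_distance(ct$achro_f[1], ct$achro_f[3], 0.05),
               tolerance = 1e-12)

  ct1 <- make_catch_table(f[1, , drop = FALSE], 0, e = c(0.1, 0.1, 0.1, 0.05))
  expect_error(pairwise_distance_matrices(ct1), "at least 2")
})

test_that("tetrahedral coordinates map relative catches into the simplex", {
  # pure-UV stimulation sits on the UV apex; equal stimulation at the origin
  f <- matrix(0, 2, 4)
  ct <- make_catch_table(f, c(0, 0), e = c(0.1, 0.1, 0.1, 0.05))
  ct$qrel <- rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  xyz <- tetra_coordinates(ct)
  expect_equal(unname(xyz[1, ]), c(0, 0, 0.75))
  expect_equal(unname(xyz[2, ]), c(0, 0, 0), tolerance = 1e-12)

  # random relative catches stay inside the tetrahedron: the barycentric
  # weights recovered from the coordinates equal q and are nonnegative
  V <- rbind(c(0, 0, 0.75),
             c(-sqrt(6) / 4, -sqrt(2) / 4, -0.25),
             c(sqrt(6) / 4, -sqrt(2) / 4, -0.25),
             c(0, sqrt(2) / 2, -0.25))
  A <- rbind(t(V), rep(1, 4))
  set.seed(9)
  for (i in 1:25) {
    q <- rgamma(4, 1); q <- q / sum(q)
    ct$qrel <- rbind(q, q)
    p <- tetra_coordinates(ct)[1, ]
    bary <- solve(A, c(p, 1))
    expect_equal(unname(bary), q, tolerance = 1e-10)
    expect_true(all(bary >= -1e-12))
  }

  ct3 <- make_catch_table(matrix(0, 2, 3), c(0, 0), e = c(0.1, 0.1, 0.05))
  expect_error(tetra_coordinates(ct3), "tetrachromatic")
})
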