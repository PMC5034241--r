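test_that("to_segments builds midpoints and bonds for open and closed curves", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  s <- to_segments(sq, closed = TRUE)
  expect_equal(nrow(s$bond_vectors), 4)
  expect_equal(colSums(s$bond_vectors), c(0, 0, 0))

  line <- straight_chain(3, bond = 1)
  s <- to_segments(line, closed = FALSE)
  expect_equal(nrow(s$bond_vectors), 2)
  expect_equal(s$bond_vectors[1, ], s$bond_vectors[2, ])

  poly <- make_fixture("hopf", n_vertices = 100)$curve_a
  s <- to_segments(poly, closed = TRUE)
  bl <- sqrt(rowSums(s$bond_vectors^2))
  expect_lt(diff(range(bl)), 1e-12)

  expect_error(to_segments(straight_chain(2)), "at least 3")
})

test_that("midpoint Gauss sum recovers known linking numbers", {
  f <- make_fixture("hopf", n_vertices = 200)
  v <- gauss_closed_value(f$curve_a, f$curve_b)
  expect_equal(v, 1, tolerance = 1e-3)
  expect_equal(round(v), polygonal_linking_exact(f$curve_a, f$curve_b))

  f <- make_fixture("unlinked_circles", n_vertices = 150)
  expect_lt(abs(gauss_closed_value(f$curve_a, f$curve_b)), 1e-6)

  f <- make_fixture("torus_link_k", n_vertices = 600, k = 3)
  v <- gauss_closed_value(f$curve_a, f$curve_b)
  expect_equal(v, 3, tolerance = 1e-2)
  expect_equal(round(v), polygonal_linking_exact(f$curve_a, f$curve_b))
})

test_that("midpoint sum converges to the exact linking number with refinement", {
  errs <- sapply(c(50, 100, 400), function(n) {
    f <- make_fixture("hopf", n_vertices = n)
    abs(gauss_closed_value(f$curve_a, f$curve_b) - 1)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-2)
})

test_that("Gauss sum is antisymmetric, symmetric in arguments, and invariant under rigid motion and scaling", {
  set.seed(42)
  for (kind in c("hopf", "torus_link_k", "open_coil_pair")) {
    f <- make_fixture(kind, n_vertices = 120, k = 2, seed = 5)
    seg <- function(m) to_segments(m, closed = f$closed)
    v <- gauss_double_sum(seg(f$curve_a), seg(f$curve_b))$value

    # reversing one chain negates the value
    rev_b <- f$curve_b[nrow(f$curve_b):1, ]
    expect_equal(gauss_double_sum(seg(f$curve_a), seg(rev_b))$value, -v,
                 tolerance = 1e-12)

    # swapping arguments leaves it unchanged
    expect_equal(gauss_double_sum(seg(f$curve_b), seg(f$curve_a))$value, v,
                 tolerance = 1e-12)

    # common rotation + translation
    rot <- random_rotation()
    shift <- rnorm(3, sd = 50)
    va <- gauss_double_sum(seg(apply_rigid(f$curve_a, rot, shift)),
                           seg(apply_rigid(f$curve_b, rot, shift)))$value
    expect_equal(va, v, tolerance = 1e-9)

    # uniform scaling (the kernel is scale-free)
    vs <- gauss_double_sum(seg(f$curve_a * 17.3), seg(f$curve_b * 17.3))$value
    expect_equal(vs, v, tolerance = 1e-9)
  }
})

test_that("rounded midpoint sums match the exact polygonal oracle on random torus links", {
  set.seed(101)
  for (rep in 1:25) {
    k <- sample(1:5, 1)
    f <- make_fixture("torus_link_k", n_vertices = 400, k = k)
    rot <- random_rotation()
    shift <- rnorm(3, sd = 30)
    s <- runif(1, 0.5, 3)
    a <- apply_rigid(f$curve_a * s, rot, shift)
    b <- apply_rigid(f$curve_b * s, rot, shift)
    expect_equal(round(gauss_closed_value(a, b)),
                 polygonal_linking_exact(a, b))
    expect_equal(polygonal_linking_exact(a, b), k)
  }
})

test_that("coincident midpoints raise a singular-pair error instead of a huge value", {
  a <- straight_chain(5, bond = 1)
  b <- a
  b[, 2] <- b[, 2] + 1e-12  # midpoints essentially coincide
  expect_error(gauss_double_sum(to_segments(a), to_segments(b)),
               "singular pair")
})

test_that("Gaussian entanglement of distant near-straight chains vanishes", {
  a <- ca_chain(straight_chain(50, bond = 3.8))
  b <- ca_chain(straight_chain(50, bond = 3.8, origin = c(0, 1000, 0)))
  expect_lt(abs(gaussian_entanglement(a, b)), 1e-3)
})

test_that("gaussian_entanglement accepts a dimer and matches the chain call", {
  f <- make_fixture("cut_hopf_dimer", n_vertices = 80)
  d <- fixture_as_dimer(f)
  expect_identical(gaussian_entanglement(d),
                   gaussian_entanglement(d$chain_a, d$chain_b))
  # a toy dimer straddling the closed-curve value of 1
  expect_equal(gaussian_entanglement(d), 1, tolerance = 0.3)
})
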