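test_that("single-spin operators have the canonical matrix elements", {
  sys <- sys_1pair()
  Iz0 <- spin_op(sys, 1, "z")
  expect_lt(frob(Iz0 - diag(c(0.5, 0.5, -0.5, -0.5))), 1e-12)
  expect_lt(Mod(trace_of(spin_op(sys, 2, "x"))), 1e-12)
  expect_error(spin_op(sys, 3, "x"), "out of range")
})

test_that("Tr(Ix' Ix) = 2^(2n)/4 for any spin of an n-pair system", {
  for (n in 1:3) {
    sys <- spin_system(n)
    Ix <- spin_op(sys, 1, "x")
    expect_equal(Re(op_inner(Ix, Ix)), 2^(2 * n) / 4)
  }
})

test_that("angular-momentum commutation [Ix, Iy] = i Iz holds per spin", {
  sys <- sys_2pair()
  for (i in c(1L, 4L)) {
    lhs <- spin_op(sys, i, "x") %*% spin_op(sys, i, "y") -
      spin_op(sys, i, "y") %*% spin_op(sys, i, "x")
    expect_lt(frob(lhs - 1i * spin_op(sys, i, "z")), 1e-12)
  }
})

test_that("pair scalar products have the singlet/triplet spectrum", {
  sys <- sys_1pair()
  P <- pair_scalar_op(sys, 1)
  ev <- sort(Re(eigen(P, symmetric = TRUE, only.values = TRUE)$values))
  expect_equal(ev, c(-0.75, 0.25, 0.25, 0.25))
  # Tr(P' P) = 3/4 * dim/4
  expect_equal(Re(op_inner(P, P)), 0.75)
  sys2 <- sys_2pair()
  P1 <- pair_scalar_op(sys2, 1)
  expect_equal(Re(op_inner(P1, P1)), 0.75 * sys2$dim / 4)
})

test_that("scalar products commute with global rotations of their pair", {
  sys <- sys_2pair()
  P <- pair_scalar_op(sys, 1)
  for (ax in c("x", "y", "z")) {
    tot <- total_spin_op(sys, 1:2, ax)
    expect_lt(frob(P %*% tot - tot %*% P), 1e-12)
  }
})

test_that("the free Hamiltonian reduces to the scalar coupling for one pair", {
  sys <- sys_1pair(offsets_hz = 0, j_intra_hz = 13.5)
  H <- h_free(sys)
  expect_lt(frob(H - 2 * pi * 13.5 * pair_scalar_op(sys, 1)), 1e-10)
  ev_hz <- sort(Re(eigen(H, symmetric = TRUE,
                         only.values = TRUE)$values)) / (2 * pi)
  expect_equal(ev_hz, c(-3 * 13.5 / 4, rep(13.5 / 4, 3)))
})

test_that("the six-spin Hamiltonian matches a term-by-term reconstruction", {
  sys <- sys_3pair(offsets_hz = c(-150, 0, 180))
  H <- h_free(sys, frame_hz = 10)
  # independent brute-force sum over the same physical terms
  ref <- matrix(0 + 0i, 64, 64)
  for (k in 1:3) {
    for (s in c(2 * k - 1, 2 * k)) {
      ref <- ref + (sys$offsets_hz[k] - 10) * spin_op(sys, s, "z")
    }
    ref <- ref + sys$j_intra_hz[k] *
      (spin_op(sys, 2 * k - 1, "x") %*% spin_op(sys, 2 * k, "x") +
       spin_op(sys, 2 * k - 1, "y") %*% spin_op(sys, 2 * k, "y") +
       spin_op(sys, 2 * k - 1, "z") %*% spin_op(sys, 2 * k, "z"))
  }
  for (r in seq_len(nrow(sys$j_vicinal))) {
    i <- sys$j_vicinal$i[r]; j <- sys$j_vicinal$j[r]
    ref <- ref + sys$j_vicinal$J_hz[r] *
      (spin_op(sys, i, "x") %*% spin_op(sys, j, "x") +
       spin_op(sys, i, "y") %*% spin_op(sys, j, "y") +
       spin_op(sys, i, "z") %*% spin_op(sys, j, "z"))
  }
  expect_lt(frob(H - 2 * pi * ref), 1e-9)
  expect_lt(frob(H - Conj(t(H))), 1e-10)
})

test_that("RF Hamiltonians follow the frame and superpose", {
  sys <- sys_3pair()
  # single SLIC in its own frame: time-independent 2*pi*nu1*(Ix + Ix')
  sch <- slic_scheme("excitation", 2, tau = 0.1, nu1 = 20)
  H0 <- h_rf(sys, sch, t = 0)
  expect_lt(frob(H0 - 2 * pi * 20 * total_spin_op(sys, 3:4, "x")), 1e-10)
  expect_lt(frob(h_rf(sys, sch, t = 0.0123) - H0), 1e-10)

  # triple SLIC at t = 0 with equal phases is the sum of three pair terms
  tri <- slic_scheme("excitation", 1:3, tau = 0.1, nu1 = 13.5)
  Ht <- h_rf(sys, tri, t = 0, frame_hz = sys$offsets_hz[1])
  singles <- lapply(1:3, function(k) {
    h_rf(sys, slic_scheme("excitation", k, tau = 0.1, nu1 = 13.5),
         t = 0, frame_hz = sys$offsets_hz[1])
  })
  expect_lt(frob(Ht - Reduce(`+`, singles)), 1e-10)

  # double SLIC, 200 Hz apart: cross term oscillates with period 1/200 s
  sys2 <- sys_2pair()
  dbl <- slic_scheme("excitation", 1:2, tau = 0.1, nu1 = 13.5)
  ts <- seq(0, 1 / 200, length.out = 9)
  H_a <- h_rf(sys2, dbl, t = ts[1], frame_hz = 0)
  H_b <- h_rf(sys2, dbl, t = ts[1] + 1 / 200, frame_hz = 0)
  expect_lt(frob(H_a - H_b), 1e-8)
  # and genuinely varies inside the period
  H_mid <- h_rf(sys2, dbl, t = ts[5], frame_hz = 0)
  expect_gt(frob(H_a - H_mid), 1)
})
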