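test_that("norm and angle follow their closed forms", {
  expect_equal(vector_norm(c(0, 0, 0)), 0)
  expect_equal(vector_norm(c(4, 2, 1)), sqrt(21))
  lines <- hypothesis_lines()
  expect_equal(vector_angle(lines$v_info, lines$v_dur), acos(7 / sqrt(63)),
               tolerance = 1e-12)
  expect_equal(vector_angle(c(2, 2, 2), c(1, 1, 1)), 0, tolerance = 1e-12)
  expect_equal(vector_angle(c(1, 0, 0), c(0, 1, 0)), pi / 2)
  expect_error(vector_angle(c(0, 0, 0), c(1, 1, 1)), "zero vector")
  expect_error(vector_norm(c(1, NA, 2)), "non-finite")
})

test_that("atan2 agrees with the arccos oracle on random pairs", {
  set.seed(10)
  for (r in 1:10) {
    U <- matrix(rnorm(3000), ncol = 3)
    V <- matrix(rnorm(3000), ncol = 3)
    a1 <- vapply(seq_len(nrow(U)), function(i) vector_angle(U[i, ], V[i, ]),
                 numeric(1))
    a2 <- acos(pmin(1, pmax(-1, rowSums(U * V) /
                              (vector_norm(U) * vector_norm(V)))))
    expect_lt(max(abs(a1 - a2)), 1e-9)
  }
})

test_that("angles are invariant to positive rescaling", {
  set.seed(11)
  u <- rnorm(3); v <- rnorm(3)
  expect_equal(vector_angle(u, v), vector_angle(3.7 * u, 0.2 * v),
               tolerance = 1e-12)
})

.cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("plane projection is an orthogonal projection", {
  lines <- hypothesis_lines()
  # on-plane points are fixed, and their 2-D norms/angles equal the 3-D ones
  expect_equal(project_to_plane(lines$v_info, lines), lines$v_info)
  on_plane <- 1.3 * lines$v_dur + 0.4 * lines$v_info
  p <- project_to_plane(on_plane, lines)
  expect_equal(p, on_plane, tolerance = 1e-9)
  expect_equal(vector_norm(p), vector_norm(on_plane), tolerance = 1e-9)
  expect_equal(vector_angle(p, lines$v_info), vector_angle(on_plane, lines$v_info),
               tolerance = 1e-9)
  set.seed(12)
  for (r in 1:50) {
    u <- rnorm(3) * 5
    p <- project_to_plane(u, lines)
    expect_lt(abs(sum(p * lines$normal)), 1e-9) # lands on the plane
    resid <- p - u
    expect_lt(vector_norm(.cross_oracle(resid, lines$normal)), 1e-9)
    expect_equal(project_to_plane(p, lines), p, tolerance = 1e-9) # idempotent
  }
})

test_that("the literal absolute-value correction leaves one side off-plane", {
  lines <- hypothesis_lines()
  N <- lines$normal
  u_neg <- lines$v_info - N # u . N < 0: literal and signed agree
  expect_equal(project_to_plane(u_neg, lines, literal = TRUE),
               project_to_plane(u_neg, lines), tolerance = 1e-12)
  u_pos <- lines$v_info + N # u . N > 0: literal doubles the offset
  p_lit <- project_to_plane(u_pos, lines, literal = TRUE)
  expect_equal(abs(sum(p_lit * N)), 2 * abs(sum(u_pos * N)), tolerance = 1e-9)
})

test_that("matrix input vectorizes all geometry primitives", {
  set.seed(13)
  U <- matrix(rnorm(30), ncol = 3)
  lines <- hypothesis_lines()
  expect_equal(vector_norm(U),
               apply(U, 1, function(u) vector_norm(u)))
  expect_equal(vector_angle(U, lines$v_dur),
               apply(U, 1, function(u) vector_angle(u, lines$v_dur)))
  P <- project_to_plane(U, lines)
  expect_equal(P[4, ], project_to_plane(U[4, ], lines))
})

test_that("triples stack group-averaged condition maps", {
  m <- lapply(c(2, 4, 6), function(v) matrix(v, 3, 3))
  tr <- kprime_triples(m, windows = 1:3)
  expect_equal(dim(tr), c(3, 3, 3))
  expect_equal(tr[1, 1, ], c(2, 4, 6))
  fits <- lapply(c(1, 3), function(v)
    structure(list(kprime = matrix(v, 3, 3)), class = "kprime_fit"))
  tr2 <- kprime_triples(list(fits, fits, fits), windows = 1)
  expect_equal(tr2[1, 1, ], c(2, 2, 2))
})
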