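test_that("basis conversion is the identity on a cubic cell and round-trips", {
  cubic <- unit_cell(10, 10, 10)
  u <- adp_tensor(0.01, 0.01, 0.01, basis = "cif_star")
  uc <- cif_to_cartesian(u, cubic)
  expect_equal(as.numeric(uc), c(0.01, 0.01, 0.01, 0, 0, 0), tolerance = 1e-14)

  set.seed(11)
  tric <- unit_cell(7.1, 8.2, 9.3, 95, 101, 112)
  for (rep in 1:10) {
    M <- rand_pd()
    u0 <- adp_from_mat(M, basis = "cif_star")
    back <- cartesian_to_cif(cif_to_cartesian(u0, tric), tric)
    expect_equal(as.numeric(back), as.numeric(u0), tolerance = 1e-12)
  }
  expect_error(cif_to_cartesian(adp_tensor(0.01, 0.01, 0.01), tric), "basis")
  expect_error(
    cartesian_to_cif(adp_tensor(0.01, 0.01, 0.01, basis = "cif_star"), tric),
    "basis")
})

test_that("basis conversion preserves the quadratic form of displacements", {
  set.seed(21)
  cell <- unit_cell(7.1, 8.2, 9.3, 95, 101, 112)
  A <- cell_matrix(cell)
  D <- diag(reciprocal_lengths(cell))
  for (rep in 1:20) {
    Ustar <- rand_pd()
    Ucart <- mat6(as.numeric(cif_to_cartesian(adp_from_mat(Ustar, "cif_star"),
                                              cell)))
    # the mean-square displacement projected on any Cartesian direction w
    # must equal the fractional-basis form evaluated at the pulled-back
    # direction A'w (covariance transformation law)
    w <- rnorm(3)
    qf_cart <- drop(t(w) %*% Ucart %*% w)
    wf <- drop(t(A) %*% w)
    qf_frac <- drop(t(wf) %*% (D %*% Ustar %*% D) %*% wf)
    expect_equal(qf_cart, qf_frac, tolerance = 1e-12)
  }
})

test_that("triclinic conversion matches a Gaussian sampling oracle", {
  cell <- unit_cell(7.1, 8.2, 9.3, 95, 101, 112)
  Ustar <- diag(c(0.02, 0.03, 0.01))
  Ucart <- mat6(as.numeric(cif_to_cartesian(adp_from_mat(Ustar, "cif_star"),
                                            cell)))
  # oracle: draw fractional displacements with covariance D U* D and map
  # them through the cell matrix; the empirical Cartesian covariance must
  # reproduce the converted tensor
  set.seed(31)
  A <- cell_matrix(cell)
  D <- diag(reciprocal_lengths(cell))
  Cfrac <- D %*% Ustar %*% D
  ev <- eigen(Cfrac, symmetric = TRUE)
  Z <- matrix(rnorm(3 * 1e6), ncol = 3)
  xf <- Z %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  xc <- xf %*% t(A)
  emp <- crossprod(xc) / nrow(xc)
  expect_lt(max(abs(emp - Ucart)) / max(abs(Ucart)), 0.01)
})

test_that("rigid-bond projection difference matches direct matrix arithmetic", {
  uA <- adp_tensor(0.02, 0.01, 0.01)
  uB <- adp_tensor(0.01, 0.01, 0.01)
  rA <- c(0, 0, 0); rB <- c(1.5, 0, 0)
  expect_equal(bond_projection_delta(uA, uB, rA, rB), 0.01)
  expect_equal(bond_projection_delta(uA, uA, rA, rB), 0)
  expect_equal(bond_projection_delta(uA, uB, rA, rB),
               bond_projection_delta(uB, uA, rB, rA))
  expect_error(bond_projection_delta(uA, uB, rA, rA), "coincident")

  set.seed(41)
  for (rep in 1:20) {
    MA <- rand_pd(); MB <- rand_pd()
    rA <- rnorm(3); rB <- rnorm(3)
    n <- (rB - rA) / sqrt(sum((rB - rA)^2))
    oracle <- abs(drop(t(n) %*% MA %*% n) - drop(t(n) %*% MB %*% n))
    expect_equal(bond_projection_delta(adp_from_mat(MA), adp_from_mat(MB),
                                       rA, rB),
                 oracle, tolerance = 1e-15)
  }
})

test_that("overlap statistic hits its boundary and closed-form values", {
  set.seed(51)
  for (rep in 1:10) {
    M <- rand_pd()
    expect_equal(overlap_similarity_s(adp_from_mat(M), adp_from_mat(M)), 0,
                 tolerance = 1e-10)
  }
  # strongly prolate, orthogonal long axes: essentially disjoint densities
  u1 <- adp_tensor(0.1, 1e-13, 1e-13)
  u2 <- adp_tensor(1e-13, 0.1, 1e-13)
  expect_equal(overlap_similarity_s(u1, u2), 100, tolerance = 0.01)
  # frozen closed-form value, verified against numeric_overlap_s
  expect_equal(
    overlap_similarity_s(adp_tensor(0.01, 0.01, 0.01),
                         adp_tensor(0.04, 0.04, 0.04)),
    28.45, tolerance = 0.01)
  expect_error(
    overlap_similarity_s(adp_tensor(-0.01, 0.01, 0.01),
                         adp_tensor(0.01, 0.01, 0.01)),
    "first")
  expect_error(
    overlap_similarity_s(adp_tensor(0.01, 0.01, 0.01),
                         adp_tensor(-0.01, 0.01, 0.01)),
    "second")
})

test_that("overlap statistic is symmetric, rotation invariant and bounded", {
  set.seed(61)
  for (rep in 1:25) {
    M1 <- rand_pd(); M2 <- rand_pd()
    s12 <- overlap_similarity_s(adp_from_mat(M1), adp_from_mat(M2))
    s21 <- overlap_similarity_s(adp_from_mat(M2), adp_from_mat(M1))
    expect_equal(s12, s21, tolerance = 1e-12)
    expect_gte(s12, 0)
    expect_lte(s12, 100)
    R <- rand_rotation()
    sr <- overlap_similarity_s(adp_from_mat(R %*% M1 %*% t(R)),
                               adp_from_mat(R %*% M2 %*% t(R)))
    expect_equal(s12, sr, tolerance = 1e-10)
  }
})

test_that("ADP scaling fit recovers constructed transformations", {
  set.seed(71)
  src <- lapply(1:10, function(k) vec6(rand_pd()))
  # identity
  f0 <- fit_adp_scaling(src, src)
  expect_equal(f0$kappa, 1, tolerance = 1e-10)
  expect_equal(f0$offset, rep(0, 6), tolerance = 1e-10)
  expect_lt(f0$rms, 1e-12)
  # planted kappa + isotropic offset
  tgt <- lapply(src, function(u) 1.1 * u + c(0.002, 0.002, 0.002, 0, 0, 0))
  f1 <- fit_adp_scaling(src, tgt)
  expect_equal(f1$kappa, 1.1, tolerance = 1e-10)
  expect_equal(f1$offset, c(0.002, 0.002, 0.002, 0, 0, 0), tolerance = 1e-10)
  expect_lt(f1$rms, 1e-12)
  # independent normal-equations oracle for a noisy problem
  tgt2 <- lapply(tgt, function(u) u + rnorm(6, 0, 5e-4))
  f2 <- fit_adp_scaling(src, tgt2)
  w <- sqrt(c(1, 1, 1, 2, 2, 2))
  X <- do.call(rbind, lapply(src, function(u) cbind(u * w, diag(w))))
  y <- unlist(lapply(tgt2, function(u) u * w))
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(f2$kappa, beta[1], tolerance = 1e-8)
  expect_equal(f2$offset, beta[2:7], tolerance = 1e-8)
  # least-squares optimality: fitted residual <= residual of (1, 0)
  null_rms <- sqrt(mean(unlist(Map(`-`, tgt2, src))^2))
  expect_lte(f2$rms, null_rms)
  # too few pairs
  expect_error(fit_adp_scaling(src[1:5], tgt[1:5]), "7")
})

test_that("applying a scaling composes with the fit", {
  set.seed(81)
  u <- adp_tensor(0.01, 0.02, 0.03, 0.001, -0.002, 0.003)
  ident <- structure(list(kappa = 1, offset = rep(0, 6), rms = 0, n = 1),
                     class = "adp_scaling")
  expect_equal(as.numeric(apply_adp_scaling(u, ident)), as.numeric(u))
  dbl <- structure(list(kappa = 2, offset = rep(0, 6), rms = 0, n = 1),
                   class = "adp_scaling")
  expect_equal(as.numeric(apply_adp_scaling(u, dbl)), 2 * as.numeric(u))
  src <- lapply(1:9, function(k) vec6(rand_pd()))
  tgt <- lapply(src, function(v) 0.93 * v + c(1, 1, 1, 0, 0, 0) * 0.0015)
  f <- fit_adp_scaling(src, tgt)
  for (k in seq_along(src)) {
    got <- apply_adp_scaling(adp_from_mat(mat6(src[[k]])), f)
    expect_equal(as.numeric(got), tgt[[k]], tolerance = 1e-9)
  }
  expect_warning(
    apply_adp_scaling(u, structure(list(kappa = 1, offset = c(-1, -1, -1, 0, 0, 0),
                                        rms = 0, n = 1),
                                   class = "adp_scaling")),
    "semidefinite")
})
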