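test_that("subtract_internal returns observed minus transferred internal", {
  ss <- make_structure(synth_spec("arg9", seed = 3))
  s <- ss$structure
  g <- ss$graph
  # with the generator's database the planted external part comes back
  u_eff <- subtract_internal(s, ss$db, g, 100)
  for (i in which(!s$atoms$is_h)) {
    expect_equal(u_eff[[as.character(i)]], ss$truth$u_ext[[i]],
                 tolerance = 1e-12)
  }
  # with an all-zero database the observed Cartesian ADPs come back
  zero_db <- ss$db
  for (k in seq_along(zero_db)) zero_db[[k]]$u_local <- rep(0, 6)
  u_obs <- subtract_internal(s, zero_db, g, 100)
  for (i in which(!s$atoms$is_h)) {
    expect_equal(u_obs[[as.character(i)]], atom_adp_cart(s, i),
                 tolerance = 1e-12)
  }
  # missing database entries: error by default, zero fallback on request
  empty_db <- structure(list(), class = "internal_adp_db")
  expect_error(subtract_internal(s, empty_db, g, 100))
  u_fb <- suppressWarnings(subtract_internal(s, empty_db, g, 100,
                                             missing_internal = "zero"))
  expect_equal(u_fb[["1"]], atom_adp_cart(s, 1), tolerance = 1e-12)
  # isotropic-only atoms enter as U_iso * I
  s_iso <- s
  s_iso$atoms[1, c("u11", "u22", "u33", "u23", "u13", "u12")] <- NA_real_
  s_iso$atoms$uiso[1] <- 0.025
  u_iso_eff <- suppressMessages(
    subtract_internal(s_iso, zero_db, s_iso |> detect_bonds(), 100))
  expect_equal(u_iso_eff[["1"]], c(0.025, 0.025, 0.025, 0, 0, 0))
})

test_that("external_adp obeys its limiting cases and the MC oracle", {
  zero <- list(T = matrix(0, 3, 3), L = matrix(0, 3, 3), S = matrix(0, 3, 3),
               origin = c(0, 0, 0))
  expect_equal(external_adp(zero, position = c(1, 2, 3)), matrix(0, 3, 3))
  # at the origin the libration lever arm vanishes: pure L gives zero
  pureL <- list(T = matrix(0, 3, 3), L = diag(c(0.01, 0.02, 0.03)),
                S = matrix(0, 3, 3), origin = c(1, 1, 1))
  expect_equal(external_adp(pureL, position = c(1, 1, 1)), matrix(0, 3, 3))
  # random parameters against the Monte-Carlo rigid-motion covariance
  set.seed(33)
  par <- rand_tls_params()
  origin <- c(0.5, -0.2, 0.8)
  r <- c(3.1, -2.0, 1.4)
  arg <- list(axis_point = c(1, 0, 0), axis_dir = c(0, 0.6, 0.8),
              amplitude = 0.012)
  U <- external_adp(list(T = par$T, L = par$L, S = make_traceless(par$S),
                         origin = origin),
                    args = list(arg), position = r, membership = 1L)
  Umc <- mc_external_adp(par$T, par$L, par$S, origin, r, nsamp = 2e5,
                         arg = arg)
  expect_lt(max(abs(U - Umc)) / max(abs(U)), 0.02)
})

test_that("a pure-T world is recovered exactly", {
  ss <- make_structure(synth_spec("rigid_ring", seed = 2,
                                  tls = list(T = 0.02 * diag(3),
                                             L = matrix(0, 3, 3),
                                             S = matrix(0, 3, 3))))
  seg <- segment_molecule(ss$graph, molecules(ss$graph)[[1]],
                          setNames(lapply(which(!ss$structure$atoms$is_h),
                                          function(i) ss$truth$u_ext[[i]]),
                                   which(!ss$structure$atoms$is_h)))
  u_t <- setNames(lapply(which(!ss$structure$atoms$is_h),
                         function(i) ss$truth$u_ext[[i]]),
                  which(!ss$structure$atoms$is_h))
  fit <- fit_tls_arg(u_t, atom_positions(ss$structure), seg)
  expect_equal(fit$tls$T, 0.02 * diag(3), tolerance = 1e-12)
  expect_equal(fit$tls$L, matrix(0, 3, 3), tolerance = 1e-12)
  expect_lt(fit$rms, 1e-12)
})

test_that("all 20 TLS parameters and the group amplitude are recovered", {
  for (seed in c(3, 12)) {
    ss <- make_structure(synth_spec("arg9", tls = "random", seed = seed))
    s <- ss$structure
    u_eff <- subtract_internal(s, ss$db, ss$graph, 100)
    seg <- segment_molecule(ss$graph, molecules(ss$graph)[[1]], u_eff)
    fit <- fit_tls_arg(u_eff, atom_positions(s), seg)
    truth <- ss$truth$tls[[1]]
    expect_equal(fit$tls$T, truth$T, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$tls$L, truth$L, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$tls$S, make_traceless(truth$S), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$args[[1]]$amplitude, 0.01, tolerance = 1e-8)
    expect_lt(fit$rms, 1e-10)
    expect_equal(abs(sum(diag(fit$tls$S))), 0, tolerance = 1e-12)
    # forcing the amplitude to zero must worsen the fit
    seg_rigid <- seg
    seg_rigid$args <- list()
    seg_rigid$body_atoms <- seg$molecule
    fit0 <- fit_tls_arg(u_eff, atom_positions(s), seg_rigid)
    expect_gt(fit0$rms, fit$rms + 1e-6)
  }
})

test_that("fitted ADPs are invariant under the choice of TLS origin", {
  ss <- make_structure(synth_spec("arg9", tls = "random", seed = 21))
  u_eff <- subtract_internal(ss$structure, ss$db, ss$graph, 100)
  seg <- segment_molecule(ss$graph, molecules(ss$graph)[[1]], u_eff)
  pos <- atom_positions(ss$structure)
  fit1 <- fit_tls_arg(u_eff, pos, seg)
  fit2 <- fit_tls_arg(u_eff, pos, seg, origin = fit1$tls$origin + c(2, -1, 3))
  for (k in names(fit1$fitted)) {
    expect_equal(fit1$fitted[[k]], fit2$fitted[[k]], tolerance = 1e-10)
  }
  # T and S compensate the shift (they must differ)
  expect_gt(max(abs(fit1$tls$T - fit2$tls$T)), 1e-6)
})

test_that("parameter recovery error scales with the ADP noise", {
  err_at <- function(sigma, seed) {
    ss <- make_structure(synth_spec("arg9", tls = "random", seed = seed,
                                    noise_sd = sigma))
    u_eff <- subtract_internal(ss$structure, ss$db, ss$graph, 100)
    fit <- fit_tls_arg(u_eff, atom_positions(ss$structure),
                       true_segmentation(ss))
    truth <- ss$truth$tls[[1]]
    max(abs(fit$tls$T - truth$T))
  }
  e_small <- mean(vapply(1:5, function(s) err_at(1e-4, s), numeric(1)))
  e_large <- mean(vapply(1:5, function(s) err_at(1e-3, s), numeric(1)))
  expect_gt(e_large / e_small, 3)
  expect_lt(e_large / e_small, 30)
})

test_that("hydrogen assembly adds external and internal parts", {
  ss <- make_structure(synth_spec("arg9", seed = 3))
  s <- ss$structure
  g <- ss$graph
  u_eff <- subtract_internal(s, ss$db, g, 100)
  seg <- segment_molecule(g, molecules(g)[[1]], u_eff)
  fit <- fit_tls_arg(u_eff, atom_positions(s), seg)
  out <- assemble_hydrogen_adps(s, g, seg, fit, ss$db, 100)
  expect_lt(h_adp_error(out, ss$truth), 1e-8)
  # an H belonging to the librating group gets a strictly larger tensor
  # than the same position evaluated without the membership
  pos <- atom_positions(s)
  hd <- match("HD3", s$atoms$label)
  with_m <- predict(fit, pos[hd, , drop = FALSE], list(1L))[[1]]
  without <- predict(fit, pos[hd, , drop = FALSE])[[1]]
  expect_gt(sum(diag(with_m)), sum(diag(without)))
  ev <- eigen(with_m - without, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
})

test_that("degenerate hydrogen assembly flags non-physical tensors", {
  ss <- make_structure(synth_spec("rigid_ring", seed = 2))
  s <- ss$structure
  g <- ss$graph
  zero_fit <- structure(list(
    tls = list(T = matrix(0, 3, 3), L = matrix(0, 3, 3),
               S = matrix(0, 3, 3), origin = c(0, 0, 0)),
    args = list()), class = "tls_arg_fit")
  zero_db <- ss$db
  for (k in seq_along(zero_db)) zero_db[[k]]$u_local <- rep(0, 6)
  seg <- list(molecule = molecules(g)[[1]],
              body_atoms = molecules(g)[[1]], args = list())
  class(seg) <- "segmentation_model"
  out <- assemble_hydrogen_adps(s, g, seg, zero_fit, zero_db, 100)
  for (i in which(out$atoms$is_h)) {
    expect_equal(atom_adp_cart(out, i), rep(0, 6), tolerance = 1e-12)
  }
})
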