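# CODATA constants for the independent closed-form evaluations
HBAR <- 1.054571817e-34
KB <- 1.380649e-23
CCM <- 2.99792458e10
AMU <- 1.66053906660e-27

test_that("the neutral mode format round-trips exactly", {
  geom <- rbind(c(0, 0, 0), c(0, 0, 1.1))
  nm <- make_mock_modes(geom, c("C", "O"), c(500, 1800), seed = 3,
                        labels = c("C1", "O1"))
  p <- withr::local_tempfile(fileext = ".txt")
  write_modes(nm, p)
  nm2 <- parse_modes(p, "neutral")
  expect_equal(nm2$frequencies, nm$frequencies, tolerance = 1e-9)
  expect_equal(nm2$modes, nm$modes, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(nm2$masses, nm$masses, tolerance = 1e-8)
  expect_equal(nm2$geometry, nm$geometry, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(nm2$labels, c("C1", "O1"))
  # truncated file errors
  txt <- readLines(p)
  pt <- withr::local_tempfile(fileext = ".txt")
  writeLines(txt[1:(length(txt) - 1)], pt)
  expect_error(parse_modes(pt, "neutral"), "truncated|bad mode")
})

test_that("a QM text log yields mass-weighted orthonormal modes", {
  # synthetic log in the common Gaussian frequency-output layout
  p <- withr::local_tempfile(fileext = ".log")
  writeLines(c(
    "                         Standard orientation:",
    " ---------------------------------------------------------------------",
    " Center     Atomic      Atomic             Coordinates (Angstroms)",
    " Number     Number       Type             X           Y           Z",
    " ---------------------------------------------------------------------",
    "      1          6           0        0.000000    0.000000    0.000000",
    "      2          1           0        0.000000    0.000000    1.090000",
    " ---------------------------------------------------------------------",
    " Frequencies --   1000.0000              3000.0000",
    " Red. masses --      1.0000                 1.0000",
    "  Atom  AN      X      Y      Z        X      Y      Z",
    "     1   6     0.10   0.00   0.00     0.00   0.00   0.28",
    "     2   1     0.00   0.00   0.00     0.00   0.00  -0.96"), p)
  nm <- parse_modes(p, "qm_log")
  expect_equal(nm$frequencies, c(1000, 3000))
  expect_equal(nm$elements, c("C", "H"))
  expect_equal(nm$geometry[2, 3], 1.09)
  expect_equal(rowSums(nm$modes^2), c(1, 1), tolerance = 1e-12)
  # mass weighting: mode 1 lives on the C atom only
  expect_equal(nm$modes[1, 4:6], c(0, 0, 0))
  pbad <- withr::local_tempfile(fileext = ".log")
  writeLines("no frequencies here", pbad)
  expect_error(parse_modes(pbad, "qm_log"), "orientation|frequency")
})

test_that("a single mode reproduces the quantum-oscillator closed form", {
  geom <- rbind(c(0, 0, 0), c(0, 0, 1.1))
  nm <- make_mock_modes(geom, c("C", "O"), 1800, seed = 2)
  for (T_K in c(50, 150, 300)) {
    U <- internal_adp(nm, 1, T_K, cutoff = 200)
    omega <- 2 * pi * CCM * 1800
    amp <- HBAR / (2 * 12.011 * AMU * omega) /
      tanh(HBAR * omega / (2 * KB * T_K)) * 1e20
    l <- nm$modes[1, 1:3]
    expect_equal(U, amp * tcrossprod(l), tolerance = 1e-12)
  }
  # T -> 0 limit equals the zero-point amplitude hbar / (2 m omega)
  U0 <- internal_adp(nm, 2, 1e-6, cutoff = 200)
  omega <- 2 * pi * CCM * 1800
  zp <- HBAR / (2 * 15.999 * AMU * omega) * 1e20
  expect_equal(sum(diag(U0)), zp * sum(nm$modes[1, 4:6]^2), tolerance = 1e-9)
  # classical limit: at hbar omega << kB T the amplitude approaches
  # kB T / (m omega^2) within 1 percent
  nml <- make_mock_modes(geom, c("C", "O"), 210, seed = 4)
  Uhot <- internal_adp(nml, 1, 5000, cutoff = 200)
  omega_l <- 2 * pi * CCM * 210
  classical <- KB * 5000 / (12.011 * AMU * omega_l^2) * 1e20
  got <- sum(diag(Uhot)) / sum(nml$modes[1, 1:3]^2)
  expect_lt(abs(got - classical) / classical, 0.01)
  expect_error(internal_adp(nm, 1, -5), "positive")
})

test_that("internal ADPs are PSD, increase with T and decrease with cutoff", {
  geom <- methane_structure()
  pos <- atom_positions(geom)
  nm <- make_mock_modes(pos, geom$atoms$element,
                        c(80, 150, 400, 900, 1500, 2000, 3000, 3100),
                        seed = 7)
  temps <- c(20, 100, 200, 300, 400)
  for (a in c(1, 2, 5)) {
    traces <- vapply(temps, function(T_K) {
      U <- internal_adp(nm, a, T_K)
      ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-12)
      sum(diag(U))
    }, numeric(1))
    expect_true(all(diff(traces) > 0))
    # raising the cutoff can only lower the displacement
    tr_all <- sum(diag(internal_adp(nm, a, 150, cutoff = 0)))
    tr_cut <- sum(diag(internal_adp(nm, a, 150, cutoff = 200)))
    tr_high <- sum(diag(internal_adp(nm, a, 150, cutoff = 1000)))
    expect_gte(tr_all, tr_cut)
    expect_gte(tr_cut, tr_high)
  }
  # temperature-dependence shape: U(T)/U(T0) is convex non-decreasing
  r <- vapply(temps, function(T_K) sum(diag(internal_adp(nm, 2, T_K))),
              numeric(1)) / sum(diag(internal_adp(nm, 2, temps[1])))
  expect_true(all(diff(r) >= -1e-12))
  expect_true(all(diff(diff(r) / diff(temps)) >= -1e-10))
})

test_that("mode normalization conserves the mass-weighted trace sum", {
  geom <- methane_structure()
  pos <- atom_positions(geom)
  freqs <- c(300, 700, 1200, 1800, 2600, 3000)
  nm <- make_mock_modes(pos, geom$atoms$element, freqs, seed = 9)
  T_K <- 120
  lhs <- sum(vapply(seq_len(5), function(a) {
    nm$masses[a] * AMU * sum(diag(internal_adp(nm, a, T_K, cutoff = 0))) / 1e20
  }, numeric(1)))
  rhs <- sum(vapply(freqs, function(nu) {
    omega <- 2 * pi * CCM * nu
    HBAR / (2 * omega) / tanh(HBAR * omega / (2 * KB * T_K))
  }, numeric(1)))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("the database keys, caches and transfers internal ADPs", {
  s <- methane_structure()
  pos <- atom_positions(s)
  nm <- make_mock_modes(pos, s$atoms$element, c(400, 1300, 2900), seed = 5)
  db <- suppressWarnings(
    build_internal_db(list(list(structure = s, modes = nm)), 100))
  expect_true(any(vapply(db, function(e) e$name == "H1c[1h1h1h]", logical(1))))
  # idempotent cache: rebuilding writes byte-identical files
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_internal_db(db, p1)
  db2 <- suppressWarnings(
    build_internal_db(list(list(structure = s, modes = nm)), 100))
  write_internal_db(db2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # cache file round trip
  db3 <- read_internal_db(p1)
  expect_equal(length(db3), length(db))
  for (k in names(db)) {
    expect_equal(db3[[k]]$u_local, db[[k]]$u_local, tolerance = 1e-10)
  }
  # hotter database entries are uniformly larger
  db_cold <- suppressWarnings(
    build_internal_db(list(list(structure = s, modes = nm)), 50))
  db_hot <- suppressWarnings(
    build_internal_db(list(list(structure = s, modes = nm)), 300))
  for (nme in vapply(db_cold, function(e) e$name, character(1))) {
    uc <- Filter(function(e) e$name == nme, db_cold)[[1]]$u_local
    uh <- Filter(function(e) e$name == nme, db_hot)[[1]]$u_local
    expect_gt(sum(uh[1:3]), sum(uc[1:3]))
  }
})

test_that("frame transfer preserves eigenvalues and round-trips", {
  s <- methane_structure()
  pos <- atom_positions(s)
  nm <- make_mock_modes(pos, s$atoms$element, c(400, 1300, 2900), seed = 5)
  g <- detect_bonds(s)
  db <- suppressWarnings(
    build_internal_db(list(list(structure = s, modes = nm)), 100))
  # identity frame returns the stored tensor unchanged
  e <- db_entry <- Filter(function(x) x$name == "H1c[1h1h1h]", db)[[1]]
  ident <- structure(list(origin = 1L, rotation = diag(3)),
                     class = "local_frame")
  expect_equal(as.numeric(transfer_internal_adp(db, e$name, ident, 100)),
               e$u_local, tolerance = 1e-12)
  # arbitrary rotations preserve eigenvalues
  set.seed(23)
  R <- rand_rotation()
  fr <- structure(list(origin = 1L, rotation = R), class = "local_frame")
  ur <- mat6(as.numeric(transfer_internal_adp(db, e$name, fr, 100)))
  expect_equal(sort(eigen(ur, symmetric = TRUE)$values),
               sort(eigen(mat6(e$u_local), symmetric = TRUE)$values),
               tolerance = 1e-12)
  # transferring back through the donor frame reproduces the donor tensor
  donor <- 2L  # first H of methane (the db donor for this name)
  fr_d <- local_frame(g, donor)
  u_back <- mat6(as.numeric(transfer_internal_adp(db, e$name, fr_d, 100)))
  expect_equal(u_back, internal_adp(nm, donor, 100), tolerance = 1e-10)
  # missing key lists available names; nearby temperature accepted
  expect_error(transfer_internal_adp(db, "H1n[1c]", ident, 100), "available")
  expect_error(transfer_internal_adp(db, e$name, ident, 200), "available")
  expect_equal(as.numeric(transfer_internal_adp(db, e$name, ident, 100.6)),
               e$u_local, tolerance = 1e-12)
})
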