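# Spin centers, ensemble distances, vector deviations, SASA, chi deviation,
# contacts.

test_that("spin-center rules behave and differ by half the N1-O1 bond", {
  at <- rbind(N1 = c(1, 1, 1), O1 = c(1, 1, 3))
  expect_equal(spin_center(at, "N1"), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(spin_center(at, "NO_midpoint"), c(1, 1, 2),
               ignore_attr = TRUE)
  conf <- build_label(ideal_backbone(), c(-60, 180, -90, 100, 10))
  d <- sqrt(sum((spin_center(conf, "N1") -
                   spin_center(conf, "NO_midpoint"))^2))
  no <- sqrt(sum((conf$atoms["N1", ] - conf$atoms["O1", ])^2))
  expect_equal(d, no / 2, tolerance = 1e-12)
  expect_error(spin_center(rbind(X = c(0, 0, 0)), "N1"), "N1")
})

test_that("mean spin position is the brute-force weighted sum", {
  withr::local_seed(14)
  ctr <- matrix(rnorm(60, sd = 8), 20)
  w <- runif(20); w <- w / sum(w)
  ens <- fake_ensemble(ctr, w)
  expected <- colSums(ctr * w)
  expect_equal(mean_spin_position(ens, "N1"), expected, tolerance = 1e-12)
  # degenerate weights pick out a single conformer
  ens2 <- fake_ensemble(ctr[1:2, ], c(1, 0))
  expect_equal(mean_spin_position(ens2, "N1"), ctr[1, ], tolerance = 1e-12)
})

test_that("ensemble distances: singleton anchors, translation equivariance, brute-force moments", {
  a <- fake_ensemble(matrix(c(0, 0, 0), 1))
  b <- fake_ensemble(matrix(c(20, 0, 0), 1))
  ed <- ensemble_distance(a, b, rule = "N1")
  expect_equal(ed$mean_position_distance, 20)
  expect_equal(nrow(ed$distribution), 1L)
  expect_equal(ed$pair_sd, 0)

  withr::local_seed(2)
  ca <- matrix(rnorm(36, sd = 3), 12)
  cb <- sweep(matrix(rnorm(30, sd = 3), 10), 2, c(25, 0, 0), `+`)
  wa <- runif(12); wa <- wa / sum(wa)
  wb <- runif(10); wb <- wb / sum(wb)
  ea <- fake_ensemble(ca, wa); eb <- fake_ensemble(cb, wb)
  ed <- ensemble_distance(ea, eb, rule = "N1")
  # oracle: explicit double loop over all pairs
  pm <- 0; pm2 <- 0
  for (i in 1:12) for (j in 1:10) {
    d <- sqrt(sum((ca[i, ] - cb[j, ])^2))
    pm <- pm + wa[i] * wb[j] * d
    pm2 <- pm2 + wa[i] * wb[j] * d^2
  }
  expect_equal(ed$pair_mean, pm, tolerance = 1e-9)
  expect_equal(ed$pair_sd, sqrt(pm2 - pm^2), tolerance = 1e-9)
  expect_equal(sum(ed$distribution$probability), 1, tolerance = 1e-9)
  # translating b along the inter-mean axis adds exactly that distance
  mu_a <- colSums(ca * wa); mu_b <- colSums(cb * wb)
  axis <- (mu_b - mu_a) / sqrt(sum((mu_b - mu_a)^2))
  eb5 <- fake_ensemble(sweep(cb, 2, 5 * axis, `+`), wb)
  ed5 <- ensemble_distance(ea, eb5, rule = "N1")
  expect_equal(ed5$mean_position_distance, ed$mean_position_distance + 5,
               tolerance = 1e-9)
  # the mean-position distance is bracketed by the pairwise extremes
  expect_gte(ed$mean_position_distance, min(ed$distribution$distance) - 0.5)
  expect_lte(ed$mean_position_distance, max(ed$distribution$distance) + 0.5)
})

test_that("vector angle deviation matches arccos of the normalized dot product", {
  v <- rbind(c(0, 0, 0), c(1, 2, 3))
  expect_equal(vector_angle_deviation(v, v), 0)
  expect_equal(vector_angle_deviation(v, rbind(c(5, 5, 5),
                                               c(5, 5, 5) - c(1, 2, 3))),
               180)
  withr::local_seed(8)
  for (i in 1:50) {
    a <- matrix(rnorm(6), 2); b <- matrix(rnorm(6), 2)
    va <- a[2, ] - a[1, ]; vb <- b[2, ] - b[1, ]
    expected <- acos(sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))) * 180 / pi
    expect_equal(vector_angle_deviation(a, b), expected, tolerance = 1e-9)
  }
  expect_error(vector_angle_deviation(rbind(c(0, 0, 0), c(0, 0, 0)), v),
               "zero-length")
})

test_that("SASA reproduces the analytic sphere and two-sphere closed forms", {
  m1 <- one_atom_model(matrix(c(0, 0, 0), 1))
  r <- 1.7 + 1.4
  s1 <- sasa(m1, 1L)
  expect_equal(s1$total_asa, 4 * pi * r^2, tolerance = 0.02 * 4 * pi * r^2)
  expect_equal(s1$buried_asa, 0)
  # two identical atoms far apart: full spheres, nothing buried
  m2 <- one_atom_model(rbind(c(0, 0, 0), c(100, 0, 0)))
  s2 <- sasa(m2, 1:2)
  expect_equal(s2$total_asa, 2 * 4 * pi * r^2,
               tolerance = 0.02 * 8 * pi * r^2)
  expect_equal(s2$buried_asa, 0)
  # overlapping spheres at several separations vs. the cap formula;
  # different chains so the pair also exercises buried-area bookkeeping
  for (d in c(2.0, 3.5, 5.0)) {
    mo <- one_atom_model(rbind(c(0, 0, 0), c(d, 0, 0)))
    mo$atoms$chain <- c("A", "B")
    so <- sasa(mo, 1L)
    expected <- oracle_two_sphere_area(r, r, d)
    expect_equal(so$total_asa, expected, tolerance = 0.02 * expected)
    expect_equal(so$buried_asa, 4 * pi * r^2 - expected,
                 tolerance = 0.02 * 4 * pi * r^2)
  }
  expect_error(sasa(m1, rep(FALSE, 1)), "empty")
})

test_that("SASA quadrature is converged at the default point count", {
  open <- make_open_site()
  sel <- which(open$model$atoms$resno %in% 5:12)  # ~40 atoms
  a1 <- sasa(open$model, sel, n_points = 480)$total_asa
  a2 <- sasa(open$model, sel, n_points = 960)$total_asa
  expect_lt(abs(a2 - a1) / a2, 0.01)
})

test_that("buried area is bounded by the isolated-sphere sum", {
  tight <- make_tight_site()
  sel <- which(tight$model$atoms$chain == "A" &
                 tight$model$atoms$resno == tight$site$resno)
  sr <- sasa(tight$model, sel)
  iso <- sum(4 * pi * (tight$model$atoms$vdw[sel] + sr$probe)^2)
  expect_gte(sr$buried_asa, 0)
  expect_lte(sr$buried_asa, iso)
})

test_that("chi deviation handles wraparound, exact hits, and matches exhaustive search", {
  lib <- make_synthetic_library(50, seed = 21)
  hit <- as.numeric(lib$entries[17, 1:5])
  cd <- chi_deviation(hit, lib)
  expect_equal(cd$max_abs_delta, 0, tolerance = 1e-12)
  expect_equal(cd$delta, rep(0, 5), tolerance = 1e-12, ignore_attr = TRUE)
  # wraparound: 179 vs -179 is 2 degrees
  two <- rotamer_library(rbind(c(-179, 0, 0, 0, 0), c(100, 0, 0, 0, 0)))
  cd2 <- chi_deviation(c(179, 0, 0, 0, 0), two)
  expect_equal(cd2$nearest, 1L)
  expect_equal(cd2$max_abs_delta, 2)
  withr::local_seed(3)
  for (i in 1:20) {
    obs <- runif(5, -180, 180)
    cd3 <- chi_deviation(obs, lib)
    worst <- apply(abs(circular_diff(as.matrix(lib$entries[, 1:5]),
                                     matrix(obs, 50, 5, byrow = TRUE))),
                   1, max)
    expect_equal(cd3$nearest, which.min(worst))
    expect_equal(cd3$max_abs_delta, min(worst), tolerance = 1e-12)
  }
  # permutation invariance of the library rows
  perm <- lib
  perm$entries <- perm$entries[50:1, ]
  obs <- c(10, 20, 30, 40, 50)
  expect_equal(chi_deviation(obs, lib)$max_abs_delta,
               chi_deviation(obs, perm)$max_abs_delta, tolerance = 1e-12)
  # convention guard
  libc9 <- make_synthetic_library(10, seed = 1)
  libc9$metadata$chi5_convention <- "SD-CE-C3-C9"
  expect_error(chi_deviation(obs, libc9, convention = "SD-CE-C3-C4"),
               "convention mismatch")
})

test_that("contact listing matches brute-force classification and sees polar bridges", {
  # lone residue: no contacts
  m <- make_helix(8)
  lone <- m
  lone$atoms <- lone$atoms[lone$atoms$resno == 4, ]
  expect_equal(nrow(contacts(lone, "A", 4)), 0L)
  # an ordered water 2.8 A from a backbone O: one polar contact
  o <- as.numeric(m$atoms[m$atoms$resno == 4 & m$atoms$name == "O",
                          c("x", "y", "z")])
  wat <- data.frame(record = "HETATM", serial = 999L, name = "O",
                    altloc = "", resname = "HOH", chain = "W", resno = 1L,
                    icode = "", x = o[1] + 2.8, y = o[2], z = o[3],
                    occ = 1, b = 0, element = "O", vdw = 1.52,
                    stringsAsFactors = FALSE)
  m2 <- m; m2$atoms <- rbind(m2$atoms, wat)
  cl <- contacts(m2, "A", 4)
  pol <- cl[cl$type == "polar" & cl$partner_resname == "HOH", ]
  expect_equal(nrow(pol), 1L)
  expect_equal(pol$distance, 2.8, tolerance = 1e-9)
  expect_false(pol$same_chain)
  # random cluster vs. brute force
  withr::local_seed(17)
  at <- m2$atoms
  own <- at[at$chain == "A" & at$resno == 4 & at$element != "H", ]
  oth <- at[!(at$chain == "A" & at$resno == 4) & at$element != "H", ]
  n_expected <- 0L
  for (i in seq_len(nrow(own))) for (j in seq_len(nrow(oth))) {
    d <- sqrt(sum((c(own$x[i], own$y[i], own$z[i]) -
                     c(oth$x[j], oth$y[j], oth$z[j]))^2))
    polar <- own$element[i] %in% c("N", "O") &&
      oth$element[j] %in% c("N", "O") && d < 3.5
    if (polar || d < own$vdw[i] + oth$vdw[j] + 0.5)
      n_expected <- n_expected + 1L
  }
  expect_equal(nrow(contacts(m2, "A", 4)), n_expected)
})
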