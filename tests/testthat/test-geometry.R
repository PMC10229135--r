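rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
         3, 3, byrow = TRUE)
}

base_frame <- function() {
  rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0), c(0.75, 0.4, 1.2),
        c(-0.5, 0.8, 0.5))
}

test_that("Kabsch superposition recovers rigid transforms to machine precision", {
  ref <- base_frame()
  id <- superpose_kabsch(ref, ref)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  set.seed(2)
  for (i in 1:20) {
    R <- rand_rotation()
    mob <- sweep(ref %*% t(R), 2, rnorm(3, 0, 5), `+`)
    sp <- superpose_kabsch(ref, mob)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    # re-applying the transform and recomputing reproduces the RMSD
    moved <- sp$transform(mob)
    expect_equal(sqrt(mean(rowSums((moved - ref)^2))), sp$rmsd,
                 tolerance = 1e-10)
  }
  expect_error(superpose_kabsch(ref[1:2, ], ref[1:2, ]), ">= 3")
  line <- cbind(0:3, 0, 0)
  expect_error(superpose_kabsch(line, line), "collinear")
})

test_that("translated copies: unfitted RMSD is the shift, fitted RMSD is zero", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))  # unit right triangle
  shifted <- sweep(tri, 2, c(1, 0, 0), `+`)
  co <- array(NA_real_, c(2, 3, 3))
  co[1, , ] <- tri; co[2, , ] <- shifted
  tr2 <- trajectory(co)
  expect_equal(rmsd_series(tr2, fit = FALSE)[2], 1.0)
  expect_lt(rmsd_series(tr2, fit = TRUE)[2], 1e-9)
})

test_that("RMSD series: reference frame zero, rigid motion removed by fitting", {
  tr <- make_reference_trajectory("rigid_motion", n_frames = 12,
                                  seed = 3)
  fitted <- rmsd_series(tr)
  expect_equal(fitted[1], 0, tolerance = 1e-10)
  expect_true(all(fitted < 1e-9))
  unfitted <- rmsd_series(tr, fit = FALSE)
  expect_true(all(unfitted[-1] > 0.1))
})

test_that("RMSD of a known displacement matches the brute-force formula", {
  co <- array(NA_real_, c(2, 6, 3))
  base <- rbind(base_frame(), c(2, 1, 0.8))
  co[1, , ] <- base
  moved <- base; moved[6, ] <- moved[6, ] + c(0, 0, 2)
  co[2, , ] <- moved
  tr <- trajectory(co)
  # fit on the five static atoms, measure all six: RMSD = d / sqrt(6)
  r <- rmsd_series(tr, fit_selection = 1:5)
  expect_equal(r[2], 2 / sqrt(6), tolerance = 1e-9)
  # measured on the displaced atom only: exactly d (needs >= 1 atom)
  r6 <- rmsd_series(tr, fit_selection = 1:5, measure_selection = 6)
  expect_equal(r6[2], 2, tolerance = 1e-9)
})

test_that("RMSF oracles: static zero, symmetric oscillation amplitude, rigid invariance", {
  st <- make_reference_trajectory("static", 10)
  expect_equal(unname(rmsf(st)), rep(0, 6), tolerance = 1e-10)
  osc <- make_reference_trajectory("single_atom_oscillation",
                                   n_frames = 10, amplitude = 0.8)
  f <- rmsf(osc, selection = 1:6, fit_selection = 1:5)
  expect_equal(unname(f[6]), 0.8, tolerance = 1e-9)
  expect_true(all(f[1:5] < 1e-10))
  # applying one global rigid motion to every frame changes nothing
  set.seed(7)
  R <- rand_rotation(); shift <- rnorm(3, 0, 4)
  co <- osc$coords
  for (fr in seq_len(dim(co)[1]))
    co[fr, , ] <- sweep(co[fr, , ] %*% t(R), 2, shift, `+`)
  f2 <- rmsf(trajectory(co), selection = 1:6, fit_selection = 1:5)
  expect_equal(unname(f2), unname(f), tolerance = 1e-9)
  expect_error(rmsf(make_reference_trajectory("static", 1)), "single frame")
})

test_that("dihedral angles follow the signed atan2 convention", {
  cis <- rbind(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1.5), c(1, 0, 2.5))
  trans <- rbind(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1.5), c(-1, 0, 2.5))
  expect_equal(dihedral_series(trajectory(cis), 1:4), 0)
  expect_equal(dihedral_series(trajectory(trans), 1:4), 180)
  # explicit 60-degree construction
  th <- pi / 3
  p60 <- rbind(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1.5),
               c(cos(th), sin(th), 2.5))
  expect_equal(dihedral_series(trajectory(p60), 1:4), 60,
               tolerance = 1e-6)
  # mirror reflection flips the sign
  mir <- p60; mir[, 1] <- -mir[, 1]
  expect_equal(dihedral_series(trajectory(mir), 1:4), -60,
               tolerance = 1e-6)
  sweep19 <- make_reference_trajectory("torsion_sweep", 19)
  expect_equal(dihedral_series(sweep19, 1:4), seq(0, 180, by = 10),
               tolerance = 1e-9)
  coll <- rbind(c(0, 0, -1), c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  expect_error(dihedral_series(trajectory(coll), 1:4), "collinear")
})

test_that("distance series covers atom and centroid modes", {
  co <- array(NA_real_, c(1, 4, 3))
  co[1, , ] <- rbind(c(0, 0, 0), c(3, 4, 0), c(-1, 0, 0), c(1, 0, 0))
  tr <- trajectory(co)
  expect_equal(distance_series(tr, 1, 2, mode = "atom"), 5)
  expect_equal(distance_series(tr, 1, 1, mode = "atom"), 0)
  # centroid of atoms at +/-1 on x sits at the origin
  expect_equal(distance_series(tr, c(3, 4), 1, mode = "centroid"), 0)
  expect_error(distance_series(tr, integer(0), 1), "selection")
  expect_error(distance_series(tr, c(1, 2), 3, mode = "atom"),
               "single-atom")
})

test_that("fitted RMSD never exceeds unfitted RMSD and is symmetric", {
  set.seed(9)
  for (i in 1:10) {
    a <- matrix(rnorm(15), 5, 3)
    b <- a + matrix(rnorm(15, 0, 0.3), 5, 3)
    sab <- superpose_kabsch(a, b)$rmsd
    sba <- superpose_kabsch(b, a)$rmsd
    expect_equal(sab, sba, tolerance = 1e-9)
    unfitted <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(sab, unfitted + 1e-12)
  }
})

test_that("superposition RMSD agrees with the bio3d reference implementation", {
  library(bio3d)
  set.seed(13)
  a <- matrix(rnorm(24), 8, 3)
  b <- a %*% t(rand_rotation()) + matrix(rnorm(24, 0, 0.2), 8, 3)
  ours <- superpose_kabsch(a, b)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                        fit = TRUE)
  expect_lt(abs(ours - theirs), 5e-4)  # bio3d rounds to 3 decimals
  # torsion cross-check
  th <- 1.234
  p <- rbind(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1.5),
             c(cos(th), sin(th), 2.5))
  ours_t <- dihedral_series(trajectory(p), 1:4)
  theirs_t <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
  expect_equal(abs(ours_t), abs(theirs_t[!is.na(theirs_t)]),
               tolerance = 1e-6)
})
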