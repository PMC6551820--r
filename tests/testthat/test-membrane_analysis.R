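# Leaflet split, thickness maps, bulk reference, mismatch calculus.

flat_bilayer <- function(pp = 31.6, n_frames = 1, noise = 0, seed = 1,
                         dent = 0, dent_sigma = 10) {
  generate_trajectory(synthetic_config(
    bulk_pp_thickness = pp, bulk_hydrophobic_thickness = pp - 11.3,
    dent_amplitude = dent, dent_sigma = dent_sigma,
    noise_sigma = noise, n_frames = n_frames, seed = seed))
}

test_that("leaflet split partitions the marker lattice 200/200", {
  gen <- flat_bilayer()
  sp <- split_leaflets(gen$traj, "name P")
  expect_length(sp$upper, 200L)
  expect_length(sp$lower, 200L)
  expect_length(intersect(sp$upper, sp$lower), 0L)
  expect_equal(sp$midplane_z[1], 0, tolerance = 1e-9)
  expect_error(split_leaflets(gen$traj, "name NOPE"), "marker")
})

test_that("jittered markers keep their noise-free leaflet labels", {
  clean <- flat_bilayer()
  noisy <- flat_bilayer(noise = 1, n_frames = 3, seed = 8)
  sp0 <- split_leaflets(clean$traj, "name P")
  sp1 <- split_leaflets(noisy$traj, "name P")
  expect_identical(sort(sp0$upper), sort(sp1$upper))
  expect_identical(sort(sp0$lower), sort(sp1$lower))
})

test_that("a one-sided marker set is a degenerate bilayer", {
  gen <- flat_bilayer()
  traj <- gen$traj
  pidx <- select_atoms(traj, "name P")
  traj$xyz[pidx, 3, ] <- abs(traj$xyz[pidx, 3, ])  # everything upper
  expect_error(split_leaflets(traj, "name P"), "degenerate")
})

test_that("flat bilayers give uniform maps at the three P-P thicknesses", {
  for (pp in c(31.6, 38.7, 47.3)) {
    gen <- flat_bilayer(pp = pp)
    map <- thickness_map(gen$traj, split_leaflets(gen$traj, "name P"))
    expect_lt(max(abs(map$thickness - pp)), 0.05)
  }
})

test_that("the hydrophobic (chain alpha-carbon) surface maps equally", {
  gen <- flat_bilayer(pp = 38.7)
  map <- thickness_map(gen$traj, split_leaflets(gen$traj, "name C22,C32"))
  expect_lt(max(abs(map$thickness - 27.4)), 0.05)
})

test_that("a Gaussian dent is recovered at the center cell", {
  gen <- flat_bilayer(pp = 38.7, dent = -4)
  map <- thickness_map(gen$traj, split_leaflets(gen$traj, "name P"))
  icx <- which.min(abs(map$cell_x - gen$truth$box[1] / 2))
  icy <- which.min(abs(map$cell_y - gen$truth$box[2] / 2))
  expect_equal(map$thickness[icx, icy], 38.7 - 4, tolerance = 0.2)
  # closed-form dent profile at every occupied cell
  occ <- which(map$occupancy_upper > 0 & map$occupancy_lower > 0,
               arr.ind = TRUE)
  want <- expected_thickness(gen$truth, map$cell_x[occ[, 1]],
                             map$cell_y[occ[, 2]])
  got <- map$thickness[occ]
  # markers sit up to half a cell diagonal (~2.3 A) from the cell center;
  # on a 4 A, sigma = 10 A dent that moves the profile by up to ~0.5 A
  expect_lt(max(abs(got - want)), 0.5)
})

test_that("fill policies handle empty cells", {
  gen <- flat_bilayer()
  sp <- split_leaflets(gen$traj, "name P")
  m_none <- thickness_map(gen$traj, sp, fill = "none")
  expect_true(any(is.na(m_none$thickness)))
  expect_true(all(is.na(m_none$thickness[m_none$occupancy_upper == 0])))
  for (f in c("nearest", "idw")) {
    m <- thickness_map(gen$traj, sp, fill = f)
    expect_false(any(is.na(m$thickness)))
    expect_lt(max(abs(m$thickness - 31.6)), 0.05)
  }
  expect_error(thickness_map(gen$traj, sp, spacing = 80), "grid")
})

test_that("map occupancy conserves marker count x frame count", {
  gen <- flat_bilayer(n_frames = 4, noise = 0.5, seed = 2)
  sp <- split_leaflets(gen$traj, "name P")
  map <- thickness_map(gen$traj, sp)
  expect_equal(sum(map$occupancy_upper) + sum(map$occupancy_lower),
               400L * 4L)
})

test_that("bulk thickness reads the far field, not the dent", {
  gen <- flat_bilayer(pp = 38.7, dent = -4)
  map <- thickness_map(gen$traj, split_leaflets(gen$traj, "name P"))
  foot <- protein_footprint(gen$traj)
  expect_equal(bulk_thickness(map, foot), 38.7, tolerance = 0.1)
  # uniform map: any far_fraction returns the uniform value
  flat <- flat_bilayer(pp = 31.6)
  fm <- thickness_map(flat$traj, split_leaflets(flat$traj, "name P"))
  for (ff in c(0.1, 0.5, 1.0)) {
    expect_equal(bulk_thickness(fm, protein_footprint(flat$traj), ff), 31.6,
                 tolerance = 1e-6)
  }
  # far_fraction = 1 is the occupancy-weighted global mean
  g <- expand.grid(ix = seq_len(map$nx), iy = seq_len(map$ny))
  occ <- (map$occupancy_upper + map$occupancy_lower)[cbind(g$ix, g$iy)]
  th <- map$thickness[cbind(g$ix, g$iy)]
  expect_equal(bulk_thickness(map, foot, 1.0),
               sum(pmax(occ, 1) * th) / sum(pmax(occ, 1)), tolerance = 1e-9)
})

test_that("lateral translation leaves thickness statistics unchanged", {
  gen <- flat_bilayer(pp = 38.7, dent = -4, noise = 0.3, n_frames = 3,
                      seed = 4)
  shift <- c(13.7, -21.2)
  shifted <- gen$traj
  shifted$xyz[, 1, ] <- shifted$xyz[, 1, ] + shift[1]
  shifted$xyz[, 2, ] <- shifted$xyz[, 2, ] + shift[2]
  m1 <- thickness_map(gen$traj, split_leaflets(gen$traj, "name P"))
  m2 <- thickness_map(shifted, split_leaflets(shifted, "name P"))
  b1 <- bulk_thickness(m1, protein_footprint(gen$traj))
  b2 <- bulk_thickness(m2, protein_footprint(shifted))
  expect_lt(abs(b1 - b2), 0.05)
  expect_lt(abs(mean(m1$thickness) - mean(m2$thickness)), 0.05)
  expect_lt(abs(min(m1$thickness) - min(m2$thickness)), 0.3)
})

test_that("halving the grid spacing barely moves the bulk estimate", {
  gen <- flat_bilayer(pp = 38.7, dent = -4)
  sp <- split_leaflets(gen$traj, "name P")
  foot <- protein_footprint(gen$traj)
  b1 <- bulk_thickness(thickness_map(gen$traj, sp, spacing = 3.3), foot)
  b2 <- bulk_thickness(thickness_map(gen$traj, sp, spacing = 1.65), foot)
  expect_lt(abs(b1 - b2), 0.1)
})

test_that("hydrophobic length follows the 1.5 A per residue rule", {
  expect_equal(hydrophobic_length(17), 25.5)
  expect_equal(hydrophobic_length(23), 34.5)
  expect_equal(hydrophobic_length(29), 43.5)
  expect_equal(hydrophobic_length(20), 30)
  expect_equal(hydrophobic_length(0), 0)
  expect_error(hydrophobic_length(-1), "non-negative")
  expect_error(hydrophobic_length(2.5), "integer")
})

test_that("mismatch labels follow the sign convention", {
  pos <- mismatch_report(43.5, 20.0)
  expect_equal(pos$mismatch, 23.5)
  expect_equal(pos$label, "positive")
  neg <- mismatch_report(25.5, 35.7)
  expect_equal(neg$mismatch, -10.2)
  expect_equal(neg$label, "negative")
  expect_equal(mismatch_report(27.4, 27.4)$label, "matched")
  expect_equal(mismatch_report(27.9, 27.4)$label, "matched")  # deadband
  expect_equal(mismatch_report(27.9, 27.4, tolerance = 0.1)$label,
               "positive")
})

test_that("perturbation map is thickness minus bulk", {
  gen <- flat_bilayer(pp = 38.7, dent = -4)
  map <- thickness_map(gen$traj, split_leaflets(gen$traj, "name P"))
  bulk <- bulk_thickness(map, protein_footprint(gen$traj))
  pert <- perturbation_map(map, bulk)
  expect_equal(pert, map$thickness - bulk)
  expect_lt(min(pert), -3)   # the dent shows up
  expect_gt(max(pert), -0.5) # far field is flat
})
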