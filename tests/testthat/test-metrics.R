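test_that("hollow cylinder geometry is recovered within a voxel", {
  n <- 64; apix <- 4
  ax <- (seq_len(n) - (n / 2 + 1)) * apix
  r2d <- sqrt(outer(ax^2, ax^2, `+`))
  vals <- array(rep((r2d >= 75 & r2d <= 110) * 1, n), c(n, n, n))
  g <- helix_geometry(density_map(vals, apix), threshold = 0.5)
  expect_lt(abs(g$outer_diameter - 220), apix + 1e-9)
  expect_lt(abs(g$lumen_diameter - 150), 1.6 * apix)
  expect_gt(abs(g$axis[3]), 0.99) # axis along z
})

test_that("helix geometry is invariant under rigid rotation of the map", {
  m <- render_reference(demo_lattice(), demo_asym_unit(), 96, 4)
  g0 <- helix_geometry(m)
  # rotate the volume 90 degrees about y (lattice-exact up to half a voxel)
  n <- 96
  rot <- aperm(m$values[, , n:1], c(3, 2, 1))
  g1 <- helix_geometry(density_map(rot, 4))
  expect_lt(abs(g1$outer_diameter - g0$outer_diameter), 2 * 4)
  expect_lt(abs(g1$lumen_diameter - g0$lumen_diameter), 2 * 4)
  expect_gt(abs(g1$axis[1]), 0.99) # axis now along x
})

test_that("lattice groove follows pitch minus envelope exactly", {
  lat <- helical_lattice(rise = 15, twist = -36, radius = 60) # pitch 150
  gs <- groove_and_spacing(lat, envelope_extent = 80)
  expect_equal(gs$pitch, 150)
  expect_equal(gs$groove, 70)
})

test_that("site spacing doubles when all lattice dimensions double", {
  lat <- helical_lattice(rise = 15, twist = -49, radius = 92.5)
  lat2 <- helical_lattice(rise = 30, twist = -49, radius = 185)
  a <- groove_and_spacing(lat, envelope_extent = 40)
  b <- groove_and_spacing(lat2, envelope_extent = 80)
  expect_equal(b$site_spacing, 2 * a$site_spacing, tolerance = 1e-12)
  expect_equal(b$groove, 2 * a$groove, tolerance = 1e-12)
})

test_that("zinc-to-zinc spacing of adjacent units matches the lattice chord", {
  mod <- synthetic_zinc_model()
  gs <- groove_and_spacing(mod, selector = list(element = "ZN"))
  lat <- demo_lattice()
  r_site <- sqrt((lat$radius - 3)^2 + 2^2) # cylindrical radius of the zinc
  expected <- groove_and_spacing(lat, envelope_extent = 40,
                                 site_radius = r_site)$site_spacing
  expect_lt(abs(gs$site_spacing - expected) / expected, 0.02)
  # scale equivariance
  gs2 <- groove_and_spacing(synthetic_zinc_model(scale = 2),
                            selector = list(element = "ZN"))
  expect_equal(gs2$site_spacing, 2 * gs$site_spacing, tolerance = 1e-9)
})

test_that("an empty selector names the available atoms", {
  mod <- synthetic_zinc_model()
  expect_error(groove_and_spacing(mod, selector = list(element = "AU")),
               "Available elements")
})

test_that("non-contacting chain groups bury exactly zero area", {
  atoms <- data.frame(chain = c("A", "B"), resno = 1:2, atom = "C",
                      element = "C", x = c(0, 50), y = 0, z = 0)
  mod <- coordinate_model(atoms)
  expect_identical(buried_interface_area(mod, "A", "B"), 0)
})

test_that("two-carbon toy interface matches the spherical-cap oracle within 1%", {
  d <- 4
  atoms <- data.frame(chain = c("A", "B"), resno = 1:2, atom = "C",
                      element = "C", x = c(0, d), y = 0, z = 0)
  mod <- coordinate_model(atoms)
  got <- buried_interface_area(mod, "A", "B", probe = 1.4,
                               points_per_atom = 960)
  # closed form: each sphere of radius r = 1.7 + 1.4 loses a cap of height
  # h = r - d/2; buried = (2 * 2 pi r h) / 2
  r <- 1.7 + 1.4
  h <- r - d / 2
  oracle <- 2 * pi * r * h
  expect_lt(abs(got - oracle) / oracle, 0.01)
})

test_that("interface area is symmetric in the two groups", {
  mod <- synthetic_zinc_model(n_units = 2)
  ab <- buried_interface_area(mod, "A", "B")
  ba <- buried_interface_area(mod, "B", "A")
  expect_identical(ab, ba)
})

test_that("unknown elements are reported by name", {
  atoms <- data.frame(chain = c("A", "B"), resno = 1:2, atom = "X",
                      element = c("C", "XX"), x = c(0, 3), y = 0, z = 0)
  mod <- coordinate_model(atoms)
  expect_error(buried_interface_area(mod, "A", "B"), "XX")
})

test_that("sequence masses match textbook values and are additive", {
  expect_equal(sequence_average_mass(""), 18.01528, tolerance = 1e-6)
  expect_equal(sequence_average_mass("G"), 75.07, tolerance = 0.01)
  a <- "WSHPQFEK"
  b <- "GAVLIMFWP"
  expect_equal(sequence_average_mass(paste0(a, b)),
               sequence_average_mass(a) + sequence_average_mass(b) - 18.01528,
               tolerance = 1e-9)
  expect_error(sequence_average_mass("ACDX"), "position 4")
})

test_that("mutation counts bucket residues exactly once", {
  rng <- domain_ranges(pro = c(22, 60), M12A = c(61, 260), MAM = c(261, 430),
                       MATH = c(431, 600))
  expect_equal(sum(mutations_per_domain(integer(0), rng)), 0L)
  one <- mutations_per_domain(c(700, 10), rng)
  expect_equal(unname(one["unassigned"]), 2L)
  set.seed(6)
  res <- sample(1:700, 200, replace = TRUE)
  got <- mutations_per_domain(res, rng)
  # brute-force membership oracle
  brute <- c(pro = sum(res >= 22 & res <= 60),
             M12A = sum(res >= 61 & res <= 260),
             MAM = sum(res >= 261 & res <= 430),
             MATH = sum(res >= 431 & res <= 600))
  brute <- c(brute, unassigned = length(res) - sum(brute))
  expect_equal(as.integer(got), as.integer(brute))
  expect_equal(sum(got), 200L)
  expect_error(domain_ranges(a = c(1, 10), b = c(5, 20)), "overlap")
})
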