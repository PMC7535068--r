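carbon <- function(x, y, z) data.frame(x = x, y = y, z = z, radius = 1.7)

test_that("an isolated sphere reproduces its closed-form area", {
  s <- shrake_rupley_sasa(carbon(0, 0, 0))
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(s$total_area - exact) / exact, 0.01)
  expect_equal(s$total_area, sum(s$per_atom_area))
})

test_that("two far-apart atoms are additive", {
  s <- shrake_rupley_sasa(rbind(carbon(0, 0, 0), carbon(100, 0, 0)))
  one <- shrake_rupley_sasa(carbon(0, 0, 0))
  expect_equal(s$total_area, 2 * one$total_area, tolerance = 1e-12)
})

test_that("an atom caged by neighbours has zero accessible area", {
  cage <- sphere_points(60) * 3.0
  atoms <- rbind(carbon(0, 0, 0),
                 data.frame(x = cage[, 1], y = cage[, 2], z = cage[, 3],
                            radius = 1.7))
  s <- shrake_rupley_sasa(atoms)
  expect_equal(s$per_atom_area[1], 0)
})

test_that("per-atom areas never exceed the free-sphere bound", {
  set.seed(5)
  atoms <- data.frame(x = runif(30, 0, 10), y = runif(30, 0, 10),
                      z = runif(30, 0, 10), radius = 1.7)
  s <- shrake_rupley_sasa(atoms, n_sphere_points = 240)
  expect_true(all(s$per_atom_area >= 0))
  expect_true(all(s$per_atom_area <= 4 * pi * 3.1^2 + 1e-9))
})

test_that("adding environment atoms never increases any fixed atom's area", {
  set.seed(7)
  base <- data.frame(x = runif(20, 0, 8), y = runif(20, 0, 8),
                     z = runif(20, 0, 8), radius = 1.7)
  extra <- data.frame(x = runif(10, 0, 8), y = runif(10, 0, 8),
                      z = runif(10, 0, 8), radius = 1.7)
  a0 <- shrake_rupley_sasa(base, n_sphere_points = 480)$per_atom_area
  a1 <- shrake_rupley_sasa(rbind(base, extra),
                           n_sphere_points = 480)$per_atom_area[1:20]
  expect_true(all(a1 <= a0 + 1e-9))
})

test_that("the quadrature converges: doubling points changes < 1%", {
  set.seed(9)
  atoms <- data.frame(x = runif(50, 0, 12), y = runif(50, 0, 12),
                      z = runif(50, 0, 12), radius = 1.7)
  t1 <- shrake_rupley_sasa(atoms, n_sphere_points = 960)$total_area
  t2 <- shrake_rupley_sasa(atoms, n_sphere_points = 1920)$total_area
  expect_lt(abs(t1 - t2) / t2, 0.01)
})

test_that("SASA is deterministic for a fixed point set", {
  set.seed(3)
  atoms <- data.frame(x = runif(15, 0, 6), y = runif(15, 0, 6),
                      z = runif(15, 0, 6), radius = 1.7)
  expect_identical(shrake_rupley_sasa(atoms)$per_atom_area,
                   shrake_rupley_sasa(atoms)$per_atom_area)
})

test_that("non-finite coordinates and tiny point counts are rejected", {
  expect_error(shrake_rupley_sasa(data.frame(x = NaN, y = 0, z = 0,
                                             radius = 1.7)),
               "finite")
  expect_error(shrake_rupley_sasa(carbon(0, 0, 0), n_sphere_points = 8),
               ">= 32")
})

test_that("buried area of two overlapping atoms matches the analytic caps", {
  # two solvent-expanded spheres R = 3.1 at centre distance d: the buried
  # area is the sum of the two spherical caps each hides inside the other
  for (d in c(3.0, 4.5, 5.8)) {
    R <- 3.1
    h <- R - d / 2  # cap height, equal radii
    analytic <- 2 * (2 * pi * R * h)
    got <- buried_area(carbon(0, 0, 0), carbon(d, 0, 0),
                       n_sphere_points = 1920)
    expect_lt(abs(got - analytic) / analytic, 0.03)
  }
})

test_that("buried area is symmetric and zero for distant elements", {
  set.seed(21)
  a <- data.frame(x = runif(10, 0, 5), y = runif(10, 0, 5),
                  z = runif(10, 0, 5), radius = 1.7)
  b <- data.frame(x = runif(10, 100, 105), y = runif(10, 0, 5),
                  z = runif(10, 0, 5), radius = 1.7)
  expect_equal(buried_area(a, b), 0, tolerance = 1e-9)
  c2 <- data.frame(x = a$x + 4, y = a$y, z = a$z, radius = 1.7)
  expect_equal(buried_area(a, c2), buried_area(c2, a))
  expect_gt(buried_area(a, c2), 0)
})

test_that("interaction calls recover a planted adjacency", {
  els <- toy_elements()
  adj <- cbind(c("E1", "E1", "E3"), c("E2", "E3", "E4"))
  toy <- generate_toy_structure(els, adj, seed = 4)
  elements <- assign_elements(toy$model, toy$element_map)
  calls <- detect_interactions(elements)
  expect_equal(nrow(calls), choose(5, 2))
  got <- calls[calls$is_interaction, c("element_a", "element_b")]
  got <- got[order(got$element_a, got$element_b), ]
  expect_equal(unname(as.matrix(got)),
               unname(as.matrix(toy$adjacency[order(toy$adjacency$a,
                                                    toy$adjacency$b), ])))
})

test_that("bounding-sphere pruning does not change any interaction call", {
  toy <- generate_toy_structure(toy_elements(),
                                cbind(c("E2", "E3"), c("E3", "E4")),
                                seed = 8)
  elements <- assign_elements(toy$model, toy$element_map)
  fast <- detect_interactions(elements, n_sphere_points = 480)
  slow <- detect_interactions(elements, n_sphere_points = 480,
                              prune = FALSE)
  expect_equal(fast$is_interaction, slow$is_interaction)
  # buried areas agree where actually evaluated; pruned pairs are exact 0
  expect_true(all(abs(fast$buried_area - slow$buried_area) < 0.5))
})

test_that("a single element yields an empty call list", {
  toy <- generate_toy_structure(toy_elements(30), seed = 2)
  elements <- assign_elements(toy$model, toy$element_map)
  calls <- detect_interactions(elements)
  expect_equal(nrow(calls), 0L)
})

test_that("interaction tables round-trip through TSV", {
  toy <- generate_toy_structure(toy_elements(c(20, 20, 20)),
                                cbind("E1", "E2"), seed = 6)
  elements <- assign_elements(toy$model, toy$element_map)
  calls <- detect_interactions(elements)
  f <- tempfile(fileext = ".tsv")
  write_interactions(calls, f)
  back <- read_interactions(f)
  expect_equal(back$is_interaction, calls$is_interaction)
  expect_equal(back$buried_area, calls$buried_area, tolerance = 1e-6)
})

test_that("detection agrees with an independent SASA implementation", {
  # cross-check the total SASA of one blob against biotite's Shrake-Rupley
  toy <- generate_toy_structure(toy_elements(30), seed = 13,
                                path = tempfile(fileext = ".pdb"))
  ours <- shrake_rupley_sasa(toy$model$atoms, n_sphere_points = 960)
  py <- sprintf(paste0(
    "import biotite.structure.io.pdb as pdb\n",
    "import biotite.structure as struc\n",
    "import numpy as np\n",
    "f = pdb.PDBFile.read(%s)\n",
    "arr = f.get_structure(model=1)\n",
    "sasa = struc.sasa(arr, probe_radius=1.4, point_number=960,\n",
    "                  vdw_radii=np.full(arr.array_length(), 1.7))\n",
    "print(float(np.sum(sasa)))\n"), deparse(toy$file))
  out <- tryCatch(
    system2("python", "-", input = py, stdout = TRUE, stderr = TRUE),
    warning = function(w) NULL, error = function(e) NULL)
  ref <- suppressWarnings(as.numeric(utils::tail(out, 1)))
  expect_false(is.na(ref))
  expect_lt(abs(ours$total_area - ref) / ref, 0.02)
})
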