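test_that("PDB loading keeps model 1, best altloc, and drops waters", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(path)
  m <- load_structure(path)
  expect_equal(nrow(m$atoms), 4L)                  # 3 + resolved altloc
  expect_false(any(m$atoms$resid == "HOH"))
  # altloc resolved to the highest occupancy (B, o = 0.6)
  val <- m$atoms[m$atoms$resno == 2, ]
  expect_equal(nrow(val), 1L)
  expect_equal(val$x, 3.8)
  # model 2 atoms (at 50,50,50) are absent
  expect_true(all(m$atoms$x < 10))

  empty <- withr::local_tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(load_structure(empty), "missing or empty")
})

test_that("superposing a structure onto itself or a rigid copy gives rmsd 0", {
  m <- helix_structure(30, seed = 1)
  self <- superpose(m, m)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)

  # pure translation
  shift <- apply_transform(m, list(rotation = diag(3),
                                   translation = c(5, 0, 0)))
  expect_equal(superpose(shift, m)$rmsd, 0, tolerance = 1e-10)

  # general rigid copy
  set.seed(2)
  tr <- random_rigid()
  moved <- apply_transform(m, tr)
  sp <- superpose(moved, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  # the stated transform actually maps mobile onto target at that rmsd
  back <- apply_transform(moved, sp)
  expect_equal(back$atoms$x, m$atoms$x, tolerance = 1e-8)
})

test_that("the triangle example matches the brute-force minimization oracle", {
  tri <- function(p3y) {
    at <- data.frame(chain = "A", resno = 1:3, resid = "GLY",
                     atom_name = "CA", element = "C",
                     x = c(0, 1, 0), y = c(0, 0, p3y), z = 0,
                     occupancy = 1, stringsAsFactors = FALSE)
    structure(list(id = "tri", atoms = at), class = "structure_model")
  }
  sp <- superpose(tri(1.2), tri(1.0))
  # frozen from a 200-restart BFGS minimization over rigid transforms
  expect_equal(sp$rmsd, 0.0887654724, tolerance = 1e-6)
})

test_that("superposition errors on unequal, too-few or collinear selections", {
  m <- helix_structure(30, seed = 1)
  expect_error(superpose(m, m, "A:1-10", "A:1-12"), "must be equal")
  short <- helix_structure(2, seed = 1)
  expect_error(superpose(short, short), "at least 3")
  line <- helix_structure(5, seed = 1)
  line$atoms$x <- 0; line$atoms$y <- 0
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition rmsd is invariant under rigid pre-transformation", {
  target <- helix_structure(25, seed = 3)
  mobile <- helix_structure(25, seed = 4, jitter = 0.5)
  base <- superpose(mobile, target)$rmsd
  set.seed(9)
  for (i in 1:5) {
    pre <- apply_transform(mobile, random_rigid())
    expect_equal(superpose(pre, target)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("Kabsch agrees with the independent bio3d superposition", {
  target <- helix_structure(30, seed = 5)
  mobile <- helix_structure(30, seed = 6, jitter = 0.8)
  sp <- superpose(mobile, target)
  xyz_fit <- suppressWarnings(bio3d::fit.xyz(
    fixed = as.numeric(t(as.matrix(target$atoms[, c("x", "y", "z")]))),
    mobile = as.numeric(t(as.matrix(mobile$atoms[, c("x", "y", "z")])))))
  ref <- as.numeric(t(as.matrix(target$atoms[, c("x", "y", "z")])))
  rmsd_bio3d <- sqrt(mean(colSums(matrix((xyz_fit - ref)^2, nrow = 3))))
  expect_equal(sp$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("clash detection applies the radius-sum-minus-tolerance cutoff", {
  atom_at <- function(x, element = "C", name = "CA", resno = 1) {
    data.frame(chain = "A", resno = resno, resid = "ALA", atom_name = name,
               element = element, x = x, y = 0, z = 0, occupancy = 1,
               stringsAsFactors = FALSE)
  }
  # two carbons: cutoff 1.70 + 1.70 - 0.4 = 3.0
  expect_equal(nrow(detect_clashes(atom_at(0), atom_at(2.8))), 1L)
  expect_equal(nrow(detect_clashes(atom_at(0), atom_at(3.2))), 0L)
  expect_equal(nrow(detect_clashes(atom_at(0)[0, ], atom_at(2.8))), 0L)
  expect_error(detect_clashes(atom_at(0, element = "XX"), atom_at(2.8)),
               "XX")
  # hydrogens are excluded unless requested
  expect_equal(nrow(detect_clashes(atom_at(0, element = "H", name = "H"),
                                   atom_at(0.5))), 0L)
  expect_equal(nrow(detect_clashes(atom_at(0, element = "H", name = "H"),
                                   atom_at(0.5),
                                   radii = c(vdw_radii, H = 1.1),
                                   include_hydrogens = TRUE)), 1L)
})

test_that("clash detection is symmetric and monotone in tolerance", {
  set.seed(13)
  mk <- function(n, offset) {
    data.frame(chain = "A", resno = seq_len(n), resid = "ALA",
               atom_name = "CA", element = sample(c("C", "N", "O"), n, TRUE),
               x = runif(n, 0, 8) + offset, y = runif(n, 0, 8),
               z = runif(n, 0, 8), occupancy = 1, stringsAsFactors = FALSE)
  }
  a <- mk(20, 0); b <- mk(20, 2)
  ab <- detect_clashes(a, b, tolerance = 0.4)
  ba <- detect_clashes(b, a, tolerance = 0.4)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$atom_a, ab$atom_b), paste(ba$atom_b, ba$atom_a))
  loose <- detect_clashes(a, b, tolerance = 1.2)
  expect_true(all(paste(loose$atom_a, loose$atom_b) %in%
                    paste(ab$atom_a, ab$atom_b)))
  # sorted by overlap depth
  expect_true(all(diff(ab$overlap) <= 0))
})
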