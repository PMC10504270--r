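test_that("atomic model constructor validates its invariants", {
  at <- data.frame(chain_id = "A", residue_number = 1:3,
                   residue_name = "GLY", atom_name = "CA", element = "C",
                   x = c(0, 1, 2), y = 0, z = 0)
  m <- atomic_model(at)
  expect_s3_class(m, "atomic_model")
  expect_identical(unname(m$subunit_map["A"]), "A")

  bad <- at; bad$x[2] <- NA
  expect_error(atomic_model(bad), "finite")
  dup <- rbind(at, at[1, ])
  expect_error(atomic_model(dup), "duplicate")
  expect_error(atomic_model(at, subunit_map = c(B = "S1")), "cover")
  frac <- at; frac$residue_number <- c(1, 1.5, 2)
  expect_error(atomic_model(frac), "integer")
})

test_that("rigid transforms act correctly and compose associatively", {
  m <- random_ca_model(10, seed = 1)
  expect_equal(apply_transform(m, rigid_transform())$atoms, m$atoms)

  one <- atomic_model(data.frame(chain_id = "A", residue_number = 1,
                                 residue_name = "GLY", atom_name = "CA",
                                 element = "C", x = 0, y = 0, z = 0))
  shifted <- apply_transform(one, rigid_transform(diag(3), c(1, 2, 3)))
  expect_equal(as.numeric(shifted$atoms[1, c("x", "y", "z")]), c(1, 2, 3))

  rots <- sample_rotations(2, seed = 5)
  t1 <- rigid_transform(rots[[1]]$rotation, c(3, -1, 2))
  t2 <- rigid_transform(rots[[2]]$rotation, c(-5, 0.5, 1))
  seq_applied <- apply_transform(apply_transform(m, t1), t2)
  composed <- apply_transform(m, compose_transforms(t2, t1))
  expect_equal(coords_matrix(seq_applied), coords_matrix(composed),
               tolerance = 1e-9)

  expect_error(rigid_transform(matrix(1, 3, 3)), "orthogonal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("rigid transforms preserve pairwise distances", {
  m <- random_ca_model(25, seed = 2)
  d0 <- dist(coords_matrix(m))
  for (r in sample_rotations(10, seed = 3)) {
    t <- rigid_transform(r$rotation, rnorm(3, sd = 20))
    expect_equal(as.numeric(dist(coords_matrix(apply_transform(m, t)))),
                 as.numeric(d0), tolerance = 1e-9)
  }
})

test_that("a hand-written PDB file parses field by field", {
  lines <- c(
    "ATOM      1  CA  GLY A   1      11.104  13.207   9.500  1.00 20.00           C",
    "ATOM      2  CA  ALA A   2      14.104  17.207   9.500  1.00 21.00           C",
    "ATOM      3  CA  LYS B   7      -1.500   0.000   2.250  0.50 15.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x, c(11.104, 14.104, -1.5))
  expect_equal(m$atoms$residue_number, c(1L, 2L, 7L))
  expect_equal(m$atoms$chain_id, c("A", "A", "B"))
  expect_equal(m$atoms$occupancy, c(1, 1, 0.5))
})

test_that("structure files round-trip in both formats", {
  truth <- bundle_truth()
  model <- truth$model
  for (fmt in c("pdb", "cif")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(model, f, format = fmt)
    back <- read_structure(f, format = fmt,
                           subunit_map = model$subunit_map)
    expect_equal(back$atoms$chain_id, model$atoms$chain_id)
    expect_equal(back$atoms$residue_number, model$atoms$residue_number)
    expect_equal(coords_matrix(back), coords_matrix(model),
                 tolerance = 2e-3, ignore_attr = TRUE)
  }
})

test_that("empty models produce valid structure files", {
  empty <- atomic_model(data.frame(chain_id = character(0),
                                   residue_number = integer(0),
                                   residue_name = character(0),
                                   atom_name = character(0),
                                   element = character(0),
                                   x = numeric(0), y = numeric(0),
                                   z = numeric(0)))
  f <- withr::local_tempfile(fileext = ".cif")
  write_structure(empty, f, format = "cif")
  expect_equal(nrow(read_structure(f, format = "cif")$atoms), 0)
})

test_that("written records are ordered by chain then residue", {
  at <- data.frame(chain_id = c("B", "A", "A", "B"),
                   residue_number = c(2L, 9L, 3L, 1L),
                   residue_name = "GLY", atom_name = "CA", element = "C",
                   x = 1:4, y = 0, z = 0)
  m <- atomic_model(at)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  back <- read_structure(f)$atoms
  # brute-force expected order: chains in first-appearance order, then resno
  expected <- at[order(match(at$chain_id, unique(at$chain_id)),
                       at$residue_number), ]
  expect_equal(back$chain_id, expected$chain_id)
  expect_equal(back$residue_number, expected$residue_number)
})

test_that("insertion codes are rejected with a clear error", {
  lines <- c(
    "ATOM      1  CA  GLY A   1A     11.104  13.207   9.500  1.00 20.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_error(read_structure(f), "insertion")
})

test_that("our mmCIF reader agrees with an independent mmCIF parser", {
  model <- bundle_truth()$model
  f <- withr::local_tempfile(fileext = ".cif")
  write_structure(model, f, format = "cif")
  ours <- read_structure(f, format = "cif")
  ref <- suppressWarnings(bio3d::read.cif(f))
  expect_equal(length(unique(ours$atoms$chain_id)),
               length(unique(ref$atom$chain)))
  expect_equal(nrow(ours$atoms), nrow(ref$atom))
  expect_equal(ours$atoms$x, ref$atom$x, tolerance = 1e-6)
})

test_that("MRC maps round-trip through write and read", {
  set.seed(4)
  vals <- array(rnorm(16^3), dim = c(16, 16, 16))
  m <- density_map(vals, voxel_size = 1.5, origin = c(-3, 2, 7.5))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, f)
  back <- read_map(f)
  expect_equal(dim(back$values), dim(m$values))
  expect_equal(back$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_equal(back$origin, m$origin, tolerance = 1e-5)
  expect_equal(back$values, m$values, tolerance = 1e-6)

  zero <- density_map(array(0, dim = c(4, 5, 6)), 2)
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(zero, f2)
  expect_true(all(read_map(f2)$values == 0))
})

test_that("permuted axis order on disk leaves voxel world coordinates unchanged", {
  set.seed(5)
  vals <- array(rnorm(8 * 10 * 12), dim = c(8, 10, 12))
  m <- density_map(vals, voxel_size = 2, origin = c(1, -2, 3))
  for (ord in list(c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))) {
    f <- withr::local_tempfile(fileext = ".mrc")
    write_map(m, f, axis_order = ord)
    back <- read_map(f)
    expect_equal(dim(back$values), dim(m$values))
    expect_equal(back$values, m$values, tolerance = 1e-6)
    expect_equal(back$origin, m$origin, tolerance = 1e-5)
  }
})

test_that("a second independent MRC reader agrees on header and data", {
  set.seed(6)
  vals <- array(rnorm(6 * 7 * 8), dim = c(6, 7, 8))
  m <- density_map(vals, voxel_size = 2.5, origin = c(4, -1, 0.5))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, f, axis_order = c(2, 3, 1))
  py <- c(
    "import gemmi, numpy",
    sprintf("m = gemmi.read_ccp4_map('%s')", f),
    "m.setup(float('nan'))",    # normalizes axis order to X fastest
    "g = m.grid",
    "print(g.nu, g.nv, g.nw)",
    "print(round(g.spacing[0], 6))",
    "print(round(float(numpy.array(g, copy=False).sum()), 6))")
  out <- system2("python", c("-c", shQuote(paste(py, collapse = "\n"))),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  dims <- as.integer(strsplit(out[length(out) - 2], " ")[[1]])
  expect_equal(dims, dim(m$values))
  expect_equal(as.numeric(out[length(out) - 1]), 2.5, tolerance = 1e-4)
  expect_equal(as.numeric(out[length(out)]), sum(m$values),
               tolerance = 1e-3)
})

test_that("unsupported MRC modes raise an explicit error", {
  f <- withr::local_tempfile(fileext = ".mrc")
  m <- density_map(array(1, dim = c(2, 2, 2)), 1)
  write_map(m, f)
  raw <- readBin(f, "raw", file.size(f))
  mode_bytes <- writeBin(1L, raw(), size = 4, endian = "little")
  raw[13:16] <- mode_bytes
  writeBin(raw, f)
  expect_error(read_map(f), "unsupported MRC mode")
})

test_that("rigid transforms serialize to JSON and back", {
  rots <- sample_rotations(3, seed = 9)
  tr <- lapply(seq_along(rots), function(i)
    rigid_transform(rots[[i]]$rotation, c(i, -i, 2 * i)))
  names(tr) <- paste0("S", 1:3)
  f <- withr::local_tempfile(fileext = ".json")
  transforms_to_json(tr, f)
  back <- transform_from_json(f)
  for (i in 1:3) {
    expect_equal(back[[i]]$rotation, tr[[i]]$rotation, tolerance = 1e-12)
    expect_equal(back[[i]]$translation, tr[[i]]$translation,
                 tolerance = 1e-12)
  }
})
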