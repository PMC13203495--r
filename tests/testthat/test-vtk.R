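# VTK-legacy writers: structural checks on the emitted files.

test_that("particle snapshots carry the header, points and fields", {
  pos <- matrix(runif(20), ncol = 2)
  path <- tempfile(fileext = ".vtk")
  write_vtk_points(path, pos, point_data = list(
    pressure = seq_len(10), velocity = matrix(0.5, 10, 2)))
  txt <- readLines(path)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true("DATASET POLYDATA" %in% txt)
  expect_true("POINTS 10 float" %in% txt)
  expect_true("POINT_DATA 10" %in% txt)
  expect_true("SCALARS pressure float 1" %in% txt)
  expect_true("VECTORS velocity float" %in% txt)
})

test_that("mesh files enumerate triangles as VTK cell type 5", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  tri <- rbind(c(1, 2, 3), c(2, 4, 3))
  path <- tempfile(fileext = ".vtk")
  write_vtk_mesh(path, X, tri, cell_data = list(vm = c(1, 2)))
  txt <- readLines(path)
  expect_true("DATASET UNSTRUCTURED_GRID" %in% txt)
  expect_true("CELLS 2 8" %in% txt)
  expect_true("CELL_TYPES 2" %in% txt)
  expect_true("3 0 1 2" %in% txt)   # zero-based connectivity
  expect_true("CELL_DATA 2" %in% txt)
})

test_that("a model directory contains every component plus the JSON sidecar", {
  model <- build_nested_model(nested_model_config())
  dir <- tempfile("model")
  write_model_vtk(model, dir)
  files <- list.files(dir)
  for (nm in c("uterus", "fetal_body", "skull", "brain", "amniotic_fluid",
               "csf")) {
    expect_true(sprintf("%s_rest.vtk", nm) %in% files)
  }
  js <- jsonlite::read_json(file.path(dir, "model.json"))
  expect_equal(length(js$landmarks), 10L)
  expect_equal(js$config$csf_gap, model$config$csf_gap)
})
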