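test_that("TPS records parse with curves, scale and ids", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0 1",
               "CURVES=1", "POINTS=4",
               "0 0.5", "0.2 0.6", "0.4 0.55", "0.6 0.5",
               "ID=c1",
               "LM=3", "2 4", "6 0", "0 2", "ID=c2", "SCALE=0.5"),
             path)
  cfgs <- read_tps(path)
  expect_length(cfgs, 2L)
  # curve points appended after fixed landmarks; interior points slide
  expect_equal(nrow(cfgs[[1]]$coords), 7L)
  expect_equal(unname(cfgs[[1]]$sliders),
               matrix(c(4L, 5L, 6L, 5L, 6L, 7L), 2L, byrow = TRUE))
  expect_equal(cfgs[[1]]$specimen_id, "c1")
  # SCALE multiplies coordinates
  expect_equal(cfgs[[2]]$coords[1, ], c(1, 2))
  expect_equal(nrow(cfgs[[2]]$sliders), 0L)
})

test_that("malformed TPS records are rejected with the record index", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=4", "0 0", "1 0", "0 1", "ID=bad"), path)
  expect_error(read_tps(path), "record 1")
  writeLines(c("LM=2", "0 0", "1 0", "ID=two"), path)
  expect_error(read_tps(path), "at least 3")
})

test_that("TPS write/read round trip preserves coordinates and is idempotent", {
  set.seed(42)
  cfgs <- lapply(1:3, function(i)
    landmark_config(paste0("sp", i), random_config_matrix(35)))
  expect_error(write_tps(list(), tempfile()), "empty")
  p1 <- withr::local_tempfile(fileext = ".tps")
  write_tps(cfgs, p1)
  expect_match(readLines(p1, n = 1L), "^LM=35$")
  back <- read_tps(p1)
  for (i in 1:3) {
    expect_equal(back[[i]]$coords, cfgs[[i]]$coords, tolerance = 1e-6)
    expect_equal(back[[i]]$specimen_id, cfgs[[i]]$specimen_id)
  }
  p2 <- withr::local_tempfile(fileext = ".tps")
  write_tps(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("slider validation rejects bad triples", {
  coords <- random_config_matrix(5)
  expect_error(landmark_config("a", coords, sliders = rbind(c(1, 2, 2))),
               "distinct")
  expect_error(landmark_config("a", coords, sliders = rbind(c(1, 2, 3),
                                                            c(4, 2, 5))),
               "at most one")
  expect_error(landmark_config("a", coords, sliders = rbind(c(0, 2, 3))),
               "1..5")
})

test_that("classifier tables parse and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,species,life_stage",
               "a1,D_sargus,juvenile", "a2,D_vulgaris,adult"), path)
  md <- read_classifiers(path)
  expect_equal(nrow(md), 2L)
  expect_setequal(md$species, c("D_sargus", "D_vulgaris"))

  writeLines(c("specimen_id,species,life_stage",
               "a1,D_sargus,juvenile", "a1,D_sargus,adult"), path)
  expect_error(read_classifiers(path), "duplicate")
  writeLines(c("specimen_id,species,life_stage", "a1,D_sargus,adultt"), path)
  expect_error(read_classifiers(path), "juvenile, adult")
})

test_that("generated classifier table partitions into the configured counts", {
  sim <- generate_dataset(paper_like_scenario())
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim, dir)
  md <- read_classifiers(paths$classifiers)
  expect_equal(nrow(md), 390L)
  expect_equal(sum(md$life_stage == "juvenile"), 291L)
  expect_equal(sum(md$life_stage == "adult"), 99L)
  counts <- table(md$species, md$ontogenetic_stage)
  cfg <- sim$truth$config
  expect_equal(unname(as.matrix(counts)[cfg$species, ]),
               unname(cfg$n_per_cell))
})

test_that("centroid-size staging reproduces the percentile bins", {
  md <- data.frame(specimen_id = paste0("j", 1:9), species = "sp",
                   life_stage = "juvenile", centroid_size = 1:9)
  out <- assign_ontogenetic_stage(md)
  expect_equal(out$ontogenetic_stage, c(1, 1, 1, 2, 2, 2, 3, 3, 3))

  adult <- data.frame(specimen_id = "a", species = "sp",
                      life_stage = "adult", centroid_size = 0.001)
  expect_equal(assign_ontogenetic_stage(adult)$ontogenetic_stage, 4L)

  # identical sizes share one stage through average ranks
  ties <- data.frame(specimen_id = paste0("t", 1:6), species = "sp",
                     life_stage = "juvenile", centroid_size = 5)
  expect_equal(unique(assign_ontogenetic_stage(ties)$ontogenetic_stage), 2L)
})

test_that("staging is invariant under monotone rescaling and counts add up", {
  set.seed(7)
  md <- data.frame(specimen_id = paste0("s", 1:40),
                   species = rep(c("A", "B"), each = 20),
                   life_stage = rep(c("juvenile", "adult"), c(30, 10)),
                   centroid_size = exp(rnorm(40)))
  base <- assign_ontogenetic_stage(md)
  warped <- md
  warped$centroid_size <- log1p(md$centroid_size)^3  # monotone
  expect_equal(assign_ontogenetic_stage(warped)$ontogenetic_stage,
               base$ontogenetic_stage)
  counts <- table(base$species, base$ontogenetic_stage)
  expect_equal(rowSums(counts), table(md$species), ignore_attr = TRUE)
})

test_that("partition tables round trip and are validated", {
  part <- c(rep("head", 4), rep("trunk_tail", 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition(part, path)
  expect_equal(read_partition(path), part)
  expect_error(read_partition(path, k = 12), "exactly one")
  bad <- c(rep("head", 2), rep("trunk_tail", 8))
  write_partition(bad, path)
  expect_error(read_partition(path), "at least 3")
})
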