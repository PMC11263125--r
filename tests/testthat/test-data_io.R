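test_that("the toy dataset loads with the expected shape", {
  ds <- toy_dataset()
  expect_s3_class(ds, "cooc_dataset")
  expect_equal(ds$consumers$species_ids, c("A", "B"))
  expect_equal(ds$resources$species_ids, c("x", "y"))
  expect_equal(ds$consumers$site_ids, c("s1", "s2"))
  expect_equal(nrow(ds$interactions), 1L)
  expect_true(ds$consumers$presence["s1", "A"])
  expect_false(ds$consumers$presence["s1", "B"])
})

test_that("duplicate rows collapse to one record", {
  paths <- toy_csv_files()
  inter <- read.csv(paths$inter)
  write.csv(rbind(inter, inter[1, ]), paths$inter, row.names = FALSE)
  ds <- load_dataset(paths$occ, paths$inter)
  expect_equal(nrow(ds$interactions), 1L)
  expect_identical(ds$interactions, toy_dataset()$interactions)
})

test_that("interactions violating co-presence are rejected with the offending triple", {
  paths <- toy_csv_files()
  # x is absent from s2
  write.csv(data.frame(site = "s2", consumer = "A", resource = "x"),
            paths$inter, row.names = FALSE)
  err <- expect_error(load_dataset(paths$occ, paths$inter),
                      class = "coprune_consistency_error")
  expect_match(conditionMessage(err), "s2.*A.*x")
})

test_that("schema violations raise format errors, missing guilds consistency errors", {
  paths <- toy_csv_files()
  occ <- read.csv(paths$occ)

  names(occ)[2] <- "layer"
  bad <- file.path(paths$dir, "bad.csv")
  write.csv(occ, bad, row.names = FALSE)
  expect_error(load_dataset(bad, paths$inter), class = "coprune_format_error")

  occ2 <- read.csv(paths$occ)
  occ2$guild[occ2$guild == "resource"] <- "prey"
  write.csv(occ2, bad, row.names = FALSE)
  expect_error(load_dataset(bad, paths$inter), class = "coprune_format_error")

  occ3 <- read.csv(paths$occ)
  occ3 <- occ3[occ3$guild == "consumer", ]
  write.csv(occ3, bad, row.names = FALSE)
  expect_error(load_dataset(bad, file.path(paths$dir, "interactions.csv")),
               class = "coprune_consistency_error")

  # unknown species referenced by an interaction
  write.csv(data.frame(site = "s1", consumer = "Z", resource = "x"),
            paths$inter, row.names = FALSE)
  expect_error(load_dataset(paths$occ, paths$inter),
               class = "coprune_consistency_error")
})

test_that("datasets survive a write/load round trip", {
  ds <- small_metacommunity(seed = 7)$dataset
  dir <- tempfile("rt"); dir.create(dir)
  occ <- file.path(dir, "occ.csv"); inter <- file.path(dir, "int.csv")
  write_dataset(ds, occ, inter)
  ds2 <- load_dataset(occ, inter, name = ds$name)
  expect_setequal(ds2$consumers$species_ids, ds$consumers$species_ids)
  expect_setequal(ds2$resources$species_ids, ds$resources$species_ids)
  # sites hosting no species at all are not representable in long format
  occupied <- ds$consumers$site_ids[rowSums(ds$consumers$presence) +
                                      rowSums(ds$resources$presence) > 0]
  expect_setequal(ds2$consumers$site_ids, occupied)
  expect_equal(ds2$consumers$presence[occupied, ds$consumers$species_ids],
               ds$consumers$presence[occupied, ])
  key <- function(d) sort(with(d$interactions, paste(site, consumer, resource)))
  expect_identical(key(ds2), key(ds))
})

test_that("networks round-trip through edge list + sidecar, including empty ones", {
  set.seed(42)
  adj <- matrix(runif(10 * 12) < 0.4, nrow = 10,
                dimnames = list(paste0("c", 1:10), paste0("r", 1:12)))
  net <- bipartite_network(adj, kind = "cooccurrence")
  path <- tempfile(fileext = ".csv")
  write_network(net, path, dataset = "fixture")
  back <- read_network(path)
  expect_identical(back$adjacency, net$adjacency)
  expect_identical(back$kind, net$kind)

  empty <- bipartite_network(adj & FALSE, kind = "interaction")
  path2 <- tempfile(fileext = ".csv")
  write_network(empty, path2)
  sidecar <- jsonlite::read_json(paste0(path2, ".json"))
  expect_equal(sidecar$n_links, 0)
  back2 <- read_network(path2)
  expect_equal(back2$L, 0L)
  expect_identical(back2$adjacency, empty$adjacency)
})

test_that("incidence tables reject duplicates and all-absent species", {
  m <- matrix(TRUE, 2, 2, dimnames = list(c("s1", "s2"), c("A", "A")))
  expect_error(site_species_table(m, "consumer"),
               class = "coprune_consistency_error")
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2,
               dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_error(site_species_table(m2, "consumer"),
               class = "coprune_consistency_error")
})
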