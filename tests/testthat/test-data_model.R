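test_that("abundance vectors validate, drop zeros and sum duplicates", {
  v <- as_abundance(c(a = 1, b = 0, c = 2, c = 3))
  expect_identical(sort(names(v)), c("a", "c"))
  expect_identical(unname(v[["c"]]), 5L)
  expect_error(as_abundance(c(2, 3)), "named")
  expect_error(as_abundance(c(a = -1)), "non-negative")
  expect_error(as_abundance(c(a = 1.5)), "non-negative")
  expect_length(as_abundance(c(a = 0)), 0)
})

test_that("island table ingestion validates, sums duplicates and flags empties", {
  tt <- toy_tables()
  ab_path <- withr::local_tempfile(fileext = ".csv")
  md_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(island_id = "A", species_id = c("x", "y", "z"),
                       abundance = c(1, 2, 3)), ab_path, row.names = FALSE)
  write.csv(data.frame(island_id = "A", area_km2 = 10), md_path,
            row.names = FALSE)
  ds <- read_island_table(ab_path, md_path, taxon = "toy")
  comm <- island_communities(ds)[["A"]]
  expect_identical(sum(comm), 6L)
  expect_identical(length(comm), 3L)

  # duplicate (island, species) rows are summed
  write.csv(data.frame(island_id = "A", species_id = c("x", "x", "y"),
                       abundance = c(1, 2, 5)), ab_path, row.names = FALSE)
  ds <- read_island_table(ab_path, md_path)
  expect_identical(unname(island_communities(ds)[["A"]][["x"]]), 3L)

  # non-positive area and bad abundances are rejected with row references
  write.csv(data.frame(island_id = "A", area_km2 = -1), md_path,
            row.names = FALSE)
  expect_error(read_island_table(ab_path, md_path), "area")
  write.csv(data.frame(island_id = "A", area_km2 = 10), md_path,
            row.names = FALSE)
  write.csv(data.frame(island_id = "A", species_id = "x", abundance = -2),
            ab_path, row.names = FALSE)
  expect_error(read_island_table(ab_path, md_path), "row")

  # a missing column is named in the error
  write.csv(data.frame(island_id = "A", species_id = "x", count = 2),
            ab_path, row.names = FALSE)
  expect_error(read_island_table(ab_path, md_path), "abundance")
  # ... unless remapped through col_map
  ds <- read_island_table(ab_path, md_path, col_map = c(abundance = "count"))
  expect_identical(sum(island_communities(ds)[["A"]]), 2L)

  # islands present only in metadata are kept but flagged
  expect_message(
    ds <- archipelago(tt$abundances[tt$abundances$island_id != "C", ],
                      tt$metadata),
    "empty")
  expect_identical(ds$empty_islands, "C")
  expect_false("C" %in% names(island_communities(ds)))
})

test_that("plot tables flag single-plot islands and sum duplicate rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(island_id = c("A", "A", "B"),
                       plot_id = c("p1", "p2", "p1"),
                       species_id = "x", abundance = 1),
            path, row.names = FALSE)
  expect_message(pl <- read_plot_table(path), "single")
  expect_identical(attr(pl, "single_plot_islands"), "B")

  write.csv(data.frame(island_id = "A", plot_id = "p1",
                       species_id = c("x", "x"), abundance = c(1, 2)),
            path, row.names = FALSE)
  suppressMessages(pl <- read_plot_table(path))
  expect_identical(pl$abundance, 3L)

  writeLines("island_id,plot_id,species_id,abundance", path)
  expect_warning(pl <- read_plot_table(path), "empty")
  expect_identical(nrow(pl), 0L)
})

test_that("pooling plots conserves individuals and species sums", {
  plots <- data.frame(island_id = "A",
                      plot_id = c("p1", "p2", "p2"),
                      species_id = c("a", "a", "b"),
                      abundance = c(2, 1, 3),
                      stringsAsFactors = FALSE)
  pooled <- pool_plots(plots, "A")
  expect_identical(unname(pooled[c("a", "b")]), c(3L, 3L))
  expect_equal(sum(pooled), sum(plots$abundance))

  single <- pool_plots(plots[plots$plot_id == "p1", ], "A")
  expect_identical(single, as_abundance(c(a = 2)))

  disjoint <- data.frame(island_id = "A", plot_id = c("p1", "p2"),
                         species_id = c("a", "b"), abundance = c(1, 1))
  expect_identical(sort(pool_plots(disjoint, "A")), as_abundance(c(a = 1, b = 1)))
  expect_error(pool_plots(plots, "Z"), "no plots")
})

test_that("datasets survive a write-read round trip exactly", {
  tt <- toy_tables()
  ds <- archipelago(tt$abundances, tt$metadata, plots = tt$plots, taxon = "toy")
  ab <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  pl <- withr::local_tempfile(fileext = ".csv")
  write_island_table(ds, ab, md, pl)
  ds2 <- read_island_table(ab, md, taxon = "toy")
  ds2 <- archipelago(ds2$abundances, ds2$metadata, plots = read_plot_table(pl),
                     taxon = "toy")
  by_name <- function(v) v[order(names(v))]
  for (id in ds$metadata$island_id)
    expect_identical(by_name(island_communities(ds2)[[id]]),
                     by_name(island_communities(ds)[[id]]))
  expect_equal(ds2$metadata, ds$metadata, ignore_attr = TRUE)
  expect_identical(pool_plots(ds2$plots, "A"), pool_plots(ds$plots, "A"))
})

test_that("dataset invariants are enforced", {
  tt <- toy_tables()
  md_dup <- rbind(tt$metadata, tt$metadata[1, ])
  expect_error(archipelago(tt$abundances, md_dup), "duplicated")
  orphan <- rbind(tt$abundances,
                  data.frame(island_id = "Z", species_id = "x", abundance = 1))
  expect_error(archipelago(orphan, tt$metadata), "missing from metadata")
  bad_plots <- tt$plots
  bad_plots$island_id[1] <- "Z"
  expect_error(archipelago(tt$abundances, tt$metadata, plots = bad_plots),
               "missing from metadata")
})
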