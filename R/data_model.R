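#' Coerce to a validated abundance vector
#'
#' An abundance vector is the package's representation of one community
#' sample: a named integer vector of individual counts, one entry per
#' species. Zero counts are dropped and duplicate species names are summed,
#' so every retained count is >= 1.
#'
#' @param x A named numeric vector of non-negative integer counts.
#' @return A named integer vector with all counts >= 1 (possibly empty).
#' @examples
#' as_abundance(c(a = 1, b = 0, c = 2, c = 3))  # b dropped, c summed to 5
#' @export
as_abundance <- function(x) {
  if (length(x) == 0) return(structure(integer(0), names = character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyNA(names(x)))
    stop("abundance vectors must be named by species id", call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x != trunc(x)))
    stop("abundances must be non-negative integers", call. = FALSE)
  if (anyDuplicated(names(x))) {
    x <- c(tapply(as.numeric(x), names(x), sum))
  }
  x <- x[x > 0]
  storage.mode(x) <- "integer"
  x
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.validate_abund_df <- function(df, what, id_cols) {
  bad <- which(is.na(df$abundance) | df$abundance < 0 |
                 df$abundance != trunc(df$abundance))
  if (length(bad))
    stop(sprintf("%s: non-integer or negative abundance in row(s) %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  # duplicate (id..., species) rows are summed, matching sparse field sheets
  key <- do.call(paste, c(df[id_cols], list(df$species_id), sep = "\r"))
  if (anyDuplicated(key)) {
    df <- stats::aggregate(df["abundance"], by = df[c(id_cols, "species_id")],
                           FUN = sum)
  }
  df$abundance <- as.integer(df$abundance)
  df[df$abundance > 0, , drop = FALSE]
}

#' Assemble a validated archipelago dataset
#'
#' Bundles island-level abundances, island metadata (area), and optional
#' plot-level abundances into a single validated object used by all
#' downstream analyses. Duplicate (island, species) rows are summed; islands
#' present in the metadata but absent from the abundance table are retained
#' with empty communities and flagged (they are excluded from metric
#' computations but reported). Plot tables are checked against the island
#' list, and islands with fewer than two plots are flagged for exclusion
#' from the beta-diversity analysis.
#'
#' @param abundances data.frame with columns `island_id`, `species_id`,
#'   `abundance` (non-negative integers).
#' @param metadata data.frame with columns `island_id`, `area_km2`
#'   (strictly positive).
#' @param plots Optional data.frame with columns `island_id`, `plot_id`,
#'   `species_id`, `abundance`.
#' @param taxon Label for the taxon the table describes.
#' @return An object of class `"archipelago"`: a list with elements
#'   `taxon`, `abundances`, `metadata`, `plots`, `empty_islands`,
#'   `single_plot_islands`.
#' @seealso [read_island_table()], [island_communities()], [isar()]
#' @export
archipelago <- function(abundances, metadata, plots = NULL, taxon = "") {
  abundances <- as.data.frame(abundances)
  metadata <- as.data.frame(metadata)
  .check_columns(abundances, c("island_id", "species_id", "abundance"),
                 "abundance table")
  .check_columns(metadata, c("island_id", "area_km2"), "metadata table")
  metadata$island_id <- as.character(metadata$island_id)
  if (anyDuplicated(metadata$island_id))
    stop("metadata table: duplicated island_id", call. = FALSE)
  bad_area <- which(is.na(metadata$area_km2) | metadata$area_km2 <= 0)
  if (length(bad_area))
    stop(sprintf("metadata table: non-positive area in row(s) %s",
                 paste(bad_area, collapse = ", ")), call. = FALSE)

  abundances$island_id <- as.character(abundances$island_id)
  abundances$species_id <- as.character(abundances$species_id)
  abundances <- .validate_abund_df(abundances, "abundance table", "island_id")

  orphan <- setdiff(abundances$island_id, metadata$island_id)
  if (length(orphan))
    stop(sprintf("abundance table references island(s) missing from metadata: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  empty <- setdiff(metadata$island_id, abundances$island_id)
  if (length(empty))
    message(sprintf("%d island(s) with empty communities retained but flagged: %s",
                    length(empty), paste(empty, collapse = ", ")))

  single_plot <- character(0)
  if (!is.null(plots)) {
    plots <- as.data.frame(plots)
    .check_columns(plots, c("island_id", "plot_id", "species_id", "abundance"),
                   "plot table")
    plots$island_id <- as.character(plots$island_id)
    plots$plot_id <- as.character(plots$plot_id)
    plots$species_id <- as.character(plots$species_id)
    plots <- .validate_abund_df(plots, "plot table", c("island_id", "plot_id"))
    orphan <- setdiff(plots$island_id, metadata$island_id)
    if (length(orphan))
      stop(sprintf("plot table references island(s) missing from metadata: %s",
                   paste(orphan, collapse = ", ")), call. = FALSE)
    n_plots <- tapply(plots$plot_id, plots$island_id,
                      function(p) length(unique(p)))
    single_plot <- names(n_plots)[n_plots < 2]
    if (length(single_plot))
      message(sprintf("island(s) with a single plot flagged for exclusion from beta analysis: %s",
                      paste(single_plot, collapse = ", ")))
  }

  structure(list(taxon = taxon,
                 abundances = abundances,
                 metadata = metadata[order(metadata$island_id), , drop = FALSE],
                 plots = plots,
                 empty_islands = empty,
                 single_plot_islands = single_plot),
            class = "archipelago")
}

#' @export
print.archipelago <- function(x, ...) {
  cat(sprintf("Archipelago dataset%s\n",
              if (nzchar(x$taxon)) paste0(" (", x$taxon, ")") else ""))
  cat(sprintf("  islands: %d (area %.3g-%.3g km2), species: %d, individuals: %d\n",
              nrow(x$metadata), min(x$metadata$area_km2),
              max(x$metadata$area_km2),
              length(unique(x$abundances$species_id)),
              sum(x$abundances$abundance)))
  if (length(x$empty_islands))
    cat(sprintf("  empty islands (flagged): %s\n",
                paste(x$empty_islands, collapse = ", ")))
  if (!is.null(x$plots))
    cat(sprintf("  plots: %d on %d island(s)\n",
                nrow(unique(x$plots[c("island_id", "plot_id")])),
                length(unique(x$plots$island_id))))
  invisible(x)
}

#' Extract per-island community abundance vectors
#'
#' @param x An [archipelago()] dataset.
#' @param drop_empty Drop flagged islands with no individuals (default TRUE).
#' @return Named list of abundance vectors, one per island.
#' @export
island_communities <- function(x, drop_empty = TRUE) {
  stopifnot(inherits(x, "archipelago"))
  ids <- x$metadata$island_id
  if (drop_empty) ids <- setdiff(ids, x$empty_islands)
  out <- lapply(ids, function(id) {
    sub <- x$abundances[x$abundances$island_id == id, , drop = FALSE]
    as_abundance(structure(sub$abundance, names = sub$species_id))
  })
  names(out) <- ids
  out
}

#' Extract per-plot community abundance vectors for one island
#'
#' @param plots A plot table (data.frame with island_id, plot_id,
#'   species_id, abundance), e.g. `dataset$plots`.
#' @param island_id Island to extract.
#' @return Named list (by plot_id) of abundance vectors.
#' @export
plot_communities <- function(plots, island_id) {
  sub <- plots[plots$island_id == island_id, , drop = FALSE]
  if (nrow(sub) == 0)
    stop(sprintf("no plots recorded for island '%s'", island_id), call. = FALSE)
  out <- lapply(split(sub, sub$plot_id), function(d)
    as_abundance(structure(d$abundance, names = d$species_id)))
  out[order(names(out))]
}

#' Pool plot communities into one island-scale community
#'
#' Species-wise sum of counts over all plots surveyed on an island; the
#' pooled total equals the sum of the plot totals.
#'
#' @inheritParams plot_communities
#' @return An abundance vector for the pooled island community.
#' @export
pool_plots <- function(plots, island_id) {
  comms <- plot_communities(plots, island_id)
  all <- unlist(unname(lapply(comms, function(v)
    structure(as.numeric(v), names = names(v)))))
  as_abundance(all)
}

.apply_col_map <- function(df, col_map, what) {
  if (is.null(col_map)) return(df)
  for (std in names(col_map)) {
    src <- col_map[[std]]
    if (!src %in% names(df))
      stop(sprintf("%s: mapped column '%s' (for '%s') not found", what, src, std),
           call. = FALSE)
    names(df)[names(df) == src] <- std
  }
  df
}

#' Read island abundance and metadata CSVs
#'
#' Reads the long-format (tidy) layout used for sparse island survey data:
#' one abundance row per (island, species) record plus a per-island metadata
#' table carrying area. Non-standard column names can be remapped with
#' `col_map`, e.g. `c(abundance = "count")`.
#'
#' @param abundance_path CSV with columns island_id, species_id, abundance.
#' @param metadata_path CSV with columns island_id, area_km2.
#' @param taxon Taxon label stored on the dataset.
#' @param col_map Optional named character vector mapping standard column
#'   names to the file's column names.
#' @return An [archipelago()] dataset.
#' @export
read_island_table <- function(abundance_path, metadata_path, taxon = "",
                              col_map = NULL) {
  ab <- utils::read.csv(abundance_path, stringsAsFactors = FALSE)
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  ab <- .apply_col_map(ab, col_map[names(col_map) %in%
                                     c("island_id", "species_id", "abundance")],
                       "abundance table")
  md <- .apply_col_map(md, col_map[names(col_map) %in% c("island_id", "area_km2")],
                       "metadata table")
  archipelago(ab, md, taxon = taxon)
}

#' Read a plot-level abundance CSV
#'
#' @param path CSV with columns island_id, plot_id, species_id, abundance.
#' @inheritParams read_island_table
#' @return data.frame of validated plot records; islands with a single plot
#'   are flagged in the `"single_plot_islands"` attribute (the beta analysis
#'   requires at least two plots per island).
#' @export
read_plot_table <- function(path, col_map = NULL) {
  pl <- utils::read.csv(path, stringsAsFactors = FALSE)
  pl <- .apply_col_map(pl, col_map, "plot table")
  .check_columns(pl, c("island_id", "plot_id", "species_id", "abundance"),
                 "plot table")
  if (nrow(pl) == 0) {
    warning("plot table is empty", call. = FALSE)
    attr(pl, "single_plot_islands") <- character(0)
    return(pl)
  }
  pl$island_id <- as.character(pl$island_id)
  pl$plot_id <- as.character(pl$plot_id)
  pl$species_id <- as.character(pl$species_id)
  pl <- .validate_abund_df(pl, "plot table", c("island_id", "plot_id"))
  n_plots <- tapply(pl$plot_id, pl$island_id, function(p) length(unique(p)))
  single <- names(n_plots)[n_plots < 2]
  if (length(single))
    message(sprintf("island(s) with a single plot flagged: %s",
                    paste(single, collapse = ", ")))
  attr(pl, "single_plot_islands") <- single
  pl
}

#' Write an archipelago dataset back to CSV
#'
#' Emits the same layout [read_island_table()] reads, so a read-write-read
#' round trip reproduces the dataset.
#'
#' @param x An [archipelago()] dataset.
#' @param abundance_path,metadata_path,plots_path Output CSV paths
#'   (`plots_path` only used when the dataset has plots).
#' @return Invisibly, `x`.
#' @export
write_island_table <- function(x, abundance_path, metadata_path,
                               plots_path = NULL) {
  stopifnot(inherits(x, "archipelago"))
  ab <- x$abundances[order(x$abundances$island_id, x$abundances$species_id), ]
  utils::write.csv(ab, abundance_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$metadata, metadata_path, row.names = FALSE, quote = FALSE)
  if (!is.null(x$plots) && !is.null(plots_path)) {
    pl <- x$plots[order(x$plots$island_id, x$plots$plot_id, x$plots$species_id), ]
    utils::write.csv(pl, plots_path, row.names = FALSE, quote = FALSE)
  }
  invisible(x)
}
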