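# Reading, validating and writing site-level occurrence and interaction
# records. On-disk canonical formats are long-format CSV:
#   occurrences.csv:  site, guild, species   (guild in {consumer, resource})
#   interactions.csv: site, consumer, resource
# Identifiers are opaque, case-sensitive strings; records are unweighted.

new_error <- function(message, class) {
  structure(class = c(class, "coprune_error", "error", "condition"),
            list(message = message, call = NULL))
}

stop_coprune <- function(message, class) stop(new_error(message, class))

#' Site-by-species incidence table for one guild
#'
#' Constructs the boolean incidence of one guild's species across spatial
#' units (sites). Species present at no site are rejected: the table encodes
#' the realized spatial footprint, so an all-absent row is a data error.
#'
#' @param presence logical matrix, sites in rows, species in columns, with
#'   dimnames giving site and species identifiers.
#' @param guild `"consumer"` or `"resource"`.
#' @return An object of class `site_species_table`.
#' @export
site_species_table <- function(presence, guild = c("consumer", "resource")) {
  guild <- match.arg(guild)
  if (!is.matrix(presence) || !is.logical(presence))
    stop_coprune("`presence` must be a logical matrix (sites x species)",
                 "coprune_format_error")
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop_coprune("`presence` needs site and species dimnames",
                 "coprune_format_error")
  if (anyDuplicated(rownames(presence)))
    stop_coprune("duplicated site identifiers", "coprune_consistency_error")
  if (anyDuplicated(colnames(presence)))
    stop_coprune("duplicated species identifiers", "coprune_consistency_error")
  if (ncol(presence) == 0L)
    stop_coprune(sprintf("empty %s guild", guild), "coprune_consistency_error")
  empty <- colSums(presence) == 0L
  if (any(empty))
    stop_coprune(sprintf("species occupying no site: %s",
                         paste(colnames(presence)[empty], collapse = ", ")),
                 "coprune_consistency_error")
  structure(list(guild = guild,
                 species_ids = colnames(presence),
                 site_ids = rownames(presence),
                 presence = presence),
            class = "site_species_table")
}

#' @export
print.site_species_table <- function(x, ...) {
  cat(sprintf("<site_species_table> %s guild: %d species x %d sites, %d presences\n",
              x$guild, length(x$species_ids), length(x$site_ids),
              sum(x$presence)))
  invisible(x)
}

# Build a site_species_table from long records (site, species) for one guild.
table_from_records <- function(site, species, guild, all_sites) {
  species_ids <- sort(unique(species))
  presence <- matrix(FALSE, nrow = length(all_sites), ncol = length(species_ids),
                     dimnames = list(all_sites, species_ids))
  presence[cbind(match(site, all_sites), match(species, species_ids))] <- TRUE
  site_species_table(presence, guild)
}

#' Assemble a validated bipartite dataset
#'
#' Bundles the two guilds' incidence tables and the deduplicated interaction
#' records, enforcing referential integrity and the premise that
#' co-occurrence is a necessary condition for interaction: every recorded
#' interaction (site, consumer, resource) requires both partners present at
#' that site.
#'
#' @param consumers,resources `site_species_table` objects sharing the same
#'   site list.
#' @param interactions data frame with columns `site`, `consumer`,
#'   `resource`; duplicate rows are collapsed.
#' @param name dataset label carried through reports.
#' @param interaction_type `"PP"` (plant-pollinator) or `"HP"`
#'   (host-parasitoid).
#' @return An object of class `cooc_dataset`.
#' @export
cooc_dataset <- function(consumers, resources, interactions,
                         name = "dataset", interaction_type = c("PP", "HP")) {
  interaction_type <- match.arg(interaction_type)
  stopifnot(inherits(consumers, "site_species_table"),
            inherits(resources, "site_species_table"))
  if (!identical(consumers$site_ids, resources$site_ids))
    stop_coprune("consumer and resource tables must share the same site list",
                 "coprune_consistency_error")
  req <- c("site", "consumer", "resource")
  if (!all(req %in% names(interactions)))
    stop_coprune("interaction records need columns site, consumer, resource",
                 "coprune_format_error")
  interactions <- unique(interactions[req])
  interactions[] <- lapply(interactions, as.character)
  rownames(interactions) <- NULL

  bad_site <- !(interactions$site %in% consumers$site_ids)
  if (any(bad_site))
    stop_coprune(sprintf("interaction at unknown site: %s",
                         interactions$site[which(bad_site)[1L]]),
                 "coprune_consistency_error")
  bad_c <- !(interactions$consumer %in% consumers$species_ids)
  if (any(bad_c))
    stop_coprune(sprintf("unknown consumer in interactions: %s",
                         interactions$consumer[which(bad_c)[1L]]),
                 "coprune_consistency_error")
  bad_r <- !(interactions$resource %in% resources$species_ids)
  if (any(bad_r))
    stop_coprune(sprintf("unknown resource in interactions: %s",
                         interactions$resource[which(bad_r)[1L]]),
                 "coprune_consistency_error")

  pres_c <- consumers$presence[cbind(match(interactions$site, consumers$site_ids),
                                     match(interactions$consumer, consumers$species_ids))]
  pres_r <- resources$presence[cbind(match(interactions$site, resources$site_ids),
                                     match(interactions$resource, resources$species_ids))]
  bad <- !(pres_c & pres_r)
  if (any(bad)) {
    k <- which(bad)[1L]
    stop_coprune(sprintf(
      "interaction (%s, %s, %s) recorded where a partner is absent",
      interactions$site[k], interactions$consumer[k], interactions$resource[k]),
      "coprune_consistency_error")
  }

  structure(list(name = name, interaction_type = interaction_type,
                 consumers = consumers, resources = resources,
                 interactions = interactions),
            class = "cooc_dataset")
}

#' @export
print.cooc_dataset <- function(x, ...) {
  cat(sprintf("<cooc_dataset> '%s' (%s): %d consumers, %d resources, %d sites, %d interaction records\n",
              x$name, x$interaction_type,
              length(x$consumers$species_ids), length(x$resources$species_ids),
              length(x$consumers$site_ids), nrow(x$interactions)))
  invisible(x)
}

#' Load a dataset from long-format CSV files
#'
#' @param occurrence_path CSV with columns `site`, `guild`, `species`;
#'   `guild` must be `consumer` or `resource`.
#' @param interaction_path CSV with columns `site`, `consumer`, `resource`.
#' @param name,interaction_type passed to [cooc_dataset()].
#' @return A validated `cooc_dataset`. Validation order: file schema, then
#'   species/site referential integrity, then the co-occurrence-implies-
#'   presence rule; any violation is a typed error, never a silent drop.
#' @export
load_dataset <- function(occurrence_path, interaction_path,
                         name = "dataset", interaction_type = c("PP", "HP")) {
  occ <- read.csv(occurrence_path, colClasses = "character")
  if (!all(c("site", "guild", "species") %in% names(occ)))
    stop_coprune("occurrence file needs columns site, guild, species",
                 "coprune_format_error")
  if (!all(occ$guild %in% c("consumer", "resource")))
    stop_coprune("guild column must be 'consumer' or 'resource'",
                 "coprune_format_error")
  occ <- unique(occ)
  inter <- read.csv(interaction_path, colClasses = "character")
  if (!all(c("site", "consumer", "resource") %in% names(inter)))
    stop_coprune("interaction file needs columns site, consumer, resource",
                 "coprune_format_error")

  all_sites <- sort(unique(occ$site))
  cons <- occ[occ$guild == "consumer", ]
  res <- occ[occ$guild == "resource", ]
  if (nrow(cons) == 0L)
    stop_coprune("empty consumer guild", "coprune_consistency_error")
  if (nrow(res) == 0L)
    stop_coprune("empty resource guild", "coprune_consistency_error")
  consumers <- table_from_records(cons$site, cons$species, "consumer", all_sites)
  resources <- table_from_records(res$site, res$species, "resource", all_sites)
  cooc_dataset(consumers, resources, inter,
               name = name, interaction_type = interaction_type)
}

#' Write a dataset back to the canonical CSV pair
#'
#' Inverse of [load_dataset()]: `load_dataset(write_dataset(ds))` reproduces
#' `ds` up to species/site ordering. Long-format records cannot represent a
#' site at which no species occurs, so such sites (which carry no
#' co-occurrence information) are absent from the reloaded dataset.
#'
#' @param ds a `cooc_dataset`.
#' @param occurrence_path,interaction_path output CSV paths.
#' @export
write_dataset <- function(ds, occurrence_path, interaction_path) {
  long <- function(tab) {
    idx <- which(tab$presence, arr.ind = TRUE)
    data.frame(site = tab$site_ids[idx[, 1L]], guild = tab$guild,
               species = tab$species_ids[idx[, 2L]])
  }
  occ <- rbind(long(ds$consumers), long(ds$resources))
  occ <- occ[order(occ$site, occ$guild, occ$species), ]
  write.csv(occ, occurrence_path, row.names = FALSE, quote = FALSE)
  inter <- ds$interactions
  inter <- inter[order(inter$site, inter$consumer, inter$resource), ]
  write.csv(inter, interaction_path, row.names = FALSE, quote = FALSE)
  invisible(ds)
}

#' Write a bipartite network as an edge list with a JSON sidecar
#'
#' The edge list CSV has columns `consumer, resource`; the sidecar
#' `<path>.json` records guild sizes, link count and provenance so that
#' [read_network()] can reconstruct the network exactly (including species
#' with no links).
#'
#' @param net a `bipartite_network`.
#' @param path edge-list CSV path; sidecar written to `paste0(path, ".json")`.
#' @param dataset,seed optional provenance fields for the sidecar.
#' @export
write_network <- function(net, path, dataset = NA_character_, seed = NA_integer_) {
  stopifnot(inherits(net, "bipartite_network"))
  idx <- which(net$adjacency, arr.ind = TRUE)
  edges <- data.frame(consumer = net$consumers[idx[, 1L]],
                      resource = net$resources[idx[, 2L]])
  edges <- edges[order(edges$consumer, edges$resource), , drop = FALSE]
  write.csv(edges, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(dataset = dataset, kind = net$kind,
                  n_consumers = length(net$consumers),
                  n_resources = length(net$resources),
                  n_links = nrow(edges), seed = seed,
                  consumers = net$consumers, resources = net$resources)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(net)
}

#' Read a bipartite network written by [write_network()]
#'
#' @param path edge-list CSV path with its `.json` sidecar alongside.
#' @return A `bipartite_network`.
#' @export
read_network <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  edges <- read.csv(path, colClasses = "character")
  adjacency <- matrix(FALSE,
                      nrow = sidecar$n_consumers, ncol = sidecar$n_resources,
                      dimnames = list(sidecar$consumers, sidecar$resources))
  if (nrow(edges) > 0L)
    adjacency[cbind(match(edges$consumer, sidecar$consumers),
                    match(edges$resource, sidecar$resources))] <- TRUE
  bipartite_network(adjacency, kind = sidecar$kind)
}
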