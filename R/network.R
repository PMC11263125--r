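# Co-occurrence frequency matrix, binary bipartite networks and the realized
# link fraction f = L_int / L_c.

#' Bipartite network object
#'
#' @param adjacency logical consumers x resources matrix with dimnames.
#' @param kind one of `"cooccurrence"`, `"interaction"`, `"ir_realization"`,
#'   `"random_pruned"`.
#' @return An object of class `bipartite_network` with fields `consumers`,
#'   `resources`, `adjacency`, `kind`, `L` (link count).
#' @export
bipartite_network <- function(adjacency,
                              kind = c("cooccurrence", "interaction",
                                       "ir_realization", "random_pruned")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(adjacency), is.logical(adjacency),
            !is.null(rownames(adjacency)), !is.null(colnames(adjacency)))
  structure(list(consumers = rownames(adjacency),
                 resources = colnames(adjacency),
                 adjacency = adjacency, kind = kind,
                 L = sum(adjacency)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> kind=%s: %d consumers x %d resources, %d links\n",
              x$kind, length(x$consumers), length(x$resources), x$L))
  invisible(x)
}

#' Co-occurrence frequency matrix
#'
#' Counts, for every consumer-resource pair, the number of spatial units in
#' which both species are present: `N[a, i]` is the size of the intersection
#' of the two species' site sets. Row sums `N_alpha` give each consumer's
#' total co-occurrence frequency.
#'
#' @param consumers,resources `site_species_table` objects over the same
#'   sites.
#' @return An object of class `cooc_freq` with fields `consumers`,
#'   `resources`, `N` (integer matrix), `N_alpha`, `n_sites`.
#' @export
cooccurrence_frequencies <- function(consumers, resources) {
  stopifnot(inherits(consumers, "site_species_table"),
            inherits(resources, "site_species_table"))
  if (!identical(consumers$site_ids, resources$site_ids))
    stop_coprune("consumer and resource tables have mismatched site lists",
                 "coprune_consistency_error")
  # crossprod over the shared site axis counts shared sites per pair
  N <- crossprod(consumers$presence * 1L, resources$presence * 1L)
  storage.mode(N) <- "integer"
  dimnames(N) <- list(consumers$species_ids, resources$species_ids)
  structure(list(consumers = consumers$species_ids,
                 resources = resources$species_ids,
                 N = N, N_alpha = rowSums(N),
                 n_sites = length(consumers$site_ids)),
            class = "cooc_freq")
}

#' @export
print.cooc_freq <- function(x, ...) {
  cat(sprintf("<cooc_freq> %d consumers x %d resources over %d sites; %d co-occurring pairs\n",
              length(x$consumers), length(x$resources), x$n_sites,
              sum(x$N > 0L)))
  invisible(x)
}

# Accept either a cooc_freq or a bare integer matrix for model-level ops.
as_freq_matrix <- function(N) {
  if (inherits(N, "cooc_freq")) return(N$N)
  if (is.matrix(N) && is.numeric(N)) {
    if (any(N < 0) || any(N != round(N)))
      stop_coprune("co-occurrence frequencies must be non-negative integers",
                   "coprune_domain_error")
    return(N)
  }
  stop_coprune("`N` must be a cooc_freq object or an integer matrix",
               "coprune_format_error")
}

#' Binary co-occurrence network from a frequency matrix
#'
#' A consumer and a resource are linked when they co-occur in at least one
#' spatial unit (`N >= 1`); this is the network of potential interactions.
#'
#' @param N a `cooc_freq` object (or integer matrix with dimnames).
#' @return A `bipartite_network` of kind `"cooccurrence"`.
#' @export
cooccurrence_network <- function(N) {
  M <- as_freq_matrix(N)
  if (is.null(rownames(M)))
    dimnames(M) <- list(paste0("c", seq_len(nrow(M))),
                        paste0("r", seq_len(ncol(M))))
  bipartite_network(M >= 1L, kind = "cooccurrence")
}

#' Empirical biotic interaction network from a dataset
#'
#' A pair is linked when an interaction between them was recorded in at
#' least one spatial unit; site multiplicity collapses.
#'
#' @param ds a `cooc_dataset`.
#' @return A `bipartite_network` of kind `"interaction"`.
#' @export
interaction_network <- function(ds) {
  stopifnot(inherits(ds, "cooc_dataset"))
  adjacency <- matrix(FALSE,
                      nrow = length(ds$consumers$species_ids),
                      ncol = length(ds$resources$species_ids),
                      dimnames = list(ds$consumers$species_ids,
                                      ds$resources$species_ids))
  if (nrow(ds$interactions) > 0L)
    adjacency[cbind(match(ds$interactions$consumer, ds$consumers$species_ids),
                    match(ds$interactions$resource, ds$resources$species_ids))] <- TRUE
  bipartite_network(adjacency, kind = "interaction")
}

#' Realized link fraction f
#'
#' The proportion of co-occurrence (potential) links realized as biotic
#' interactions, `f = L_int / L_c`. The interaction network must be a subset
#' of the co-occurrence network (co-occurrence is necessary for
#' interaction).
#'
#' @param cooc,inter `bipartite_network`s on the same species orderings.
#' @return A list with `L_c`, `L_int`, `f`.
#' @export
link_fraction <- function(cooc, inter) {
  stopifnot(inherits(cooc, "bipartite_network"),
            inherits(inter, "bipartite_network"))
  if (!identical(cooc$consumers, inter$consumers) ||
      !identical(cooc$resources, inter$resources))
    stop_coprune("networks have different species orderings",
                 "coprune_consistency_error")
  if (cooc$L == 0L)
    stop_coprune("co-occurrence network has no links; f undefined",
                 "coprune_degenerate_error")
  if (any(inter$adjacency & !cooc$adjacency))
    stop_coprune("interaction network is not a subset of the co-occurrence network",
                 "coprune_consistency_error")
  list(L_c = cooc$L, L_int = inter$L, f = inter$L / cooc$L)
}

#' Degree sequences of a bipartite network
#'
#' @param net a `bipartite_network`.
#' @return List with `consumer_degrees` (row sums) and `resource_degrees`
#'   (column sums), named by species.
#' @export
degree_sequences <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  list(consumer_degrees = rowSums(net$adjacency),
       resource_degrees = colSums(net$adjacency))
}
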