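#' @section Parcellation:
#' The atlas bookkeeping layer: ROI-to-network assignment, enumeration of
#' ordered functional network pairs, and extraction of the directed
#' region-to-region connections belonging to each pair.
#' @name parcellation
NULL

# printed sizes of the 12 named networks in the Gordon-style schema
GORDON_SIZES <- c(
  Aud = 24, CiO = 40, CiP = 5, Def = 41, DoA = 32, FrP = 24,
  ReT = 8, SMl = 38, SMm = 8, Sal = 4, VeA = 23, Vis = 39
)
GORDON_UNASSIGNED <- 47L

#' The six heteromodal networks analyzed by default
#'
#' Cingulo-Parietal, Default, Dorsal Attention, Fronto-Parietal, Salience and
#' Ventral Attention: 129 ROIs forming 36 ordered network pairs.
#' @export
included_networks <- function() c("CiP", "Def", "DoA", "FrP", "Sal", "VeA")

new_parcellation <- function(roi_id, network, network_names = NULL) {
  network <- as.character(network)
  network[is.na(network) | network == "" |
            tolower(network) %in% c("none", "unassigned")] <- "UNASSIGNED"
  if (anyDuplicated(roi_id)) stop("duplicate roi_id in parcellation table")
  if (is.null(network_names)) {
    network_names <- unique(network[network != "UNASSIGNED"])
  }
  structure(
    list(
      n_roi = length(roi_id),
      roi_id = roi_id,                 # printed (1-based) atlas ids
      index = seq_along(roi_id) - 1L,  # 0-based internal indices
      network = network,
      network_names = network_names
    ),
    class = "parcellation_schema"
  )
}

#' @export
print.parcellation_schema <- function(x, ...) {
  cat(sprintf("<parcellation_schema> %d ROIs, %d networks, %d unassigned\n",
              x$n_roi, length(x$network_names), sum(x$network == "UNASSIGNED")))
  invisible(x)
}

#' Load a parcellation label table
#'
#' Reads a tab-separated table with columns `roi_id` and `network` (one row
#' per ROI). Blank, `None` or `Unassigned` network strings are mapped to the
#' sentinel `UNASSIGNED` and excluded from network enumeration.
#'
#' @param path path to a TSV file with header `roi_id<TAB>network`.
#' @return a `parcellation_schema` object.
#' @export
load_parcellation <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = c("integer", "character"))
  if (nrow(tab) == 0) stop("empty parcellation table: ", path)
  if (!all(c("roi_id", "network") %in% names(tab))) {
    stop("parcellation table must have columns roi_id and network")
  }
  new_parcellation(tab$roi_id, tab$network)
}

#' The packaged Gordon-style 333-ROI parcellation
#'
#' A 333-ROI schema with the 12 named functional networks at their published
#' sizes plus 47 unassigned ROIs. Within-network ROI identity is arbitrary
#' (only network membership enters this pipeline), so ROIs are assigned to
#' networks in contiguous blocks.
#'
#' @return a `parcellation_schema` with 333 ROIs and 12 networks.
#' @export
gordon_parcellation <- function() {
  path <- system.file("extdata", "gordon333_labels.tsv",
                      package = "connectodyn", mustWork = TRUE)
  schema <- load_parcellation(path)
  schema$network_names <- names(GORDON_SIZES)
  schema
}

#' Build a reduced parcellation with chosen network sizes
#'
#' Convenience constructor for small synthetic studies: networks are laid out
#' in contiguous blocks followed by `n_unassigned` unassigned ROIs.
#'
#' @param sizes named integer vector, network name -> ROI count.
#' @param n_unassigned number of trailing unassigned ROIs.
#' @return a `parcellation_schema`.
#' @export
#' @examples
#' scaled_parcellation(c(CiP = 3, FrP = 5), n_unassigned = 2)
scaled_parcellation <- function(sizes, n_unassigned = 0) {
  stopifnot(!is.null(names(sizes)), all(sizes >= 1))
  network <- c(rep(names(sizes), times = sizes), rep("UNASSIGNED", n_unassigned))
  new_parcellation(seq_along(network), network, names(sizes))
}

roi_indices <- function(schema, network) {
  schema$index[schema$network == network]
}

#' Enumerate ordered functional network pairs
#'
#' Produces all k^2 ordered pairs (including self-pairs) of the given
#' networks. Pair (A, B) collects the directed connections with the modeled
#' (target) region in A and the predictor (source) region in B; (A, B) and
#' (B, A) are distinct. Order is deterministic: the source network varies
#' slowest, matching the conventional tabulation.
#'
#' @param schema a `parcellation_schema`.
#' @param networks character vector of network names (default: the six
#'   heteromodal networks if present, else all named networks).
#' @return a list of `network_pair` objects of length `length(networks)^2`.
#' @export
enumerate_pairs <- function(schema, networks = NULL) {
  if (is.null(networks)) {
    networks <- if (all(included_networks() %in% schema$network_names)) {
      included_networks()
    } else {
      schema$network_names
    }
  }
  unknown <- setdiff(networks, schema$network_names)
  if (length(unknown)) {
    stop("unknown network name(s): ", paste(unknown, collapse = ", "))
  }
  pairs <- list()
  for (src in networks) {
    for (tgt in networks) {
      pairs[[length(pairs) + 1L]] <- new_network_pair(schema, tgt, src)
    }
  }
  pairs
}

new_network_pair <- function(schema, target, source) {
  ti <- roi_indices(schema, target)
  si <- roi_indices(schema, source)
  # row-major over (target order, source order), self-connections excluded
  conn <- cbind(
    target = rep(ti, each = length(si)),
    source = rep(si, times = length(ti))
  )
  conn <- conn[conn[, 1] != conn[, 2], , drop = FALSE]
  structure(
    list(target_network = target, source_network = source,
         connections = conn, n_roi = schema$n_roi),
    class = "network_pair"
  )
}

#' @export
print.network_pair <- function(x, ...) {
  cat(sprintf("<network_pair> %s and %s: %d connections\n",
              x$target_network, x$source_network, nrow(x$connections)))
  invisible(x)
}

#' Number of directed connections in a network pair
#'
#' `nA * nB` for distinct networks, `nA * (nA - 1)` for self-pairs.
#'
#' @param pair a `network_pair`.
#' @return integer count.
#' @export
count_connections <- function(pair) {
  stopifnot(inherits(pair, "network_pair"))
  nrow(pair$connections)
}

#' Extract a pair's connection values from a region-by-region matrix
#'
#' Values are returned in the pair's deterministic connection order
#' (row-major over target then source ROI); the matrix diagonal is never
#' touched.
#'
#' @param mat square numeric matrix, rows = target (modeled) region,
#'   columns = source (predictor) region, dimension = schema ROI count.
#' @param pair a `network_pair` built from the same schema.
#' @return numeric vector of length `count_connections(pair)`.
#' @export
extract_pair_values <- function(mat, pair) {
  stopifnot(inherits(pair, "network_pair"))
  if (!is.matrix(mat) || nrow(mat) != pair$n_roi || ncol(mat) != pair$n_roi) {
    stop(sprintf("matrix must be %d x %d to match the pair's schema",
                 pair$n_roi, pair$n_roi))
  }
  mat[pair$connections + 1L]
}

#' Connection-count table over a network family
#'
#' Mirrors the published per-pair connection tabulation: one row per ordered
#' pair, named `"target and source"`, plus the grand total.
#'
#' @param schema a `parcellation_schema`.
#' @param networks networks to enumerate (see [enumerate_pairs()]).
#' @return a tibble with columns `name`, `target`, `source`, `n_connections`.
#' @export
connection_table <- function(schema, networks = NULL) {
  pairs <- enumerate_pairs(schema, networks)
  tibble::tibble(
    name = vapply(pairs, function(p)
      paste(p$target_network, "and", p$source_network), ""),
    target = vapply(pairs, function(p) p$target_network, ""),
    source = vapply(pairs, function(p) p$source_network, ""),
    n_connections = vapply(pairs, count_connections, 1L)
  )
}

#' Write a connection-count report as TSV
#'
#' @param schema,networks passed to [connection_table()].
#' @param path output file.
#' @return the table, invisibly.
#' @export
write_connection_table <- function(schema, path, networks = NULL) {
  tab <- connection_table(schema, networks)
  out <- rbind(
    data.frame(name = tab$name, n_connections = tab$n_connections),
    data.frame(name = "Total", n_connections = sum(tab$n_connections))
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
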