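# Counted atom-pair fingerprints and Tanimoto chemosimilarity over the
# corpus of predicted intermediates.

.sdf_graph <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  from <- integer(0); to <- integer(0); order <- integer(0)
  if (is.matrix(bb) && nrow(bb) > 0L && ncol(bb) >= 3L) {
    from <- as.integer(bb[, 1]); to <- as.integer(bb[, 2])
    order <- as.integer(bb[, 3])
  }
  keep <- elements != "H"
  idx <- cumsum(keep)
  hb <- keep[from] & keep[to]
  list(elements = elements[keep], n = sum(keep),
       from = idx[from[hb]], to = idx[to[hb]], order = order[hb])
}

.bfs_distances <- function(n, from, to) {
  adj <- vector("list", n)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

#' Counted atom-pair fingerprint of a molecule
#'
#' Enumerates every pair of heavy atoms with its shortest-path topological
#' distance. Each atom is typed by the descriptor (element, heavy-atom
#' degree, pi-bond count); a pair triple is order-normalized so the
#' fingerprint is invariant under atom reordering. The result is a counted
#' multiset (named integer vector of triple counts), empty for molecules
#' with fewer than two heavy atoms.
#'
#' @param smiles A single SMILES string.
#' @return Named integer vector of class `atom_pair_fp`; names are
#'   `"El.deg.pi|El.deg.pi|dist"`.
#' @export
atom_pair_fingerprint <- function(smiles) {
  msg <- check_smiles_syntax(smiles)
  if (!is.null(msg))
    stop("invalid SMILES '", smiles, "': ", msg, call. = FALSE)
  g <- .sdf_graph(smiles)
  if (g$n < 2L)
    return(structure(integer(0), class = "atom_pair_fp"))
  pi_count <- integer(g$n)
  for (k in seq_along(g$from)) {
    add <- if (g$order[k] == 2L) 1L else if (g$order[k] == 3L) 2L
           else if (g$order[k] == 4L) 1L else 0L
    if (add > 0L) {
      pi_count[g$from[k]] <- pi_count[g$from[k]] + add
      pi_count[g$to[k]] <- pi_count[g$to[k]] + add
    }
  }
  degree <- tabulate(c(g$from, g$to), nbins = g$n)
  desc <- sprintf("%s.%d.%d", g$elements, degree, pi_count)
  D <- .bfs_distances(g$n, g$from, g$to)
  keys <- character(0)
  for (i in seq_len(g$n - 1L)) {
    for (j in (i + 1L):g$n) {
      if (is.na(D[i, j])) next  # disconnected fragments carry no pair
      pair <- sort(c(desc[i], desc[j]))
      keys <- c(keys, paste(pair[1], pair[2], D[i, j], sep = "|"))
    }
  }
  counts <- table(keys)
  structure(stats::setNames(as.integer(counts), names(counts)),
            class = "atom_pair_fp")
}

#' Multiset Tanimoto coefficient between two fingerprints
#'
#' `sum(min(counts)) / sum(max(counts))` over the union of triples. Two
#' empty fingerprints have similarity 1; exactly one empty gives 0.
#'
#' @param a,b `atom_pair_fp` fingerprints.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  if (length(a) == 0L || length(b) == 0L) return(0)
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), a[keys], 0L)
  bv <- ifelse(keys %in% names(b), b[keys], 0L)
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

#' Index the predicted intermediates of a cluster corpus
#'
#' Simulates every cluster and fingerprints each per-module intermediate in
#' its free-acid rendering, producing the searchable index behind the
#' structure search.
#'
#' @param clusters List of `ms_cluster` objects.
#' @param table A `substrate_table`.
#' @return An `intermediate_index`: data frame `records` (`cluster_id`,
#'   `module_index`, `smiles`) plus a parallel `fingerprints` list.
#' @export
build_intermediate_index <- function(clusters,
                                     table = default_substrates()) {
  recs <- list(); fps <- list()
  for (cl in clusters) {
    sim <- simulate_cluster(cl, table)
    for (i in seq_len(nrow(sim$intermediates))) {
      recs[[length(recs) + 1L]] <- data.frame(
        cluster_id = cl$id,
        module_index = sim$intermediates$module_index[i],
        smiles = sim$intermediates$smiles[i])
      fps[[length(fps) + 1L]] <-
        atom_pair_fingerprint(sim$intermediates$smiles[i])
    }
  }
  structure(list(records = if (length(recs)) do.call(rbind, recs)
                           else data.frame(cluster_id = character(0),
                                           module_index = integer(0),
                                           smiles = character(0)),
                 fingerprints = fps),
            class = "intermediate_index")
}

#' Persist or reload an intermediate index
#'
#' TSV of `cluster_id`, `module_index`, `smiles`; fingerprints are
#' recomputed on load (they are derived data).
#'
#' @param index An `intermediate_index`.
#' @param path TSV file path.
#' @return `path` (write) or an `intermediate_index` (read).
#' @export
write_intermediate_index <- function(index, path) {
  stopifnot(inherits(index, "intermediate_index"))
  utils::write.table(index$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_intermediate_index
#' @export
read_intermediate_index <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  structure(list(records = df,
                 fingerprints = lapply(df$smiles, atom_pair_fingerprint)),
            class = "intermediate_index")
}

#' Rank indexed intermediates against a target molecule
#'
#' Scores every indexed intermediate by atom-pair Tanimoto similarity to
#' the target; ties are broken by (`cluster_id`, `module_index`). The top
#' hit's module is named as the recommended truncation/graft point for
#' chimera design.
#'
#' @param target Target molecule SMILES.
#' @param index An `intermediate_index`.
#' @param top_k Number of records to return (capped at the index size).
#' @return A `structure_hits` object: data frame with `rank`, `cluster_id`,
#'   `module_index`, `similarity`, `smiles`, plus a `recommendation`
#'   string.
#' @export
search_structure <- function(target, index, top_k = 10L) {
  stopifnot(inherits(index, "intermediate_index"))
  if (nrow(index$records) == 0L) stop("empty intermediate index",
                                      call. = FALSE)
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  tfp <- atom_pair_fingerprint(target)
  sims <- vapply(index$fingerprints, tanimoto, numeric(1), b = tfp)
  ord <- order(-sims, index$records$cluster_id, index$records$module_index,
               method = "radix")
  keep <- ord[seq_len(min(top_k, length(ord)))]
  hits <- data.frame(rank = seq_along(keep),
                     cluster_id = index$records$cluster_id[keep],
                     module_index = index$records$module_index[keep],
                     similarity = sims[keep],
                     smiles = index$records$smiles[keep])
  rec <- sprintf(
    "truncate cluster %s after module %d (similarity %.3f) as graft point",
    hits$cluster_id[1], hits$module_index[1], hits$similarity[1])
  structure(list(target = target, hits = hits, recommendation = rec),
            class = "structure_hits")
}

#' @export
print.structure_hits <- function(x, n = 5L, ...) {
  cat("<structure_hits> target ", x$target, "\n", sep = "")
  print(utils::head(x$hits, n))
  cat("  ", x$recommendation, "\n", sep = "")
  invisible(x)
}
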