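# Shared helpers: compact cluster builders and independent oracles used
# across the suite.

mod <- function(..., loading = FALSE) new_module(list(...), is_loading = loading)

load_at <- function(code)
  mod(new_domain("AT", substrate_code = code, is_loading = TRUE),
      new_domain("ACP"), loading = TRUE)

load_a <- function(code)
  mod(new_domain("A", substrate_code = code), new_domain("PCP"),
      loading = TRUE)

one_sub_cluster <- function(id, ...) {
  new_cluster(id, id, list(new_subunit("s1", list(...))))
}

canon <- function(smiles) canonical_smiles(smiles)

# Plain exponential recursion (no memoization): the independent Levenshtein
# oracle.
lev_recursive <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  ra <- substring(a, 2L); rb <- substring(b, 2L)
  if (substr(a, 1L, 1L) == substr(b, 1L, 1L)) return(lev_recursive(ra, rb))
  1L + min(lev_recursive(ra, rb), lev_recursive(ra, b), lev_recursive(a, rb))
}

random_string <- function(max_len, alphabet = letters[1:10]) {
  paste(sample(alphabet, sample(0:max_len, 1L), replace = TRUE),
        collapse = "")
}

# Independent atom-pair enumeration: graph distances and degrees via
# igraph, descriptors recomputed from the raw SDF blocks.
ap_oracle <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  stopifnot(!any(el == "H"))
  n <- length(el)
  if (n < 2L) return(structure(integer(0), class = "atom_pair_fp"))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  pi_e <- integer(n)
  if (!is.matrix(bb) || ncol(bb) < 3L) bb <- NULL
  if (!is.null(bb) && nrow(bb) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(bb[, 1:2, drop = FALSE])))
    for (k in seq_len(nrow(bb))) {
      add <- c(`2` = 1L, `3` = 2L, `4` = 1L)[as.character(bb[k, 3])]
      if (!is.na(add)) {
        pi_e[bb[k, 1]] <- pi_e[bb[k, 1]] + add
        pi_e[bb[k, 2]] <- pi_e[bb[k, 2]] + add
      }
    }
  }
  desc <- sprintf("%s.%d.%d", el, igraph::degree(g), pi_e)
  D <- igraph::distances(g)
  keys <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!is.finite(D[i, j])) next
    p <- sort(c(desc[i], desc[j]))
    keys <- c(keys, paste(p[1], p[2], as.integer(D[i, j]), sep = "|"))
  }
  counts <- table(keys)
  structure(stats::setNames(as.integer(counts), names(counts)),
            class = "atom_pair_fp")
}

fp_equal <- function(a, b) {
  identical(sort(names(a)), sort(names(b))) &&
    all(a[sort(names(a))] == b[sort(names(a))])
}
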