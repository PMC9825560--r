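# Domain Architecture Cluster Search: encode each cluster's active-domain
# configuration tokens as a Unicode string (one character per unique
# configuration, via a persistent alphabet registry), rank database entries
# by Levenshtein distance, and render edit scripts as domain-change
# instructions for chimera design.

.ALPHABET_BASE <- 0x2500L  # first codepoint handed out; printable, compact

#' Alphabet registry mapping domain tokens to Unicode characters
#'
#' The registry is a bijection between domain-configuration tokens (from
#' [architecture_of()]) and single Unicode characters. It is append-only:
#' new tokens get the next free codepoint and existing assignments are never
#' reassigned, so encodings are stable across runs when the registry is
#' persisted with [write_alphabet_registry()].
#'
#' @param tokens Optional character vector of tokens to register up front
#'   (registered in sorted order for reproducible corpus builds).
#' @return An `alphabet_registry`.
#' @export
new_alphabet_registry <- function(tokens = character(0)) {
  reg <- new.env(parent = emptyenv())
  reg$token_to_cp <- integer(0)
  class(reg) <- "alphabet_registry"
  if (length(tokens)) registry_chars(reg, sort(unique(tokens)))
  reg
}

#' Look up (and assign) characters for tokens
#'
#' @param registry An `alphabet_registry`.
#' @param tokens Character vector of domain-configuration tokens; unseen
#'   tokens are appended to the registry.
#' @return Character vector of single characters, one per token.
#' @export
registry_chars <- function(registry, tokens) {
  stopifnot(inherits(registry, "alphabet_registry"))
  map <- registry$token_to_cp
  new_tokens <- setdiff(tokens, names(map))
  if (length(new_tokens)) {
    nxt <- if (length(map)) max(map) + 1L else .ALPHABET_BASE
    add <- seq.int(nxt, length.out = length(new_tokens))
    names(add) <- new_tokens
    registry$token_to_cp <- c(map, add)
    map <- registry$token_to_cp
  }
  vapply(tokens, function(tk) intToUtf8(map[[tk]]), character(1),
         USE.NAMES = FALSE)
}

#' Decode an encoded architecture back to tokens
#'
#' @param text Encoded architecture string.
#' @param registry The `alphabet_registry` used to encode it.
#' @return Character vector of domain-configuration tokens.
#' @export
registry_tokens <- function(text, registry) {
  stopifnot(inherits(registry, "alphabet_registry"))
  map <- registry$token_to_cp
  rev_map <- names(map)
  names(rev_map) <- vapply(map, intToUtf8, character(1))
  chars <- strsplit(text, "")[[1]]
  unknown <- setdiff(chars, names(rev_map))
  if (length(unknown))
    stop("characters not in registry: ",
         paste(sprintf("U+%04X", utf8ToInt(paste(unknown, collapse = ""))),
               collapse = ", "), call. = FALSE)
  unname(rev_map[chars])
}

#' Persist or reload an alphabet registry
#'
#' The sidecar is a TSV of `token`, `codepoint` pairs; reloading yields
#' byte-identical encodings.
#'
#' @param registry An `alphabet_registry`.
#' @param path Sidecar file path (conventionally `alphabet.tsv`).
#' @return `path` (write) or an `alphabet_registry` (read).
#' @export
write_alphabet_registry <- function(registry, path) {
  stopifnot(inherits(registry, "alphabet_registry"))
  map <- registry$token_to_cp
  df <- data.frame(token = names(map), codepoint = unname(map))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_alphabet_registry
#' @export
read_alphabet_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  reg <- new_alphabet_registry()
  map <- as.integer(df$codepoint)
  names(map) <- df$token
  reg$token_to_cp <- map
  reg
}

#' Encode a cluster's architecture as a Unicode string
#'
#' One character per active-domain configuration token; the registry is
#' extended for unseen tokens. Encode after [repair_reductive_domains()] so
#' the string reflects the chemistry that actually runs. With
#' `by_subunit = TRUE` each subunit is encoded separately.
#'
#' @param cluster An `ms_cluster`.
#' @param registry An `alphabet_registry` (mutated in place as tokens are
#'   assigned).
#' @param by_subunit Encode each subunit as its own string.
#' @return An `encoded_architecture`: list of `cluster_id` and `text`
#'   (named character vector of subunit strings when `by_subunit`).
#' @export
encode_architecture <- function(cluster, registry, by_subunit = FALSE) {
  stopifnot(inherits(cluster, "ms_cluster"))
  if (by_subunit) {
    texts <- vapply(cluster$subunits, function(su) {
      toks <- unlist(lapply(su$modules, function(m)
        vapply(Filter(function(d) d$active, m$domains), .domain_token,
               character(1))), use.names = FALSE)
      paste(registry_chars(registry, toks %||% character(0)), collapse = "")
    }, character(1))
    names(texts) <- vapply(cluster$subunits, `[[`, character(1), "name")
  } else {
    toks <- architecture_of(cluster)
    texts <- paste(registry_chars(registry, toks), collapse = "")
  }
  structure(list(cluster_id = cluster$id, text = texts),
            class = "encoded_architecture")
}

.arch_similarity <- function(distance, la, lb) {
  denom <- max(la, lb)
  if (denom == 0L) 1 else 1 - distance / denom
}

#' Search a database of encoded architectures
#'
#' Ranks database entries against the query by similarity
#' `1 - d / max(|query|, |hit|)` (two empty strings have similarity 1),
#' breaking ties by `cluster_id` lexicographic order (C locale). Each hit
#' carries the Levenshtein distance and the edit script turning the query
#' architecture into the hit, both positionally and rendered as
#' human-readable domain-change instructions.
#'
#' @param query An `ms_cluster` (encoded after repair) or an
#'   `encoded_architecture` with a scalar `text`.
#' @param database List of `encoded_architecture` objects (scalar texts).
#' @param registry The `alphabet_registry` shared by query and database.
#' @param top_k Number of hits to return (capped at the database size).
#' @return A `search_hits` object: data frame `hits` (`rank`, `cluster_id`,
#'   `distance`, `similarity`) plus parallel lists `scripts` and
#'   `instructions`.
#' @export
search_architecture <- function(query, database, registry, top_k = 10L) {
  if (length(database) == 0L) stop("empty architecture database",
                                   call. = FALSE)
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  if (inherits(query, "ms_cluster")) {
    query <- encode_architecture(repair_reductive_domains(query)$cluster,
                                 registry)
  }
  stopifnot(inherits(query, "encoded_architecture"),
            length(query$text) == 1L)
  qtext <- unname(query$text)
  ids <- vapply(database, `[[`, character(1), "cluster_id")
  res <- lapply(database, function(e) levenshtein(qtext, unname(e$text)))
  dist <- vapply(res, `[[`, integer(1), "distance")
  sim <- mapply(.arch_similarity, dist, nchar(qtext),
                vapply(database, function(e) nchar(unname(e$text)),
                       integer(1)))
  ord <- order(-sim, ids, method = "radix")
  keep <- ord[seq_len(min(top_k, length(ord)))]
  hits <- data.frame(rank = seq_along(keep), cluster_id = ids[keep],
                     distance = dist[keep], similarity = sim[keep])
  scripts <- lapply(res[keep], `[[`, "script")
  instructions <- lapply(scripts, .render_instructions, registry = registry)
  structure(list(query = qtext, hits = hits, scripts = scripts,
                 instructions = instructions),
            class = "search_hits")
}

.render_instructions <- function(script, registry) {
  if (nrow(script) == 0L) return(character(0))
  vapply(seq_len(nrow(script)), function(k) {
    tok <- function(ch) registry_tokens(ch, registry)
    switch(script$op[k],
      delete = sprintf("delete domain at position %d (%s)", script$pos[k],
                       tok(script$char[k])),
      replace = sprintf("replace domain at position %d with %s",
                        script$pos[k], tok(script$char[k])),
      add = sprintf("add %s at position %d", tok(script$char[k]),
                    script$pos[k]))
  }, character(1))
}

#' @export
print.search_hits <- function(x, n = 5L, ...) {
  cat("<search_hits> query length ", nchar(x$query), ", ",
      nrow(x$hits), " hit(s)\n", sep = "")
  print(utils::head(x$hits, n))
  invisible(x)
}

#' Render an edit script for TSV output
#' @param script Edit script data frame.
#' @return A single compact string, e.g. `"replace@3=KR:A1;delete@5"`.
#' @keywords internal
format_edit_script <- function(script) {
  if (nrow(script) == 0L) return("")
  paste(vapply(seq_len(nrow(script)), function(k)
    switch(script$op[k],
           delete = sprintf("delete@%d", script$pos[k]),
           replace = sprintf("replace@%d=%s", script$pos[k],
                             script$char[k]),
           add = sprintf("add@%d=%s", script$pos[k], script$char[k])),
    character(1)), collapse = ";")
}
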