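# Cluster JSON interchange: strict schema-enforced reader and a canonical
# writer (fixed key order), so that read -> write round-trips byte-exactly
# on files produced by the writer. The normative schema document ships at
# inst/schema/cluster.schema.json.

.check_keys <- function(obj, required, optional, where) {
  if (!is.list(obj) || is.null(names(obj)) && length(obj) > 0L)
    stop(where, ": expected a JSON object", call. = FALSE)
  keys <- names(obj)
  unknown <- setdiff(keys, c(required, optional))
  if (length(unknown))
    stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(required, keys)
  if (length(missing))
    stop(where, ": missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

.scalar_chr <- function(x, where) {
  if (!is.character(x) || length(x) != 1L)
    stop(where, ": expected a string", call. = FALSE)
  x
}

.scalar_lgl <- function(x, where) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(where, ": expected true/false", call. = FALSE)
  x
}

#' Read a cluster from schema-validated JSON
#'
#' Enforces the interchange schema strictly: unknown keys anywhere in the
#' document are rejected with an error naming the key and its location, and
#' every enumeration and attribute record is checked during construction.
#'
#' @param path Path to a cluster JSON file.
#' @return An `ms_cluster`.
#' @export
read_cluster <- function(path) {
  stopifnot(file.exists(path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cluster_from_list(doc, where = basename(path))
}

#' @rdname read_cluster
#' @param doc A nested list following the cluster JSON schema.
#' @param where Label used in error messages.
#' @export
cluster_from_list <- function(doc, where = "cluster") {
  .check_keys(doc, c("id", "name", "reviewed", "subunits"), "notes", where)
  subunits <- lapply(seq_along(doc$subunits), function(si) {
    su <- doc$subunits[[si]]
    w <- sprintf("%s/subunits[%d]", where, si - 1L)
    .check_keys(su, c("name", "modules"), "description", w)
    modules <- lapply(seq_along(su$modules), function(mi) {
      mo <- su$modules[[mi]]
      wm <- sprintf("%s/modules[%d]", w, mi - 1L)
      .check_keys(mo, c("is_loading", "domains"), character(0), wm)
      domains <- lapply(seq_along(mo$domains), function(di) {
        d <- mo$domains[[di]]
        wd <- sprintf("%s/domains[%d]", wm, di - 1L)
        .check_keys(d, c("kind", "active"), "attributes", wd)
        kind <- .scalar_chr(d$kind, paste0(wd, "/kind"))
        if (!kind %in% DOMAIN_KINDS)
          stop(wd, ": unknown domain kind '", kind, "'", call. = FALSE)
        attrs <- d$attributes %||% list()
        allowed <- .domain_attr_keys[[kind]] %||% character(0)
        unknown <- setdiff(names(attrs), allowed)
        if (length(unknown))
          stop(wd, ": unknown attribute key(s) for ", kind, ": ",
               paste(unknown, collapse = ", "), call. = FALSE)
        tryCatch(
          do.call(new_domain, c(list(kind = kind,
                                     active = .scalar_lgl(d$active,
                                       paste0(wd, "/active"))), attrs)),
          error = function(e) stop(wd, ": ", conditionMessage(e),
                                   call. = FALSE))
      })
      new_module(domains, is_loading = .scalar_lgl(mo$is_loading,
                                                   paste0(wm, "/is_loading")))
    })
    new_subunit(.scalar_chr(su$name, paste0(w, "/name")), modules,
                description = if (!is.null(su$description))
                  .scalar_chr(su$description, paste0(w, "/description")))
  })
  new_cluster(id = .scalar_chr(doc$id, paste0(where, "/id")),
              name = .scalar_chr(doc$name, paste0(where, "/name")),
              subunits = subunits,
              reviewed = .scalar_lgl(doc$reviewed,
                                     paste0(where, "/reviewed")),
              notes = if (!is.null(doc$notes))
                .scalar_chr(doc$notes, paste0(where, "/notes")))
}

.empty_object <- function() structure(list(), names = character(0))

.domain_to_list <- function(d) {
  a <- d$attributes
  attrs <- switch(d$kind,
    AT = list(substrate_code = a$substrate_code,
              is_loading = a$is_loading),
    KR = list(kr_type = a$kr_type),
    C = list(c_type = a$c_type),
    A = list(substrate_code = a$substrate_code,
             modification = a$modification),
    AOX = list(substrate_code = a$substrate_code),
    TE = c(list(release_mode = a$release_mode),
           if (!is.null(a$ring_site)) list(ring_site = a$ring_site)),
    R = list(product_level = a$product_level),
    CAL = ,
    ACP = c(if (!is.null(a$starter_code))
              list(starter_code = a$starter_code),
            if (!is.null(a$starter_smiles))
              list(starter_smiles = a$starter_smiles)),
    list())
  if (length(attrs) == 0L) attrs <- .empty_object()
  list(kind = d$kind, active = d$active, attributes = attrs)
}

#' Serialize a cluster to its canonical list / JSON form
#'
#' The writer emits keys in a fixed order with stable formatting, so
#' writing, reading and re-writing a cluster file is byte-identical.
#'
#' @param cluster An `ms_cluster`.
#' @return `cluster_to_list()`: a nested list; `cluster_to_json()`: a JSON
#'   string.
#' @export
cluster_to_list <- function(cluster) {
  stopifnot(inherits(cluster, "ms_cluster"))
  list(
    id = cluster$id,
    name = cluster$name,
    reviewed = cluster$reviewed,
    notes = cluster$notes,
    subunits = lapply(cluster$subunits, function(su) list(
      name = su$name,
      description = su$description,
      modules = lapply(su$modules, function(m) list(
        is_loading = m$is_loading,
        domains = lapply(m$domains, .domain_to_list))))))
}

#' @rdname cluster_to_list
#' @export
cluster_to_json <- function(cluster) {
  jsonlite::toJSON(cluster_to_list(cluster), auto_unbox = TRUE, pretty = 2,
                   null = "null", digits = NA)
}

#' @rdname cluster_to_list
#' @param path Output file path.
#' @export
write_cluster <- function(cluster, path) {
  writeLines(cluster_to_json(cluster), path, useBytes = TRUE)
  invisible(path)
}

#' Path to the shipped cluster JSON Schema document
#' @return File path of `cluster.schema.json`.
#' @export
cluster_schema_path <- function() {
  system.file("schema", "cluster.schema.json", package = "megasynth")
}
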