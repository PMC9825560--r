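# Cluster data model: domains, modules, subunits, clusters; validation of
# the composition rules; the structure-informed reductive-domain repair; and
# serialization of a cluster to its domain-configuration token list.

DOMAIN_KINDS <- c("KS", "AT", "KR", "DH", "ER", "MT", "ACP", "PCP", "CAL",
                  "C", "A", "E", "F", "nMT", "Cy", "AOX", "R", "TE", "X")
KR_TYPES <- c("A1", "A2", "B1", "B2", "C1", "C2", "U")
KR_REDUCING_TYPES <- c("A1", "A2", "B1", "B2", "U")
C_TYPES <- c("Starter", "LCL", "DCL", "Glycopeptide", "Dual")
A_MODIFICATIONS <- c("oxidation", "reduction", "none")
TE_MODES <- c("hydrolysis", "lactone", "lactam")
R_LEVELS <- c("aldehyde", "alcohol")

.domain_attr_keys <- list(
  AT  = c("substrate_code", "is_loading"),
  KR  = "kr_type",
  C   = "c_type",
  A   = c("substrate_code", "modification"),
  AOX = "substrate_code",
  TE  = c("release_mode", "ring_site"),
  R   = "product_level",
  CAL = c("starter_code", "starter_smiles"),
  ACP = c("starter_code", "starter_smiles")
)

#' Construct a megasynthase domain
#'
#' @param kind One of the supported domain kinds (`KS`, `AT`, `KR`, `DH`,
#'   `ER`, `MT`, `ACP`, `PCP`, `CAL`, `C`, `A`, `E`, `F`, `nMT`, `Cy`,
#'   `AOX`, `R`, `TE`, `X`).
#' @param ... Kind-specific attributes: `substrate_code`/`is_loading` (AT),
#'   `kr_type` (KR), `c_type` (C), `substrate_code`/`modification` (A),
#'   `release_mode`/`ring_site` (TE), `product_level` (R),
#'   `starter_code`/`starter_smiles` (CAL and standalone loading ACP).
#' @param active Inactive domains are retained in the model but perform no
#'   chemistry and are excluded from architecture tokens.
#' @return A `ms_domain` object.
#' @examples
#' new_domain("AT", substrate_code = "mmal")
#' new_domain("KR", kr_type = "B1")
#' new_domain("TE", release_mode = "lactam", ring_site = 0L)
#' @export
new_domain <- function(kind, ..., active = TRUE) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% DOMAIN_KINDS)
    stop("unknown domain kind: ", kind, call. = FALSE)
  attrs <- list(...)
  allowed <- .domain_attr_keys[[kind]]
  bad <- setdiff(names(attrs), allowed)
  if (length(bad))
    stop("domain kind ", kind, " does not take attribute(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (kind == "AT") {
    if (is.null(attrs$substrate_code))
      stop("AT domain requires substrate_code", call. = FALSE)
    attrs$is_loading <- isTRUE(attrs$is_loading)
  }
  if (kind == "KR") {
    if (is.null(attrs$kr_type) || !attrs$kr_type %in% KR_TYPES)
      stop("KR kr_type must be one of: ", paste(KR_TYPES, collapse = ", "),
           call. = FALSE)
  }
  if (kind == "C") {
    if (is.null(attrs$c_type) || !attrs$c_type %in% C_TYPES)
      stop("C c_type must be one of: ", paste(C_TYPES, collapse = ", "),
           call. = FALSE)
  }
  if (kind %in% c("A", "AOX")) {
    if (is.null(attrs$substrate_code))
      stop(kind, " domain requires substrate_code", call. = FALSE)
    if (kind == "A") {
      if (is.null(attrs$modification)) attrs$modification <- "none"
      if (!attrs$modification %in% A_MODIFICATIONS)
        stop("A modification must be one of: ",
             paste(A_MODIFICATIONS, collapse = ", "), call. = FALSE)
    }
  }
  if (kind == "TE") {
    if (is.null(attrs$release_mode) || !attrs$release_mode %in% TE_MODES)
      stop("TE release_mode must be one of: ",
           paste(TE_MODES, collapse = ", "), call. = FALSE)
    cyclic <- attrs$release_mode %in% c("lactone", "lactam")
    if (cyclic && is.null(attrs$ring_site))
      stop("TE ", attrs$release_mode, " requires ring_site", call. = FALSE)
    if (!cyclic && !is.null(attrs$ring_site))
      stop("TE hydrolysis takes no ring_site", call. = FALSE)
    if (!is.null(attrs$ring_site)) {
      attrs$ring_site <- as.integer(attrs$ring_site)
      if (is.na(attrs$ring_site) || attrs$ring_site < 0L)
        stop("ring_site must be a non-negative 0-based unit ordinal",
             call. = FALSE)
    }
  }
  if (kind == "R") {
    if (is.null(attrs$product_level) || !attrs$product_level %in% R_LEVELS)
      stop("R product_level must be one of: ",
           paste(R_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (kind == "CAL") {
    n_set <- sum(!vapply(attrs[c("starter_code", "starter_smiles")],
                         is.null, logical(1)))
    if (n_set != 1L)
      stop("CAL requires exactly one of starter_code, starter_smiles",
           call. = FALSE)
  }
  structure(list(kind = kind, active = isTRUE(active), attributes = attrs),
            class = "ms_domain")
}

#' Construct a module, subunit or cluster
#'
#' Modules hold ordered domains in N-to-C order; subunits hold ordered
#' modules; a cluster is an ordered list of subunits. Module indices are
#' assigned contiguously across the cluster at assembly (0-based, loading
#' module first).
#'
#' @param domains List of `ms_domain` objects.
#' @param is_loading Is this the loading (chain-initiation) module?
#' @return `ms_module`, `ms_subunit` or `ms_cluster` object.
#' @export
new_module <- function(domains, is_loading = FALSE) {
  stopifnot(is.list(domains),
            all(vapply(domains, inherits, logical(1), "ms_domain")))
  structure(list(index = NA_integer_, domains = domains,
                 is_loading = isTRUE(is_loading)),
            class = "ms_module")
}

#' @rdname new_module
#' @param name Subunit (polypeptide) or cluster name.
#' @param modules List of `ms_module` objects.
#' @param description Optional free-text description.
#' @export
new_subunit <- function(name, modules, description = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.list(modules),
            all(vapply(modules, inherits, logical(1), "ms_module")))
  structure(list(name = name, modules = modules, description = description),
            class = "ms_subunit")
}

#' @rdname new_module
#' @param id Stable cluster identifier.
#' @param subunits List of `ms_subunit` objects.
#' @param reviewed Manual-curation indicator.
#' @param notes Optional curation notes.
#' @export
new_cluster <- function(id, name, subunits, reviewed = FALSE, notes = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(name), length(name) == 1L,
            is.list(subunits),
            all(vapply(subunits, inherits, logical(1), "ms_subunit")))
  cl <- structure(list(id = id, name = name, subunits = subunits,
                       reviewed = isTRUE(reviewed), notes = notes),
                  class = "ms_cluster")
  idx <- 0L
  for (s in seq_along(cl$subunits)) {
    for (m in seq_along(cl$subunits[[s]]$modules)) {
      cl$subunits[[s]]$modules[[m]]$index <- idx
      idx <- idx + 1L
    }
  }
  cl
}

#' Flatten a cluster to its ordered module list
#'
#' @param cluster An `ms_cluster`.
#' @return List of `ms_module` objects in N-to-C (index) order.
#' @export
cluster_modules <- function(cluster) {
  stopifnot(inherits(cluster, "ms_cluster"))
  unlist(lapply(cluster$subunits, `[[`, "modules"), recursive = FALSE)
}

# Apply a function to every module, writing results back in place.
.map_modules <- function(cluster, fn) {
  for (s in seq_along(cluster$subunits)) {
    for (m in seq_along(cluster$subunits[[s]]$modules)) {
      cluster$subunits[[s]]$modules[[m]] <-
        fn(cluster$subunits[[s]]$modules[[m]])
    }
  }
  cluster
}

.module_kinds <- function(module, active_only = FALSE) {
  doms <- module$domains
  if (active_only) doms <- Filter(function(d) d$active, doms)
  vapply(doms, `[[`, character(1), "kind")
}

.find_domain <- function(module, kind, active_only = TRUE) {
  for (d in module$domains)
    if (d$kind == kind && (!active_only || d$active)) return(d)
  NULL
}

#' @export
print.ms_cluster <- function(x, ...) {
  mods <- cluster_modules(x)
  cat("<ms_cluster> ", x$id, " (", x$name, "): ",
      length(x$subunits), " subunit(s), ", length(mods), " module(s)",
      if (x$reviewed) ", reviewed", "\n", sep = "")
  for (m in mods) {
    kinds <- vapply(m$domains, function(d)
      paste0(d$kind, if (!d$active) "(inactive)"), character(1))
    cat(sprintf("  module %d%s: %s\n", m$index,
                if (m$is_loading) " [loading]" else "",
                paste(kinds, collapse = "-")))
  }
  invisible(x)
}

# ---- validation -----------------------------------------------------------

.loading_cores <- list(c("AT", "ACP"), c("CAL", "ACP"), c("CAL", "PCP"),
                       c("A", "PCP"), "ACP")
.pks_only <- c("KS", "AT", "KR", "DH", "ER", "MT")
.nrps_only <- c("C", "A", "Cy", "E", "F", "nMT", "AOX")

#' Validate a cluster against the composition rules
#'
#' Checks every module-composition invariant (one carrier domain per module;
#' loading cores AT+ACP, CAL+ACP, CAL+PCP, A+PCP or standalone ACP; KS+AT in
#' PKS extension modules; C/Cy+A in NRPS extension modules; a single
#' terminal TE or R release domain in the final module) and resolves every
#' substrate code against the active substrate table. A cluster with a
#' non-empty error list is rejected by [simulate_cluster()].
#'
#' @param cluster An `ms_cluster`.
#' @param table A `substrate_table`.
#' @return A `validation_report` with `errors` and `warnings` data frames
#'   (`module`, `message`).
#' @export
validate_cluster <- function(cluster, table = default_substrates()) {
  stopifnot(inherits(cluster, "ms_cluster"))
  errors <- list(); warnings <- list()
  err <- function(mod, msg) errors[[length(errors) + 1L]] <<-
    data.frame(module = mod, message = msg)
  wrn <- function(mod, msg) warnings[[length(warnings) + 1L]] <<-
    data.frame(module = mod, message = msg)

  mods <- cluster_modules(cluster)
  if (length(mods) == 0L) {
    err(NA_integer_, "cluster has no modules")
  } else {
    if (!mods[[1]]$is_loading)
      err(0L, "first module must be the loading module")
    for (m in mods[-1]) if (m$is_loading)
      err(m$index, "only module 0 may be a loading module")
  }

  n_units <- length(mods)  # one chain unit per loading/extension module
  release_seen <- character(0)

  for (m in mods) {
    kinds <- .module_kinds(m)
    if (length(kinds) == 0L) { err(m$index, "module has no domains"); next }
    n_carrier <- sum(kinds %in% c("ACP", "PCP"))
    if (n_carrier != 1L)
      err(m$index, paste0("module must contain exactly one carrier domain ",
                          "(ACP or PCP), found ", n_carrier))
    core <- setdiff(kinds, c("TE", "R", "X"))
    if (m$is_loading) {
      core_sorted <- sort(unique(core))
      ok <- any(vapply(.loading_cores, function(cc)
        identical(sort(cc), core_sorted), logical(1))) &&
        !anyDuplicated(core)
      if (!ok) {
        err(m$index, paste0("loading module must be one of AT+ACP, CAL+ACP, ",
                            "CAL+PCP, A+PCP or standalone ACP; found ",
                            paste(core, collapse = "+")))
      } else {
        at <- .find_domain(m, "AT", active_only = FALSE)
        if (!is.null(at)) {
          if (!isTRUE(at$attributes$is_loading))
            err(m$index, "loading AT domain must set is_loading")
          else if (!at$attributes$substrate_code %in% names(table$starters))
            err(m$index, paste0("unresolved starter code '",
                                at$attributes$substrate_code, "'"))
        }
        cal <- .find_domain(m, "CAL", active_only = FALSE)
        acp <- .find_domain(m, "ACP", active_only = FALSE)
        loader <- if (!is.null(cal)) cal
                  else if (identical(core_sorted, "ACP")) acp
        if (!is.null(loader)) {
          a <- loader$attributes
          n_set <- sum(!is.null(a$starter_code), !is.null(a$starter_smiles))
          if (n_set != 1L)
            err(m$index, paste0(loader$kind, " loading requires exactly one ",
                                "of starter_code, starter_smiles"))
          else if (!is.null(a$starter_code) &&
                   !a$starter_code %in% names(table$starters))
            err(m$index, paste0("unresolved starter code '", a$starter_code,
                                "'"))
          else if (!is.null(a$starter_smiles)) {
            if (!endsWith(a$starter_smiles, "C(=O)S"))
              err(m$index, paste0("starter_smiles must be an acyl thioester ",
                                  "ending in C(=O)S"))
            else if (!is.null(check_smiles_syntax(a$starter_smiles)))
              err(m$index, paste0("starter_smiles is not valid SMILES: ",
                                  a$starter_smiles))
          }
        }
        aload <- .find_domain(m, "A", active_only = FALSE)
        if (!is.null(aload) &&
            !aload$attributes$substrate_code %in% names(table$amino_acids))
          err(m$index, paste0("unresolved amino-acid code '",
                              aload$attributes$substrate_code, "'"))
      }
    } else {
      is_pks <- any(core %in% c("KS", "AT", "KR", "DH", "ER", "MT"))
      is_nrps <- any(core %in% c("C", "Cy", "A", "AOX", "E", "F", "nMT"))
      if (is_pks && is_nrps) {
        err(m$index, "module mixes PKS and NRPS extension domains")
      } else if (is_pks) {
        if (!all(c("KS", "AT") %in% core))
          err(m$index, paste0("PKS extension module requires KS and AT ",
                              "(trans-AT modules are not supported)"))
        at <- .find_domain(m, "AT", active_only = FALSE)
        if (!is.null(at)) {
          if (isTRUE(at$attributes$is_loading))
            err(m$index, "extension AT must not set is_loading")
          else if (!at$attributes$substrate_code %in% names(table$extenders))
            err(m$index, paste0("unresolved extender code '",
                                at$attributes$substrate_code, "'"))
        }
      } else if (is_nrps) {
        has_cond <- any(c("C", "Cy") %in% core)
        has_sel <- any(c("A", "AOX") %in% core)
        if (!has_cond || !has_sel)
          err(m$index, paste0("NRPS extension module requires (C or Cy) and ",
                              "(A or AOX)"))
        sel <- .find_domain(m, "A", active_only = FALSE)
        if (is.null(sel)) sel <- .find_domain(m, "AOX", active_only = FALSE)
        if (!is.null(sel)) {
          code <- sel$attributes$substrate_code
          if (!code %in% names(table$amino_acids))
            err(m$index, paste0("unresolved amino-acid code '", code, "'"))
          else {
            cy <- .find_domain(m, "Cy", active_only = FALSE)
            if (!is.null(cy) && !code %in% c("cys", "ser", "thr"))
              err(m$index, paste0("Cy requires a cys/ser/thr substrate, ",
                                  "found '", code, "'"))
            if (is.null(cy) && sel$kind == "A" &&
                !identical(sel$attributes$modification, "none"))
              wrn(m$index, paste0("A-domain ", sel$attributes$modification,
                                  " is only applied after a Cy-formed ",
                                  "azoline; no Cy in this module"))
          }
        }
      } else {
        err(m$index, paste0("extension module is neither PKS (KS+AT) nor ",
                            "NRPS (C/Cy+A)"))
      }
    }
    for (d in m$domains) {
      if (d$kind %in% c("TE", "R")) {
        release_seen <- c(release_seen, d$kind)
        if (m$index != mods[[length(mods)]]$index)
          err(m$index, paste0(d$kind, " release domain must be in the ",
                              "final module"))
        if (d$kind == "TE" && !is.null(d$attributes$ring_site) &&
            d$attributes$ring_site >= n_units)
          err(m$index, paste0("ring_site ", d$attributes$ring_site,
                              " is out of range (chain has ", n_units,
                              " units)"))
      }
    }
  }
  if (length(release_seen) > 1L)
    err(NA_integer_, paste0("at most one terminal release domain (TE or R) ",
                            "allowed, found ",
                            paste(release_seen, collapse = "+")))

  empty <- data.frame(module = integer(0), message = character(0))
  structure(list(
    errors = if (length(errors)) do.call(rbind, errors) else empty,
    warnings = if (length(warnings)) do.call(rbind, warnings) else empty),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$errors), " error(s), ",
      nrow(x$warnings), " warning(s)\n", sep = "")
  if (nrow(x$errors)) {
    cat("errors:\n")
    for (i in seq_len(nrow(x$errors)))
      cat(sprintf("  [module %s] %s\n", x$errors$module[i],
                  x$errors$message[i]))
  }
  if (nrow(x$warnings)) {
    cat("warnings:\n")
    for (i in seq_len(nrow(x$warnings)))
      cat(sprintf("  [module %s] %s\n", x$warnings$module[i],
                  x$warnings$message[i]))
  }
  invisible(x)
}

#' Is a validation report clean?
#' @param report A `validation_report`.
#' @return `TRUE` if the report carries no errors.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  nrow(report$errors) == 0L
}

# ---- reductive-domain repair ----------------------------------------------

#' Inactivate reductive domains lacking their prerequisite reaction
#'
#' Within each module the prerequisite chain is KR -> DH -> ER: a DH can only
#' dehydrate the beta-hydroxyl produced by a reducing KR, and an ER can only
#' saturate the alkene produced by a DH. If the prerequisite domain is
#' absent, inactive, or (for KR) of a non-reducing type (C1 passthrough, C2
#' alpha-epimerase), every downstream reductive domain in the module is
#' marked inactive. Domains are never removed or re-activated and domain
#' order is untouched, so the operation is idempotent.
#'
#' @param cluster An `ms_cluster`.
#' @return A list with `cluster` (the repaired cluster) and `changes` (a
#'   data frame of `module`, `domain`, `reason` records, one per domain
#'   flipped).
#' @export
repair_reductive_domains <- function(cluster) {
  stopifnot(inherits(cluster, "ms_cluster"))
  changes <- list()
  cluster <- .map_modules(cluster, function(m) {
    kr <- .find_domain(m, "KR")
    kr_ok <- !is.null(kr) && kr$attributes$kr_type %in% KR_REDUCING_TYPES
    dh_ok <- kr_ok && !is.null(.find_domain(m, "DH"))
    for (i in seq_along(m$domains)) {
      d <- m$domains[[i]]
      if (!d$active) next
      if (d$kind == "DH" && !kr_ok) {
        m$domains[[i]]$active <- FALSE
        changes[[length(changes) + 1L]] <<- data.frame(
          module = m$index, domain = "DH",
          reason = "no active reducing KR provides the beta-hydroxyl")
      } else if (d$kind == "ER" && !dh_ok) {
        m$domains[[i]]$active <- FALSE
        changes[[length(changes) + 1L]] <<- data.frame(
          module = m$index, domain = "ER",
          reason = if (kr_ok) "no active DH provides the alkene"
                   else "no active reducing KR upstream of DH")
      }
    }
    m
  })
  list(cluster = cluster,
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(module = integer(0), domain = character(0),
                                 reason = character(0)))
}

# ---- architecture serialization -------------------------------------------

.domain_token <- function(d) {
  a <- d$attributes
  switch(d$kind,
    AT = paste0("AT:", a$substrate_code, if (isTRUE(a$is_loading)) ":load"),
    KR = paste0("KR:", a$kr_type),
    C = paste0("C:", a$c_type),
    A = paste0("A:", a$substrate_code,
               switch(a$modification, oxidation = ":ox", reduction = ":red",
                      none = "")),
    AOX = paste0("AOX:", a$substrate_code),
    TE = paste0("TE:", a$release_mode),
    R = paste0("R:", a$product_level),
    CAL = paste0("CAL:", if (!is.null(a$starter_code)) a$starter_code
                         else a$starter_smiles),
    ACP = if (!is.null(a$starter_code) || !is.null(a$starter_smiles))
            paste0("ACP:load:", if (!is.null(a$starter_code)) a$starter_code
                                else a$starter_smiles)
          else "ACP",
    d$kind)
}

#' Serialize a cluster to domain-configuration tokens
#'
#' One token per active domain in N-to-C order; the token is the domain kind
#' plus its chemistry-relevant attributes (AT substrate, KR type, C type, A
#' substrate and modification, TE release mode, R product level, loading
#' starter). Inactive domains are excluded, so serializing a repaired
#' cluster reflects the chemistry that actually runs.
#'
#' @param cluster An `ms_cluster`.
#' @return Character vector of tokens.
#' @export
architecture_of <- function(cluster) {
  stopifnot(inherits(cluster, "ms_cluster"))
  unlist(lapply(cluster_modules(cluster), function(m)
    vapply(Filter(function(d) d$active, m$domains), .domain_token,
           character(1))), use.names = FALSE) %||% character(0)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
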