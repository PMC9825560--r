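# Whole-cluster simulation: validation, repair, module walk with the fixed
# intra-module dispatch order, and the independent formula-ledger audit.

.module_context <- function(idx, expr) {
  tryCatch(expr, error = function(e)
    stop("module ", idx, ": ", conditionMessage(e), call. = FALSE))
}

#' Simulate every intermediate and the released product of a cluster
#'
#' Validates the cluster (rejecting it on any composition error), applies
#' [repair_reductive_domains()] and records its changes, then walks the
#' modules in order. Within a module the dispatch order is fixed regardless
#' of annotation order: loading / KS-AT extension / C-Cy condensation, then
#' MT, KR, DH, ER, azoline redox, E, nMT, F, and finally release. One
#' intermediate (rendered as the free acid) is emitted per loading or
#' chain-elongating module; the product is present iff a release domain
#' exists and fired. X domains contribute provenance only; AOX loads its
#' substrate like an A domain.
#'
#' @param cluster An `ms_cluster`.
#' @param table A `substrate_table`.
#' @return A `simulation_result` with `intermediates` (data frame of
#'   `module_index`, `smiles`), `product` (canonical SMILES or `NA`),
#'   `ring_size`, `log`, `warnings` and `repair_changes`.
#' @export
simulate_cluster <- function(cluster, table = default_substrates()) {
  stopifnot(inherits(cluster, "ms_cluster"))
  report <- validate_cluster(cluster, table)
  if (!is_valid(report)) {
    e <- report$errors
    stop("cluster ", cluster$id, " failed validation (", nrow(e),
         " error(s)); first: [module ", e$module[1], "] ", e$message[1],
         call. = FALSE)
  }
  rep <- repair_reductive_domains(cluster)
  log <- character(0)
  if (nrow(rep$changes))
    log <- c(log, sprintf("repair: module %d: inactivated %s (%s)",
                          rep$changes$module, rep$changes$domain,
                          rep$changes$reason))
  mods <- cluster_modules(rep$cluster)
  last_idx <- mods[[length(mods)]]$index
  chain <- NULL
  inter <- list()
  product <- NA_character_
  ring_size <- NA_integer_
  warnings <- character(0)

  for (m in mods) {
    idx <- m$index
    active <- function(kind) .find_domain(m, kind)
    elongated <- FALSE
    if (m$is_loading) {
      chain <- .module_context(idx, load_starter(m, table))
      elongated <- TRUE
    } else {
      kinds <- .module_kinds(m, active_only = TRUE)
      if (all(c("KS", "AT") %in% kinds)) {
        chain <- .module_context(idx, extend_pks(
          chain, active("AT"), mt_active = !is.null(active("MT")),
          table = table))
        elongated <- TRUE
        if (!is.null(active("KR")))
          chain <- .module_context(idx, apply_kr(chain, active("KR")))
        if (!is.null(active("DH")))
          chain <- .module_context(idx, apply_dh(chain))
        if (!is.null(active("ER")))
          chain <- .module_context(idx, apply_er(chain))
      } else if (any(c("C", "Cy") %in% kinds)) {
        a <- active("A")
        if (is.null(a)) {
          aox <- active("AOX")
          a <- new_domain("A", substrate_code = aox$attributes$substrate_code)
          chain <- .chain_note(chain,
            "AOX: monooxygenation not modeled; substrate loaded as A domain")
        }
        cy <- active("Cy")
        if (!is.null(cy)) {
          chain <- .module_context(idx, heterocyclize(chain, a, table))
          elongated <- TRUE
          amod <- a$attributes$modification %||% "none"
          if (!identical(amod, "none"))
            chain <- .module_context(idx, apply_azoline_redox(chain, amod))
        } else {
          cdom <- active("C")
          if (!is.null(cdom)) {
            chain <- .module_context(idx, condense_nrps(chain, cdom, a,
                                                        table))
            elongated <- TRUE
          } else {
            chain <- .chain_note(chain, sprintf(
              "module %d skipped: no active condensation domain", idx))
          }
        }
        if (elongated) {
          if (!is.null(active("E")))
            chain <- .module_context(idx, epimerize(chain))
          if (!is.null(active("nMT")))
            chain <- .module_context(idx, n_methylate(chain))
          if (!is.null(active("F")))
            chain <- .module_context(idx, formylate(chain))
        }
      } else {
        chain <- .chain_note(chain, sprintf(
          "module %d skipped: no active extension domains", idx))
      }
    }
    if (!is.null(active("X")))
      chain <- .chain_note(chain, "X: oxygenase recruitment, no chemistry")
    if (elongated)
      inter[[length(inter) + 1L]] <- data.frame(
        module_index = idx,
        smiles = .module_context(idx, chain_smiles(chain, "acid")))
    if (idx == last_idx) {
      te <- active("TE"); rdom <- active("R")
      if (!is.null(te)) {
        rel <- .module_context(idx, release_te(chain, te))
        product <- rel$smiles; ring_size <- rel$ring_size
        chain <- rel$chain
      } else if (!is.null(rdom)) {
        rel <- .module_context(idx, release_r(chain, rdom))
        product <- rel$smiles
        chain <- rel$chain
      }
    }
  }

  structure(list(
    cluster_id = cluster$id,
    intermediates = if (length(inter)) do.call(rbind, inter)
                    else data.frame(module_index = integer(0),
                                    smiles = character(0)),
    product = product,
    ring_size = ring_size,
    log = c(log, chain$provenance),
    warnings = c(warnings, chain$warnings),
    repair_changes = rep$changes),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", x$cluster_id, "\n", sep = "")
  for (i in seq_len(nrow(x$intermediates)))
    cat(sprintf("  module %d: %s\n", x$intermediates$module_index[i],
                x$intermediates$smiles[i]))
  cat("  product: ", if (is.na(x$product)) "<none: no release domain>"
      else x$product, "\n", sep = "")
  if (!is.na(x$ring_size))
    cat("  macrocycle ring size: ", x$ring_size, "\n", sep = "")
  invisible(x)
}

#' Write simulation results to disk
#'
#' `write_simulation_tsv()` writes a TSV of `module_index`,
#' `canonical_smiles` plus a final `product` row; `write_simulation_smi()`
#' writes a named SMILES file (one record per line).
#'
#' @param result A `simulation_result`.
#' @param path Output file.
#' @param header Optional provenance header lines (written as `#` comments).
#' @return `path`, invisibly.
#' @export
write_simulation_tsv <- function(result, path, header = character(0)) {
  stopifnot(inherits(result, "simulation_result"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines("record\tmodule_index\tcanonical_smiles", con)
  for (i in seq_len(nrow(result$intermediates)))
    writeLines(paste("intermediate", result$intermediates$module_index[i],
                     result$intermediates$smiles[i], sep = "\t"), con)
  if (!is.na(result$product))
    writeLines(paste("product", "", result$product, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_simulation_tsv
#' @export
write_simulation_smi <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  lines <- sprintf("%s %s_module%d", result$intermediates$smiles,
                   result$cluster_id, result$intermediates$module_index)
  if (!is.na(result$product))
    lines <- c(lines, sprintf("%s %s_product", result$product,
                              result$cluster_id))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- independent formula audit --------------------------------------------

#' Expected product formula from per-transform bookkeeping
#'
#' Walks the repaired cluster's active domains and sums the documented
#' per-transform molecular-formula deltas (extension `mal` +C2H2O with the
#' extender branch on top; reducing KR +H2; DH -H2O; ER +H2; MT/nMT +CH2;
#' condensation + residue - H2O; Cy an additional -H2O; azoline oxidation
#' -H2, reduction +H2; F +CO (the installed formyl consumes one N-H);
#' cyclizing release -H2O; R-domain release
#' -O for the aldehyde, -O +H2 for the alcohol) on top of the starter's
#' free-acid formula. The walk never touches the structure renderer, so it
#' serves as an independent audit of [simulate_cluster()].
#'
#' @param cluster An `ms_cluster` (repair is applied internally).
#' @param table A `substrate_table`.
#' @return A molecular formula string for the expected released product (or
#'   final free-acid intermediate when no release domain exists).
#' @export
ledger_formula <- function(cluster, table = default_substrates()) {
  stopifnot(inherits(cluster, "ms_cluster"))
  cluster <- repair_reductive_domains(cluster)$cluster
  H2 <- parse_formula("H2"); H2O <- parse_formula("H2O")
  CH2 <- parse_formula("CH2"); CO <- parse_formula("CO")
  O1 <- parse_formula("O")
  neg <- function(f) formula_scale(f, -1L)

  residue_acid_formula <- function(code) {
    rec <- resolve_amino_acid(code, table)
    molecular_formula(paste0(substr(rec$smiles, 1L, nchar(rec$smiles) - 1L),
                             "O"), strict = FALSE)
  }
  total <- NULL
  mods <- cluster_modules(cluster)
  for (m in mods) {
    kinds <- .module_kinds(m, active_only = TRUE)
    if (m$is_loading) {
      core <- setdiff(kinds, c("TE", "R", "X"))
      if (all(c("A", "PCP") %in% core)) {
        a <- .find_domain(m, "A")
        total <- parse_formula(residue_acid_formula(
          a$attributes$substrate_code))
      } else {
        attrs <- if ("AT" %in% core)
          list(starter_code = .find_domain(m, "AT")$attributes$substrate_code)
        else if ("CAL" %in% core) .find_domain(m, "CAL")$attributes
        else .find_domain(m, "ACP")$attributes
        body <- if (!is.null(attrs$starter_code))
          resolve_starter(attrs$starter_code, table)$body
        else substr(attrs$starter_smiles, 1L,
                    nchar(attrs$starter_smiles) - 6L)
        total <- parse_formula(molecular_formula(paste0(body, "C(=O)O"),
                                                 strict = FALSE))
      }
    } else if (all(c("KS", "AT") %in% kinds)) {
      ext <- resolve_extender(.find_domain(m, "AT")$attributes$substrate_code,
                              table)
      delta <- parse_formula("C2H2O")
      if (nzchar(ext$branch))
        delta <- formula_add(delta,
          parse_formula(molecular_formula(ext$branch, strict = FALSE)),
          neg(H2))
      total <- formula_add(total, delta)
      if ("MT" %in% kinds) total <- formula_add(total, CH2)
      kr <- .find_domain(m, "KR")
      if (!is.null(kr) && kr$attributes$kr_type %in% KR_REDUCING_TYPES)
        total <- formula_add(total, H2)
      if ("DH" %in% kinds) total <- formula_add(total, neg(H2O))
      if ("ER" %in% kinds) total <- formula_add(total, H2)
    } else if (any(c("C", "Cy") %in% kinds)) {
      sel <- .find_domain(m, "A") %||% .find_domain(m, "AOX")
      if (is.null(sel)) next
      code <- sel$attributes$substrate_code
      has_cy <- "Cy" %in% kinds
      if (has_cy || "C" %in% kinds) {
        total <- formula_add(total,
                             parse_formula(residue_acid_formula(code)),
                             neg(H2O))
        if (has_cy) {
          total <- formula_add(total, neg(H2O))
          amod <- sel$attributes$modification %||% "none"
          if (amod == "oxidation") total <- formula_add(total, neg(H2))
          if (amod == "reduction") total <- formula_add(total, H2)
        }
        if ("nMT" %in% kinds) total <- formula_add(total, CH2)
        # N-formylation installs CHO while consuming one N-H: net +CO
        if ("F" %in% kinds) total <- formula_add(total, CO)
      }
    }
  }
  last <- mods[[length(mods)]]
  te <- .find_domain(last, "TE"); rdom <- .find_domain(last, "R")
  if (!is.null(te) && te$attributes$release_mode != "hydrolysis")
    total <- formula_add(total, neg(H2O))
  if (!is.null(rdom)) {
    total <- formula_add(total, neg(O1))
    if (rdom$attributes$product_level == "alcohol")
      total <- formula_add(total, H2)
  }
  formula_string(total)
}
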