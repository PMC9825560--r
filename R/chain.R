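# Carrier-bound chain state and its SMILES renderer.
#
# The chain is kept as a structured list of units rather than a raw
# molecular graph: an acyl starter, ketide units (alpha substituents plus
# the oxidation state of the beta-carbon, i.e. the previous unit's former
# thioester carbonyl), and amino-acid residues (template pieces plus
# N-decorations and an optional azoline ring state). SMILES is generated on
# demand; equality and validity checks go through the chemistry backend.

new_chain_state <- function(units) {
  structure(list(units = units, released = FALSE,
                 provenance = character(0), warnings = character(0)),
            class = "chain_state")
}

.chain_note <- function(chain, what) {
  chain$provenance <- c(chain$provenance, what)
  chain
}

.chain_warn <- function(chain, what) {
  chain$warnings <- c(chain$warnings, what)
  chain
}

.last_unit <- function(chain) chain$units[[length(chain$units)]]

.set_last_unit <- function(chain, unit) {
  chain$units[[length(chain$units)]] <- unit
  chain
}

.unit_acyl <- function(body) list(type = "acyl", body = body)

.unit_ketide <- function(subs = character(0)) {
  list(type = "ketide", subs = subs, alpha_stereo = NULL,
       beta_state = "keto", beta_stereo = NULL)
}

.unit_residue <- function(rec) {
  list(type = "residue", code = rec$code, n_pre = rec$n_pre, pre = rec$pre,
       stereo = rec$stereo, alpha_ring = rec$alpha_ring, side = rec$side,
       cyclic = rec$cyclic, n_methyl = FALSE, n_formyl = FALSE,
       epimerized = FALSE, azoline = NULL)
}

# free N-H count on a residue's backbone nitrogen
.residue_n_capacity <- function(u, is_first) {
  if (!is.null(u$azoline))
    return(if (u$azoline$level == "azolidine") 1L else 0L)
  base <- if (is_first) { if (u$cyclic) 1L else 2L } else 1L
  base - (u$n_methyl + u$n_formyl)
}

# Backbone atoms a unit contributes to a macrocycle threaded through the
# main chain (residue: N, C-alpha, C1; azoline residue: N3, C4, C1;
# ketide: C-alpha, C1).
.unit_backbone_len <- function(u) {
  switch(u$type, acyl = 1L, ketide = 2L, residue = 3L)
}

.count_atoms <- function(smiles_fragment) {
  s <- gsub("\\[[^]]*\\]", "X", smiles_fragment)  # bracket atom = one atom
  sum(strsplit(s, "")[[1]] %in%
        c("X", "C", "c", "N", "n", "O", "o", "S", "s", "P", "p", "F",
          "B", "I"))
}

# Mark the first hydroxyl oxygen of an acyl body with the macrocycle
# ring-closure label; returns the marked body and the number of atoms on the
# path from that oxygen's carbon to the body's attachment end (used for
# ring-size accounting).
.mark_body_hydroxyl <- function(body) {
  if (grepl("(O)", body, fixed = TRUE)) {
    marked <- sub("(O)", "(O%99)", body, fixed = TRUE)
    tail <- sub("^.*?\\(O\\)", "", body)
    list(body = marked, tail_atoms = .count_atoms(tail))
  } else if (grepl("O$", body)) {
    list(body = sub("O$", "O%99", body), tail_atoms = 0L)
  } else {
    NULL
  }
}

.azoline_tail <- function(az, aromatic) {
  c5 <- if (aromatic) tolower("c") else "C"
  paste0(c5, if (nzchar(az$c5)) paste0("(", az$c5, ")"),
         if (aromatic) tolower(az$het) else az$het, "1")
}

# mark: NULL or list(unit = <index into units>, where = one of
# "beta_O", "body_O", "alpha_N", "side_O", "side_N") for macrocyclization.
.render_chain <- function(units, terminal = "thioester", mark = NULL) {
  n <- length(units)
  out <- character(0)
  marked_here <- function(i, where)
    !is.null(mark) && mark$unit == i && mark$where == where
  for (i in seq_len(n)) {
    u <- units[[i]]
    nxt <- if (i < n) units[[i + 1L]] else NULL

    # --- head of the unit ---------------------------------------------
    if (u$type == "acyl") {
      body <- u$body
      if (marked_here(i, "body_O")) body <- .mark_body_hydroxyl(body)$body
      out <- c(out, body)
    } else if (u$type == "ketide") {
      if (u$beta_state == "ene") {
        # alpha carbon is the second alkene carbon; "/C=C" was emitted by
        # the previous unit's carbonyl. Geometry markers give the E-alkene;
        # when the next unit is also an ene (conjugated diene) its own
        # "/C=C" supplies the marker for the shared single bond.
        nxt_ene <- !is.null(nxt) && nxt$type == "ketide" &&
          nxt$beta_state == "ene"
        if (length(u$subs) == 0L) {
          if (!nxt_ene) out <- c(out, "/")
        } else out <- c(out, paste0("(\\", u$subs[[1]], ")"))
      } else {
        atom <- if (!is.null(u$alpha_stereo) && length(u$subs) == 1L)
          paste0("[C", u$alpha_stereo, "H]") else "C"
        out <- c(out, atom,
                 vapply(u$subs, function(s) paste0("(", s, ")"),
                        character(1)))
      }
    } else {  # residue
      if (!is.null(u$azoline)) {
        az <- u$azoline
        ring <- switch(az$level,
          azoline = {
            alpha <- if (!is.null(u$stereo))
              paste0("[C", u$stereo, "H]") else "C"
            paste0("C1=N", alpha, "(", .azoline_tail(az, FALSE), ")")
          },
          azole = paste0("c1nc(", .azoline_tail(az, TRUE), ")"),
          azolidine = {
            alpha <- if (!is.null(u$stereo))
              paste0("[C", u$stereo, "H]") else "C"
            nat <- if (u$n_methyl) "N(C)" else "N"
            paste0("C1", nat, alpha, "(", .azoline_tail(az, FALSE), ")")
          })
        out <- c(out, ring)
      } else {
        natom <- u$n_pre
        if (marked_here(i, "alpha_N")) natom <- paste0(natom, "%99")
        decos <- c(if (u$n_formyl) "(C=O)", if (u$n_methyl) "(C)")
        alpha <- if (!is.null(u$stereo)) paste0("[C", u$stereo, "H]") else "C"
        alpha <- paste0(alpha, u$alpha_ring)
        side <- u$side
        if (!is.null(side)) {
          if (marked_here(i, "side_O")) side <- sub("O", "O%99", side)
          if (marked_here(i, "side_N")) side <- sub("N", "N%99", side)
        }
        out <- c(out, natom, decos, u$pre, alpha,
                 if (!is.null(side)) paste0("(", side, ")"))
      }
    }

    # --- carbonyl carbon of the unit, styled by the following unit -----
    if (!is.null(nxt)) {
      if (nxt$type == "residue") {
        # azoline consumes this carbonyl as its ring C2
        if (!is.null(nxt$azoline)) out <- c(out, "")
        else out <- c(out, "C(=O)")
      } else if (nxt$type == "ketide") {
        out <- c(out, switch(nxt$beta_state,
          keto = "C(=O)",
          hydroxyl = {
            oat <- if (marked_here(i + 1L, "beta_O")) "O%99" else "O"
            atom <- if (!is.null(nxt$beta_stereo))
              paste0("[C", nxt$beta_stereo, "H]") else "C"
            paste0(atom, "(", oat, ")")
          },
          ene = "/C=C",
          methylene = "C"))
      } else {
        stop("internal: acyl unit cannot follow another unit")
      }
    } else {
      out <- c(out, switch(terminal,
        thioester = "C(=O)S",
        acid = "C(=O)O",
        aldehyde = "C=O",
        alcohol = "CO",
        lactone = "C%99(=O)",
        lactam = "C%99(=O)"))
    }
  }
  paste(out, collapse = "")
}

#' Render a chain state as SMILES
#'
#' Carrier-bound intermediates carry a single thioester attachment point;
#' the `"acid"` form renders the same chain as the free carboxylic acid,
#' which is the display form used for intermediates and structure search.
#'
#' @param chain A `chain_state`.
#' @param form `"thioester"` (internal carrier-bound form) or `"acid"`.
#' @param canonical Canonicalize through the chemistry backend.
#' @return A SMILES string.
#' @export
chain_smiles <- function(chain, form = c("acid", "thioester"),
                         canonical = TRUE) {
  stopifnot(inherits(chain, "chain_state"))
  if (chain$released)
    stop("chain has been released from the carrier", call. = FALSE)
  form <- match.arg(form)
  smi <- .render_chain(chain$units,
                       terminal = if (form == "acid") "acid" else "thioester")
  if (canonical) canonical_smiles(smi, strict = FALSE) else smi
}

#' @export
print.chain_state <- function(x, ...) {
  cat("<chain_state> ", length(x$units), " unit(s)",
      if (x$released) " [released]", "\n", sep = "")
  if (!x$released)
    cat("  thioester: ", .render_chain(x$units, "thioester"), "\n", sep = "")
  if (length(x$provenance))
    cat("  provenance: ", paste(x$provenance, collapse = " -> "), "\n",
        sep = "")
  invisible(x)
}
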