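# Biosynthesis engine: one function per domain chemistry, plus the module
# walker that simulates a whole cluster.

.attrs_of <- function(x) {
  if (inherits(x, "ms_domain")) x$attributes else x
}

.check_not_released <- function(chain, op) {
  if (!inherits(chain, "chain_state"))
    stop(op, ": expected a chain_state", call. = FALSE)
  if (chain$released)
    stop(op, ": chain has already been released from the carrier",
         call. = FALSE)
}

#' Load the starter unit of a chain
#'
#' Supports the five loading configurations: AT+ACP (starter code), CAL+ACP
#' and CAL+PCP (starter code or arbitrary acyl thioester SMILES), A+PCP
#' (aminoacyl starter with a free alpha-amine), and a standalone N-terminal
#' ACP that attaches its `starter_smiles` verbatim.
#'
#' @param module A loading `ms_module`.
#' @param table A `substrate_table`.
#' @return A `chain_state` with one unit bound to the thioester placeholder.
#' @export
load_starter <- function(module, table = default_substrates()) {
  stopifnot(inherits(module, "ms_module"))
  if (!module$is_loading)
    stop("load_starter: module is not a loading module", call. = FALSE)
  kinds <- .module_kinds(module, active_only = TRUE)
  core <- setdiff(kinds, c("TE", "R", "X"))

  acyl_from <- function(attrs, what) {
    if (!is.null(attrs$starter_code)) {
      rec <- resolve_starter(attrs$starter_code, table)
      list(body = rec$body, label = rec$code)
    } else if (!is.null(attrs$starter_smiles)) {
      smi <- attrs$starter_smiles
      if (!endsWith(smi, "C(=O)S"))
        stop(what, ": starter_smiles must be an acyl thioester ending in ",
             "C(=O)S", call. = FALSE)
      msg <- check_smiles_syntax(smi)
      if (!is.null(msg)) stop(what, ": invalid starter_smiles: ", msg,
                              call. = FALSE)
      canonical_smiles(smi)  # must parse
      list(body = substr(smi, 1L, nchar(smi) - 6L), label = smi)
    } else {
      stop(what, ": missing starter specification", call. = FALSE)
    }
  }

  if (all(c("AT", "ACP") %in% core)) {
    at <- .attrs_of(.find_domain(module, "AT"))
    rec <- resolve_starter(at$substrate_code, table)
    chain <- new_chain_state(list(.unit_acyl(rec$body)))
    return(.chain_note(chain, paste0("load_starter[AT:", rec$code, "]")))
  }
  if ("CAL" %in% core) {
    st <- acyl_from(.attrs_of(.find_domain(module, "CAL")), "CAL loading")
    chain <- new_chain_state(list(.unit_acyl(st$body)))
    return(.chain_note(chain, paste0("load_starter[CAL:", st$label, "]")))
  }
  if (all(c("A", "PCP") %in% core)) {
    a <- .attrs_of(.find_domain(module, "A"))
    rec <- resolve_amino_acid(a$substrate_code, table)
    chain <- new_chain_state(list(.unit_residue(rec)))
    return(.chain_note(chain, paste0("load_starter[A:", rec$code, "]")))
  }
  if (identical(core, "ACP")) {
    st <- acyl_from(.attrs_of(.find_domain(module, "ACP")),
                    "standalone ACP loading")
    chain <- new_chain_state(list(.unit_acyl(st$body)))
    return(.chain_note(chain, paste0("load_starter[ACP:", st$label, "]")))
  }
  stop("load_starter: unsupported loading configuration: ",
       paste(core, collapse = "+"), call. = FALSE)
}

#' Claisen extension of the chain by one ketide unit
#'
#' The AT-selected extender contributes the new alpha-carbon substituent
#' (`mal` = hydrogen, `mmal` = methyl, `emal` = ethyl, `mxmal` = methoxy);
#' the previous thioester carbonyl becomes the new unit's beta-ketone. An
#' active MT places one additional methyl on the alpha-carbon.
#'
#' @param chain A carrier-bound `chain_state`.
#' @param at AT attributes (or an AT `ms_domain`).
#' @param mt_active Apply alpha-methylation after extension.
#' @param table A `substrate_table`.
#' @return The extended `chain_state`.
#' @export
extend_pks <- function(chain, at, mt_active = FALSE,
                       table = default_substrates()) {
  .check_not_released(chain, "extend_pks")
  at <- .attrs_of(at)
  ext <- resolve_extender(at$substrate_code, table)
  subs <- if (nzchar(ext$branch)) ext$branch else character(0)
  chain$units[[length(chain$units) + 1L]] <- .unit_ketide(subs)
  chain <- .chain_note(chain, paste0("extend_pks[", ext$code, "]"))
  if (mt_active) {
    u <- .last_unit(chain)
    if (length(u$subs) >= 2L)
      stop("extend_pks: MT requires a free alpha position; alpha-carbon is ",
           "fully substituted", call. = FALSE)
    u$subs <- c(u$subs, "C")
    chain <- .set_last_unit(chain, u)
    chain <- .chain_note(chain, "alpha_methylate[MT]")
  }
  chain
}

#' Ketoreduction of the newest beta-ketone
#'
#' Reducing types (A1, A2, B1, B2, U) convert the beta-ketone to a
#' beta-hydroxyl with stereodescriptors taken from the shipped convention
#' table; C1 is a structure passthrough; C2 epimerizes the
#' alpha-substituent only.
#'
#' @param chain A carrier-bound `chain_state` whose newest unit carries a
#'   beta-ketone (not required for C1/C2).
#' @param kr KR attributes (or a KR `ms_domain`).
#' @return The reduced `chain_state`.
#' @export
apply_kr <- function(chain, kr) {
  .check_not_released(chain, "apply_kr")
  kr <- .attrs_of(kr)
  type <- kr$kr_type
  map <- kr_stereo_map()
  if (!type %in% rownames(map) || type == "ER")
    stop("apply_kr: unknown KR type: ", type, call. = FALSE)
  if (type == "C1")
    return(.chain_note(chain, "apply_kr[C1:passthrough]"))
  u <- .last_unit(chain)
  if (type == "C2") {
    if (u$type == "ketide" && length(u$subs) == 1L) {
      u$alpha_stereo <- map["C2", "alpha_stereo"]
      chain <- .set_last_unit(chain, u)
    } else {
      chain <- .chain_warn(chain,
        "apply_kr[C2]: no single alpha-substituent to epimerize")
    }
    return(.chain_note(chain, "apply_kr[C2:alpha-epimerase]"))
  }
  if (u$type != "ketide" || u$beta_state != "keto")
    stop("apply_kr: no beta-ketone on the newest chain unit", call. = FALSE)
  u$beta_state <- "hydroxyl"
  bs <- map[type, "beta_stereo"]
  u$beta_stereo <- if (is.na(bs)) NULL else bs
  as <- map[type, "alpha_stereo"]
  u$alpha_stereo <- if (!is.na(as) && length(u$subs) == 1L) as else NULL
  chain <- .set_last_unit(chain, u)
  .chain_note(chain, paste0("apply_kr[", type, "]"))
}

#' Dehydration of the newest beta-hydroxyl to the E-configured alkene
#'
#' @param chain A carrier-bound `chain_state` whose newest unit carries a
#'   beta-hydroxyl.
#' @return The dehydrated `chain_state`.
#' @export
apply_dh <- function(chain) {
  .check_not_released(chain, "apply_dh")
  u <- .last_unit(chain)
  if (u$type != "ketide" || u$beta_state != "hydroxyl")
    stop("apply_dh: no beta-hydroxyl on the newest chain unit",
         call. = FALSE)
  if (length(u$subs) >= 2L)
    stop("apply_dh: alpha-carbon is fully substituted; no alpha-H to ",
         "eliminate", call. = FALSE)
  u$beta_state <- "ene"
  u$beta_stereo <- NULL
  u$alpha_stereo <- NULL
  chain <- .set_last_unit(chain, u)
  .chain_note(chain, "apply_dh[E]")
}

#' Enoylreduction of the newest alpha,beta-alkene
#'
#' @param chain A carrier-bound `chain_state` whose newest unit carries an
#'   alpha,beta-alkene.
#' @return The saturated `chain_state`.
#' @export
apply_er <- function(chain) {
  .check_not_released(chain, "apply_er")
  u <- .last_unit(chain)
  if (u$type != "ketide" || u$beta_state != "ene")
    stop("apply_er: no alpha,beta-alkene on the newest chain unit",
         call. = FALSE)
  u$beta_state <- "methylene"
  as <- kr_stereo_map()["ER", "alpha_stereo"]
  u$alpha_stereo <- if (!is.na(as) && length(u$subs) == 1L) as else NULL
  chain <- .set_last_unit(chain, u)
  .chain_note(chain, "apply_er")
}

#' Amide condensation of an A-selected amino acid onto the chain
#'
#' The incoming residue's alpha-amine attacks the chain's thioester
#' carbonyl. `Dual`-type C domains epimerize the new residue after
#' condensation; LCL/DCL/Glycopeptide types are recorded in provenance, and
#' a donor-configuration mismatch (an epimerized donor before an LCL, or an
#' L donor before a DCL) is reported as a warning, never an error.
#'
#' @param chain A carrier-bound `chain_state`.
#' @param c_attrs C attributes (or a C `ms_domain`).
#' @param a_attrs A attributes (or an A `ms_domain`).
#' @param table A `substrate_table`.
#' @return The elongated `chain_state`.
#' @export
condense_nrps <- function(chain, c_attrs, a_attrs,
                          table = default_substrates()) {
  .check_not_released(chain, "condense_nrps")
  c_attrs <- .attrs_of(c_attrs); a_attrs <- .attrs_of(a_attrs)
  rec <- resolve_amino_acid(a_attrs$substrate_code, table)
  ctype <- c_attrs$c_type
  donor <- .last_unit(chain)
  if (donor$type == "residue" && !is.null(donor$stereo)) {
    if (ctype == "LCL" && donor$epimerized)
      chain <- .chain_warn(chain,
        "condense_nrps[LCL]: donor residue is D-configured")
    if (ctype == "DCL" && !donor$epimerized)
      chain <- .chain_warn(chain,
        "condense_nrps[DCL]: donor residue is L-configured")
  }
  chain$units[[length(chain$units) + 1L]] <- .unit_residue(rec)
  chain <- .chain_note(chain, paste0("condense_nrps[", ctype, ":",
                                     rec$code, "]"))
  if (ctype == "Dual") chain <- epimerize(chain)
  chain
}

#' Heterocyclization of an incoming cys/ser/thr residue
#'
#' Condensation followed by cyclodehydration: the new residue's side-chain
#' thiol (cys, giving a thiazoline) or hydroxyl (ser/thr, giving an
#' oxazoline) closes a five-membered azoline ring onto the previous
#' carbonyl carbon. Net formula change versus a plain condensation is the
#' loss of one water.
#'
#' @inheritParams condense_nrps
#' @param a_attrs A attributes naming a cys, ser or thr substrate.
#' @return The elongated `chain_state` carrying the azoline.
#' @export
heterocyclize <- function(chain, a_attrs, table = default_substrates()) {
  .check_not_released(chain, "heterocyclize")
  a_attrs <- .attrs_of(a_attrs)
  rec <- resolve_amino_acid(a_attrs$substrate_code, table)
  ring <- switch(rec$code,
                 cys = list(het = "S", c5 = ""),
                 ser = list(het = "O", c5 = ""),
                 thr = list(het = "O", c5 = "C"),
                 stop("heterocyclize: residue '", rec$code, "' has no ",
                      "suitable side-chain nucleophile (need cys, ser or ",
                      "thr)", call. = FALSE))
  u <- .unit_residue(rec)
  u$side <- NULL  # consumed into the ring
  u$azoline <- list(het = ring$het, c5 = ring$c5, level = "azoline")
  chain$units[[length(chain$units) + 1L]] <- u
  .chain_note(chain, paste0("heterocyclize[Cy:", rec$code, "->",
                            if (ring$het == "S") "thiazoline" else "oxazoline",
                            "]"))
}

#' Oxidize or reduce the newest azoline ring
#'
#' Oxidation aromatizes the azoline to the azole (net -H2); reduction gives
#' the azolidine (net +H2).
#'
#' @param chain A carrier-bound `chain_state` whose newest unit carries an
#'   azoline.
#' @param modification `"oxidation"` or `"reduction"`.
#' @return The modified `chain_state`.
#' @export
apply_azoline_redox <- function(chain, modification) {
  .check_not_released(chain, "apply_azoline_redox")
  if (!modification %in% c("oxidation", "reduction"))
    stop("apply_azoline_redox: modification must be 'oxidation' or ",
         "'reduction'", call. = FALSE)
  u <- .last_unit(chain)
  if (u$type != "residue" || is.null(u$azoline) ||
      u$azoline$level != "azoline")
    stop("apply_azoline_redox: no azoline on the newest chain unit",
         call. = FALSE)
  if (modification == "oxidation") {
    u$azoline$level <- "azole"
    u$stereo <- NULL  # C4 becomes aromatic
  } else {
    u$azoline$level <- "azolidine"
  }
  chain <- .set_last_unit(chain, u)
  .chain_note(chain, paste0("apply_azoline_redox[", modification, "]"))
}

#' Epimerize the newest residue's alpha-carbon
#'
#' Inverts the alpha stereodescriptor (L to D and back); an achiral
#' alpha-carbon leaves the structure unchanged with a warning recorded.
#'
#' @param chain A carrier-bound `chain_state`.
#' @return The `chain_state`.
#' @export
epimerize <- function(chain) {
  .check_not_released(chain, "epimerize")
  u <- .last_unit(chain)
  if (u$type != "residue" || is.null(u$stereo)) {
    return(.chain_warn(.chain_note(chain, "epimerize[no-op]"),
      "epimerize: newest residue has no alpha stereocenter"))
  }
  u$stereo <- if (u$stereo == "@@") "@" else "@@"
  u$epimerized <- !u$epimerized
  chain <- .set_last_unit(chain, u)
  .chain_note(chain, "epimerize")
}

#' N-formylate the chain's free N-terminal amine
#'
#' @param chain A carrier-bound `chain_state` starting with a residue whose
#'   alpha-amine is free.
#' @return The formylated `chain_state`.
#' @export
formylate <- function(chain) {
  .check_not_released(chain, "formylate")
  u <- chain$units[[1L]]
  if (u$type != "residue" || u$cyclic ||
      .residue_n_capacity(u, is_first = TRUE) < 2L)
    stop("formylate: chain has no free primary N-terminal amine",
         call. = FALSE)
  u$n_formyl <- TRUE
  chain$units[[1L]] <- u
  .chain_note(chain, "formylate")
}

#' N-methylate the newest residue's backbone nitrogen
#'
#' On an elongated chain this methylates the newest amide nitrogen; on a
#' loading aminoacyl unit with no amide yet, the free alpha-amine is
#' methylated and a warning recorded.
#'
#' @param chain A carrier-bound `chain_state` whose newest residue nitrogen
#'   bears at least one hydrogen.
#' @return The methylated `chain_state`.
#' @export
n_methylate <- function(chain) {
  .check_not_released(chain, "n_methylate")
  u <- .last_unit(chain)
  if (u$type != "residue")
    stop("n_methylate: newest chain unit is not a residue", call. = FALSE)
  is_first <- length(chain$units) == 1L
  if (.residue_n_capacity(u, is_first) < 1L)
    stop("n_methylate: backbone nitrogen bears no hydrogen", call. = FALSE)
  u$n_methyl <- TRUE
  chain <- .set_last_unit(chain, u)
  chain <- .chain_note(chain, "n_methylate")
  if (is_first)
    chain <- .chain_warn(chain,
      "n_methylate: no amide yet; methylated the free alpha-amine")
  chain
}

# ---- release --------------------------------------------------------------

.release_product <- function(smiles, ring_size, chain, how) {
  chain$released <- TRUE
  chain <- .chain_note(chain, how)
  structure(list(smiles = canonical_smiles(smiles, strict = FALSE),
                 ring_size = ring_size, chain = chain),
            class = "release_product")
}

#' @export
print.release_product <- function(x, ...) {
  cat("<release_product> ", x$smiles,
      if (!is.na(x$ring_size)) paste0(" (ring size ", x$ring_size, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Thioesterase release
#'
#' Hydrolysis renders the free carboxylic acid; lactone/lactam modes close a
#' macrocycle from the C1 carbonyl onto the hydroxyl or amine nucleophile of
#' the chain unit named by `ring_site` (a 0-based ordinal counted from the
#' chain start). Supported nucleophiles: a surviving beta-hydroxyl on a
#' ketide unit or a hydroxylated acyl starter (lactone), a ser/thr side
#' chain (lactone), the free N-terminal alpha-amine or a lys side chain
#' (lactam). The closed ring size is reported; rings smaller than four
#' atoms are rejected.
#'
#' @param chain A carrier-bound `chain_state`.
#' @param te TE attributes (or a TE `ms_domain`).
#' @return A `release_product` with `smiles`, `ring_size` and the final
#'   `chain`.
#' @export
release_te <- function(chain, te) {
  .check_not_released(chain, "release_te")
  te <- .attrs_of(te)
  mode <- te$release_mode
  units <- chain$units
  n <- length(units)
  if (mode == "hydrolysis") {
    smi <- .render_chain(units, "acid")
    return(.release_product(smi, NA_integer_, chain,
                            "release_te[hydrolysis]"))
  }
  site <- te$ring_site
  if (is.null(site) || site < 0L || site >= n)
    stop("release_te: ring_site must name a chain unit (0-based, chain has ",
         n, " units)", call. = FALSE)
  i <- site + 1L
  u <- units[[i]]
  downstream <- if (i < n)
    sum(vapply(units[(i + 1L):n], .unit_backbone_len, integer(1))) else 0L

  if (mode == "lactone") {
    if (u$type == "ketide" && u$beta_state == "hydroxyl") {
      mark <- list(unit = i, where = "beta_O")
      # O + beta-carbon + this unit's backbone + downstream backbones
      ring_size <- 2L + .unit_backbone_len(u) + downstream
    } else if (u$type == "acyl") {
      mb <- .mark_body_hydroxyl(u$body)
      if (is.null(mb))
        stop("release_te: starter unit carries no hydroxyl nucleophile",
             call. = FALSE)
      mark <- list(unit = i, where = "body_O")
      # O + its carbon + body tail + this unit's carbonyl + downstream
      ring_size <- 2L + mb$tail_atoms + 1L + downstream
    } else if (u$type == "residue" && is.null(u$azoline) &&
               u$code %in% c("ser", "thr")) {
      mark <- list(unit = i, where = "side_O")
      # O + side-chain carbon + C-alpha + C1 + downstream
      ring_size <- 4L + downstream
    } else {
      stop("release_te: ring_site unit ", site, " carries no hydroxyl ",
           "nucleophile for lactone formation", call. = FALSE)
    }
  } else {  # lactam
    if (u$type == "residue" && i == 1L && is.null(u$azoline) && !u$cyclic &&
        !u$n_formyl) {
      mark <- list(unit = i, where = "alpha_N")
      ring_size <- 3L + downstream
    } else if (u$type == "residue" && is.null(u$azoline) &&
               u$code == "lys") {
      mark <- list(unit = i, where = "side_N")
      # N + 4 side-chain carbons + C-alpha + C1 + downstream
      ring_size <- 7L + downstream
    } else {
      stop("release_te: ring_site unit ", site, " carries no amine ",
           "nucleophile for lactam formation", call. = FALSE)
    }
  }
  if (ring_size < 4L)
    stop("release_te: closing a ", ring_size, "-membered ring is not ",
         "supported (minimum 4)", call. = FALSE)
  smi <- .render_chain(units, mode, mark = mark)
  .release_product(smi, ring_size, chain,
                   paste0("release_te[", mode, ":ring_site=", site,
                          ":ring_size=", ring_size, "]"))
}

#' Reductive release by a terminal reductase domain
#'
#' Reduces the thioester linkage to an aldehyde or, with a second reduction,
#' a primary alcohol.
#'
#' @param chain A carrier-bound `chain_state`.
#' @param r R attributes (or an R `ms_domain`).
#' @return A `release_product`.
#' @export
release_r <- function(chain, r) {
  .check_not_released(chain, "release_r")
  r <- .attrs_of(r)
  lvl <- r$product_level
  smi <- .render_chain(chain$units,
                       if (lvl == "aldehyde") "aldehyde" else "alcohol")
  .release_product(smi, NA_integer_, chain, paste0("release_r[", lvl, "]"))
}
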