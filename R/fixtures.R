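# Deterministic fixture clusters: six hand-built named clusters covering
# the main chemistry routes, and a seeded random generator producing
# arbitrary numbers of schema-valid, simulatable clusters for
# property-style testing. The generator draws only from substrate codes in
# the bundled tables and only composes module layouts whose chemistry is
# defined, so that (after reductive-domain repair) every generated cluster
# simulates without error.

FIXTURE_NAMES <- c("triketide", "dh-no-kr", "lactam-release", "azoline",
                   "nrps-dipeptide", "r-release")

#' Hand-built named fixture clusters
#'
#' * `triketide`: propionyl loading, one methylmalonyl extension with a
#'   B1 ketoreduction, hydrolytic release; product
#'   3-hydroxy-2-methylpentanoic acid.
#' * `dh-no-kr`: a module annotated with an active DH but no KR, the
#'   abyssomicin-style inconsistency fixed by
#'   [repair_reductive_domains()]; product acetoacetic acid.
#' * `lactam-release`: glycine loading, two malonyl extensions, macrolactam
#'   closure onto the N-terminal amine.
#' * `azoline`: acetyl loading, cysteine heterocyclization with A-domain
#'   oxidation; product 2-methylthiazole-4-carboxylic acid.
#' * `nrps-dipeptide`: glycine loading, LCL condensation of alanine,
#'   hydrolytic release; product glycyl-L-alanine.
#' * `r-release`: propionyl loading, malonyl extension with B1
#'   ketoreduction, reductive release to the primary alcohol.
#'
#' @param name One of `r paste(FIXTURE_NAMES, collapse = ", ")`.
#' @return An `ms_cluster`.
#' @export
make_named_fixture <- function(name) {
  load_at <- function(code)
    new_module(list(new_domain("AT", substrate_code = code,
                               is_loading = TRUE),
                    new_domain("ACP")), is_loading = TRUE)
  load_a <- function(code)
    new_module(list(new_domain("A", substrate_code = code),
                    new_domain("PCP")), is_loading = TRUE)
  one_sub <- function(id, nm, ...)
    new_cluster(id, nm, list(new_subunit(paste0(nm, "-s1"), list(...))))

  switch(name,
    "triketide" = one_sub("fx-triketide", "triketide",
      load_at("prop"),
      new_module(list(new_domain("KS"),
                      new_domain("AT", substrate_code = "mmal"),
                      new_domain("KR", kr_type = "B1"),
                      new_domain("ACP"),
                      new_domain("TE", release_mode = "hydrolysis")))),
    "dh-no-kr" = one_sub("fx-dh-no-kr", "dh-no-kr",
      load_at("ace"),
      new_module(list(new_domain("KS"),
                      new_domain("AT", substrate_code = "mal"),
                      new_domain("DH"),
                      new_domain("ACP"),
                      new_domain("TE", release_mode = "hydrolysis")))),
    "lactam-release" = one_sub("fx-lactam-release", "lactam-release",
      load_a("gly"),
      new_module(list(new_domain("KS"),
                      new_domain("AT", substrate_code = "mal"),
                      new_domain("KR", kr_type = "B1"),
                      new_domain("ACP"))),
      new_module(list(new_domain("KS"),
                      new_domain("AT", substrate_code = "mal"),
                      new_domain("ACP"),
                      new_domain("TE", release_mode = "lactam",
                                 ring_site = 0L)))),
    "azoline" = one_sub("fx-azoline", "azoline",
      load_at("ace"),
      new_module(list(new_domain("Cy"),
                      new_domain("A", substrate_code = "cys",
                                 modification = "oxidation"),
                      new_domain("PCP"),
                      new_domain("TE", release_mode = "hydrolysis")))),
    "nrps-dipeptide" = one_sub("fx-nrps-dipeptide", "nrps-dipeptide",
      load_a("gly"),
      new_module(list(new_domain("C", c_type = "LCL"),
                      new_domain("A", substrate_code = "ala"),
                      new_domain("PCP"),
                      new_domain("TE", release_mode = "hydrolysis")))),
    "r-release" = one_sub("fx-r-release", "r-release",
      load_at("prop"),
      new_module(list(new_domain("KS"),
                      new_domain("AT", substrate_code = "mal"),
                      new_domain("KR", kr_type = "B1"),
                      new_domain("ACP"),
                      new_domain("R", product_level = "alcohol")))),
    stop("unknown fixture name '", name, "'; shipped fixtures: ",
         paste(FIXTURE_NAMES, collapse = ", "), call. = FALSE))
}

#' Generate random, simulatable clusters
#'
#' Draws cluster layouts from a fixed scheme: one of the five loading
#' configurations, one to `max_extension` extension modules (PKS Claisen
#' extensions with optional MT and reductive loops, or NRPS condensations
#' with optional heterocyclization, azoline redox, epimerization,
#' N-methylation and N-formylation), and a terminal release domain.
#' A fraction `p_broken` of PKS reductive loops is generated with the KR
#' dropped while DH/ER stay annotated active, emulating the inconsistent
#' annotations that [repair_reductive_domains()] fixes. The same `seed`
#' always yields the same clusters.
#'
#' @param n Number of clusters.
#' @param seed Integer seed.
#' @param max_extension Maximum extension modules per cluster.
#' @param p_nrps Probability that an extension module is NRPS-type.
#' @param p_broken Probability of a KR-less broken reductive loop.
#' @return List of `ms_cluster` objects.
#' @export
make_random_clusters <- function(n, seed, max_extension = 4L,
                                 p_nrps = 0.35, p_broken = 0.15) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))
  aa_codes <- c("ala", "gly", "ser", "leu", "val", "phe", "thr", "cys",
                "lys", "pro", "trp", "asp", "gln", "met", "ile", "tyr")
  starter_codes <- c("ace", "prop", "but", "ibut", "benz")
  starter_smiles_pool <- c("CC(O)CC(=O)S", "OCCC(=O)S", "CCCCCC(=O)S")
  extender_codes <- c("mal", "mal", "mal", "mmal", "mmal", "emal", "mxmal")

  lapply(seq_len(n), function(k) {
    loading_kind <- sample(c("AT-ACP", "A-PCP", "CAL-ACP", "CAL-PCP",
                             "ACP"), 1L,
                           prob = c(0.35, 0.25, 0.1, 0.1, 0.2))
    loading_residue <- sample(aa_codes, 1L)
    loading <- switch(loading_kind,
      "AT-ACP" = new_module(list(
        new_domain("AT", substrate_code = sample(starter_codes, 1L),
                   is_loading = TRUE),
        new_domain("ACP")), is_loading = TRUE),
      "A-PCP" = new_module(list(
        new_domain("A", substrate_code = loading_residue),
        new_domain("PCP")), is_loading = TRUE),
      "CAL-ACP" = ,
      "CAL-PCP" = new_module(list(
        if (stats::runif(1) < 0.5)
          new_domain("CAL", starter_code = sample(starter_codes, 1L))
        else
          new_domain("CAL",
                     starter_smiles = sample(starter_smiles_pool, 1L)),
        new_domain(if (loading_kind == "CAL-ACP") "ACP" else "PCP")),
        is_loading = TRUE),
      "ACP" = new_module(list(
        new_domain("ACP",
                   starter_smiles = sample(starter_smiles_pool, 1L))),
        is_loading = TRUE))

    # proline's ring nitrogen is secondary: no primary N-terminal amine to
    # formylate or lactamize
    has_free_n_terminus <- loading_kind == "A-PCP" &&
      loading_residue != "pro"
    n_ext <- sample.int(max_extension, 1L)
    lactone_sites <- integer(0)
    modules <- vector("list", n_ext)
    for (e in seq_len(n_ext)) {
      unit_ord <- e  # 0-based ordinal of the unit this module adds
      if (stats::runif(1) < p_nrps) {
        code <- sample(aa_codes, 1L)
        doms <- list()
        use_cy <- stats::runif(1) < 0.18
        if (use_cy) {
          code <- sample(c("cys", "ser", "thr"), 1L)
          amod <- sample(c("none", "oxidation", "reduction"), 1L,
                         prob = c(0.4, 0.4, 0.2))
          doms <- c(doms, list(new_domain("Cy"),
                               new_domain("A", substrate_code = code,
                                          modification = amod)))
        } else {
          ctype <- sample(c("LCL", "DCL", "Dual", "Glycopeptide"), 1L,
                          prob = c(0.5, 0.2, 0.2, 0.1))
          doms <- c(doms, list(new_domain("C", c_type = ctype),
                               new_domain("A", substrate_code = code)))
          if (code != "gly" && stats::runif(1) < 0.2)
            doms <- c(doms, list(new_domain("E")))
          if (code != "pro" && stats::runif(1) < 0.15)
            doms <- c(doms, list(new_domain("nMT")))
          if (has_free_n_terminus && stats::runif(1) < 0.1) {
            doms <- c(doms, list(new_domain("F")))
            has_free_n_terminus <- FALSE
          }
        }
        doms <- c(doms, list(new_domain("PCP")))
        modules[[e]] <- new_module(doms)
      } else {
        ext_code <- sample(extender_codes, 1L)
        doms <- list(new_domain("KS"),
                     new_domain("AT", substrate_code = ext_code))
        use_mt <- ext_code == "mal" && stats::runif(1) < 0.12
        if (use_mt) doms <- c(doms, list(new_domain("MT")))
        loop <- sample(c("none", "KR", "KR+DH", "KR+DH+ER"), 1L,
                       prob = c(0.25, 0.3, 0.2, 0.25))
        if (loop != "none") {
          kr_type <- if (loop == "KR")
            sample(c(KR_REDUCING_TYPES, "C1", "C2"), 1L)
          else sample(KR_REDUCING_TYPES, 1L)
          broken <- stats::runif(1) < p_broken
          if (!broken) doms <- c(doms,
                                 list(new_domain("KR", kr_type = kr_type)))
          if (loop %in% c("KR+DH", "KR+DH+ER"))
            doms <- c(doms, list(new_domain("DH")))
          if (loop == "KR+DH+ER") doms <- c(doms, list(new_domain("ER")))
          if (!broken && loop == "KR" &&
              kr_type %in% KR_REDUCING_TYPES)
            lactone_sites <- c(lactone_sites, unit_ord)
        }
        doms <- c(doms, list(new_domain("ACP")))
        modules[[e]] <- new_module(doms)
      }
    }

    release <- sample(c("hydrolysis", "aldehyde", "alcohol", "cyclic"), 1L,
                      prob = c(0.55, 0.1, 0.1, 0.25))
    rel_dom <- NULL
    if (release == "cyclic") {
      if (loading_kind == "A-PCP" && has_free_n_terminus &&
          length(modules) >= 1L) {
        rel_dom <- new_domain("TE", release_mode = "lactam", ring_site = 0L)
      } else if (length(lactone_sites)) {
        site <- min(lactone_sites)
        # ring = O + beta-C + 2/3 backbone atoms per downstream unit
        if (2L + 2L * (n_ext - site + 1L) >= 5L)
          rel_dom <- new_domain("TE", release_mode = "lactone",
                                ring_site = site)
      }
      if (is.null(rel_dom))
        rel_dom <- new_domain("TE", release_mode = "hydrolysis")
    } else if (release %in% c("aldehyde", "alcohol")) {
      rel_dom <- new_domain("R", product_level = release)
    } else {
      rel_dom <- new_domain("TE", release_mode = "hydrolysis")
    }
    last <- modules[[n_ext]]
    modules[[n_ext]] <- new_module(c(last$domains, list(rel_dom)))

    # split modules across 1-2 subunits at a random boundary
    all_mods <- c(list(loading), modules)
    subunits <- if (length(all_mods) >= 3L && stats::runif(1) < 0.4) {
      cut <- sample(2:(length(all_mods) - 1L), 1L)
      list(new_subunit("subA", all_mods[seq_len(cut)]),
           new_subunit("subB", all_mods[(cut + 1L):length(all_mods)]))
    } else {
      list(new_subunit("subA", all_mods))
    }
    new_cluster(sprintf("rnd-%03d", k), sprintf("random cluster %d", k),
                subunits, reviewed = FALSE)
  })
}
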