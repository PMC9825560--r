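# Domain chemistry, one transform at a time, checked against
# hand-canonicalized reference structures and molecular-formula oracles.

thioester_formula <- function(chain)
  molecular_formula(chain_smiles(chain, "thioester"))

test_that("loading configurations bind the documented starter units", {
  # AT+ACP: propionyl thioester; free-acid rendering is propionic acid
  ch <- load_starter(load_at("prop"))
  expect_identical(chain_smiles(ch), canon("CCC(=O)O"))
  expect_identical(thioester_formula(ch), "C3H6OS")

  # A+PCP: glycyl with a free alpha-amine
  ch2 <- load_starter(load_a("gly"))
  expect_identical(chain_smiles(ch2), canon("NCC(=O)O"))
  expect_identical(count_smarts(chain_smiles(ch2), "[NX3H2]"), 1L)

  # standalone ACP attaches starter_smiles verbatim
  m <- mod(new_domain("ACP", starter_smiles = "CC(O)CC(=O)S"),
           loading = TRUE)
  ch3 <- load_starter(m)
  expect_identical(chain_smiles(ch3), canon("CC(O)CC(=O)O"))

  # CAL loading by code
  m2 <- mod(new_domain("CAL", starter_code = "benz"), new_domain("PCP"),
            loading = TRUE)
  expect_identical(chain_smiles(load_starter(m2)), canon("c1ccccc1C(=O)O"))

  # missing starter specification errors
  m3 <- new_module(list(new_domain("ACP")), is_loading = TRUE)
  expect_error(load_starter(m3), "missing starter specification")
})

test_that("Claisen extension grows the chain by one ketide unit", {
  at_mmal <- list(substrate_code = "mmal")
  at_mal <- list(substrate_code = "mal")

  # propionyl + mmal -> 2-methyl-3-oxopentanoyl (acyl C6H9O2)
  ch <- extend_pks(load_starter(load_at("prop")), at_mmal)
  expect_identical(chain_smiles(ch), canon("CCC(=O)C(C)C(=O)O"))
  expect_identical(thioester_formula(ch), "C6H10O2S")

  # acetyl + mal -> acetoacetyl
  ch2 <- extend_pks(load_starter(load_at("ace")), at_mal)
  expect_identical(chain_smiles(ch2), canon("CC(=O)CC(=O)O"))

  # heavy-atom deltas: mal +C2,+O; mmal +C3,+O; MT adds +C1
  base <- parse_formula(thioester_formula(load_starter(load_at("ace"))))
  f_mal <- parse_formula(thioester_formula(ch2))
  expect_identical(f_mal[["C"]] - base[["C"]], 2L)
  expect_identical(f_mal[["O"]] - base[["O"]], 1L)
  ch3 <- extend_pks(load_starter(load_at("ace")), at_mal, mt_active = TRUE)
  expect_identical(parse_formula(thioester_formula(ch3))[["C"]] -
                     f_mal[["C"]], 1L)

  # a released chain cannot be extended
  rel <- release_te(load_starter(load_at("ace")),
                    list(release_mode = "hydrolysis"))
  expect_error(extend_pks(rel$chain, at_mal), "already been released")
})

test_that("ketoreduction respects KR types and the stereo convention table", {
  ch <- extend_pks(load_starter(load_at("ace")),
                   list(substrate_code = "mal"))
  red <- apply_kr(ch, list(kr_type = "B1"))
  # B-type beta-hydroxyl gets the [C@@H] descriptor by convention
  expect_identical(chain_smiles(red), canon("C[C@@H](O)CC(=O)O"))
  expect_identical(molecular_formula(chain_smiles(red)), "C4H8O3")
  # formula delta +H2 on the thioester form
  expect_identical(
    formula_string(formula_add(parse_formula(thioester_formula(ch)),
                               parse_formula("H2"))),
    thioester_formula(red))

  atype <- apply_kr(ch, list(kr_type = "A1"))
  expect_identical(chain_smiles(atype), canon("C[C@H](O)CC(=O)O"))
  expect_false(identical(chain_smiles(atype), chain_smiles(red)))

  # C1 is a structure passthrough
  c1 <- apply_kr(ch, list(kr_type = "C1"))
  expect_identical(chain_smiles(c1), chain_smiles(ch))

  # reducing types demand a beta-ketone
  expect_error(apply_kr(load_starter(load_at("prop")),
                        list(kr_type = "A1")),
               "no beta-ketone")
})

test_that("dehydration and enoylreduction walk the reductive loop", {
  ch <- apply_kr(extend_pks(load_starter(load_at("ace")),
                            list(substrate_code = "mal")),
                 list(kr_type = "B1"))
  ene <- apply_dh(ch)
  expect_identical(chain_smiles(ene), canon("C/C=C/C(=O)O"))  # E-crotonic
  expect_error(apply_dh(ene), "no beta-hydroxyl")

  sat <- apply_er(ene)
  expect_identical(chain_smiles(sat), canon("CCCC(=O)O"))
  expect_error(apply_er(sat), "no alpha,beta-alkene")

  # net KR+DH+ER formula change is +H2 -H2O +H2 versus the beta-ketone
  keto <- extend_pks(load_starter(load_at("ace")),
                     list(substrate_code = "mal"))
  expect_identical(
    thioester_formula(sat),
    formula_string(formula_add(parse_formula(thioester_formula(keto)),
                               parse_formula("H4"),
                               formula_scale(parse_formula("H2O"), -1L))))
})

test_that("amide condensation builds peptides and flags donor stereo", {
  lcl <- list(c_type = "LCL")
  ch <- condense_nrps(load_starter(load_at("prop")), lcl,
                      list(substrate_code = "gly"))
  expect_identical(chain_smiles(ch), canon("CCC(=O)NCC(=O)O"))
  expect_identical(count_smarts(chain_smiles(ch), "[CX3](=O)[NX3]"), 1L)

  # Dual on glycine equals LCL (achiral, epimerization no-op with warning)
  dual <- condense_nrps(load_starter(load_at("prop")),
                        list(c_type = "Dual"),
                        list(substrate_code = "gly"))
  expect_identical(chain_smiles(dual), chain_smiles(ch))
  expect_match(dual$warnings, "no alpha stereocenter")

  # Dual on alanine gives the D-residue (inverted descriptor)
  duala <- condense_nrps(load_starter(load_at("prop")),
                         list(c_type = "Dual"),
                         list(substrate_code = "ala"))
  expect_identical(chain_smiles(duala), canon("CCC(=O)N[C@H](C)C(=O)O"))

  # two successive condensations: amide count equals residue count - 1
  tri <- condense_nrps(condense_nrps(load_starter(load_a("gly")), lcl,
                                     list(substrate_code = "ala")),
                       lcl, list(substrate_code = "val"))
  expect_identical(count_smarts(chain_smiles(tri), "[CX3](=O)[NX3]"), 2L)

  # DCL after an L donor records a configuration warning
  dcl <- condense_nrps(condense_nrps(load_starter(load_a("ala")), lcl,
                                     list(substrate_code = "ala")),
                       list(c_type = "DCL"), list(substrate_code = "gly"))
  expect_match(dcl$warnings, "donor residue is L-configured", all = FALSE)
})

test_that("heterocyclization forms azolines from cys/ser/thr only", {
  ace <- load_starter(load_at("ace"))
  thia <- heterocyclize(ace, list(substrate_code = "cys"))
  expect_identical(chain_smiles(thia), canon("CC1=N[C@@H](CS1)C(=O)O"))
  oxa <- heterocyclize(ace, list(substrate_code = "ser"))
  expect_identical(chain_smiles(oxa), canon("CC1=N[C@@H](CO1)C(=O)O"))
  # thiazoline ring contains S, oxazoline O; neither is aromatic yet
  expect_identical(count_smarts(chain_smiles(thia), "[S;R]"), 1L)
  expect_identical(count_smarts(chain_smiles(oxa), "[O;R]"), 1L)
  expect_error(heterocyclize(ace, list(substrate_code = "gly")),
               "no suitable side-chain nucleophile")
  # net delta vs plain condensation is -H2O
  plain <- condense_nrps(ace, list(c_type = "LCL"),
                         list(substrate_code = "cys"))
  expect_identical(
    thioester_formula(thia),
    formula_string(formula_add(parse_formula(thioester_formula(plain)),
                               formula_scale(parse_formula("H2O"), -1L))))
})

test_that("azoline redox reaches the azole and azolidine oxidation levels", {
  thia <- heterocyclize(load_starter(load_at("ace")),
                        list(substrate_code = "cys"))
  f0 <- parse_formula(thioester_formula(thia))

  ox <- apply_azoline_redox(thia, "oxidation")
  expect_identical(chain_smiles(ox), canon("Cc1nc(C(=O)O)cs1"))
  expect_identical(count_smarts(chain_smiles(ox), "[c;R]"), 3L)  # aromatic
  expect_identical(parse_formula(thioester_formula(ox))[["H"]],
                   f0[["H"]] - 2L)

  red <- apply_azoline_redox(thia, "reduction")
  expect_identical(chain_smiles(red), canon("CC1N[C@@H](CS1)C(=O)O"))
  expect_identical(parse_formula(thioester_formula(red))[["H"]],
                   f0[["H"]] + 2L)

  expect_error(apply_azoline_redox(load_starter(load_a("gly")),
                                   "oxidation"), "no azoline")
})

test_that("epimerization inverts the newest alpha-descriptor and is an involution", {
  ch <- condense_nrps(load_starter(load_at("prop")), list(c_type = "LCL"),
                      list(substrate_code = "ala"))
  once <- epimerize(ch)
  expect_identical(chain_smiles(once), canon("CCC(=O)N[C@H](C)C(=O)O"))
  expect_false(identical(chain_smiles(once), chain_smiles(ch)))
  twice <- epimerize(once)
  expect_identical(chain_smiles(twice), chain_smiles(ch))
  # glycine: unchanged plus warning
  chg <- condense_nrps(load_starter(load_at("prop")), list(c_type = "LCL"),
                       list(substrate_code = "gly"))
  eg <- epimerize(chg)
  expect_identical(chain_smiles(eg), chain_smiles(chg))
  expect_match(eg$warnings, "no alpha stereocenter", all = FALSE)
})

test_that("N-formylation and N-methylation decorate the right nitrogens", {
  gly <- load_starter(load_a("gly"))
  f <- formylate(gly)
  expect_identical(chain_smiles(f), canon("O=CNCC(=O)O"))
  # formylation is net +CO: the installed CHO consumes one N-H
  expect_identical(
    thioester_formula(f),
    formula_string(formula_add(parse_formula(thioester_formula(gly)),
                               parse_formula("CO"))))
  expect_error(formylate(f), "no free primary N-terminal amine")
  expect_error(formylate(load_starter(load_at("prop"))),
               "no free primary N-terminal amine")

  pep <- condense_nrps(load_starter(load_at("prop")), list(c_type = "LCL"),
                       list(substrate_code = "gly"))
  nm <- n_methylate(pep)
  expect_identical(chain_smiles(nm), canon("CCC(=O)N(C)CC(=O)O"))
  expect_identical(count_smarts(chain_smiles(nm),
                                "[CX3](=O)[NX3H0]([CH3])"), 1L)
  expect_identical(
    thioester_formula(nm),
    formula_string(formula_add(parse_formula(thioester_formula(pep)),
                               parse_formula("CH2"))))
  expect_error(n_methylate(nm), "bears no hydrogen")

  # loading aminoacyl: methylates the free alpha-amine with a warning
  nm2 <- n_methylate(gly)
  expect_identical(chain_smiles(nm2), canon("CNCC(=O)O"))
  expect_match(nm2$warnings, "methylated the free alpha-amine")
})

test_that("release chemistry produces acids, macrocycles, aldehydes and alcohols", {
  prop <- load_starter(load_at("prop"))
  expect_identical(release_te(prop, list(release_mode = "hydrolysis"))$smiles,
                   canon("CCC(=O)O"))
  expect_identical(release_r(prop, list(product_level = "aldehyde"))$smiles,
                   canon("CCC=O"))
  alc <- release_r(prop, list(product_level = "alcohol"))
  expect_identical(alc$smiles, canon("CCCO"))
  expect_identical(molecular_formula(alc$smiles), "C3H8O")
  rel <- release_te(prop, list(release_mode = "hydrolysis"))
  expect_error(release_te(rel$chain, list(release_mode = "hydrolysis")),
               "already been released")

  # macrolactone onto a hydroxylated starter: ester present, no free acid
  m <- mod(new_domain("ACP", starter_smiles = "CC(O)CC(=O)S"),
           loading = TRUE)
  chain <- extend_pks(load_starter(m), list(substrate_code = "mal"))
  lac <- release_te(chain, list(release_mode = "lactone", ring_site = 0L))
  expect_identical(lac$ring_size, 6L)
  expect_identical(count_smarts(lac$smiles, "[CX3](=O)[OX2H0;R]"), 1L)
  expect_identical(count_smarts(lac$smiles, "[CX3](=O)[OX2H1]"), 0L)

  # macrolactam onto the free N-terminus: cyclic amide, no free acid
  pep <- condense_nrps(condense_nrps(load_starter(load_a("gly")),
                                     list(c_type = "LCL"),
                                     list(substrate_code = "ala")),
                       list(c_type = "LCL"), list(substrate_code = "gly"))
  lam <- release_te(pep, list(release_mode = "lactam", ring_site = 0L))
  expect_identical(lam$ring_size, 9L)
  expect_identical(count_smarts(lam$smiles, "[CX3](=O)[OX2H1]"), 0L)
  expect_identical(count_smarts(lam$smiles, "[CX3](=O)[NX3;R]"), 3L)

  # missing nucleophile at the requested site
  expect_error(release_te(chain, list(release_mode = "lactam",
                                      ring_site = 0L)),
               "no amine nucleophile")
  expect_error(release_te(prop, list(release_mode = "lactone",
                                     ring_site = 0L)),
               "no hydroxyl nucleophile")
})
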