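# Data model: composition validation, reductive-domain repair,
# architecture tokens.

test_that("a well-formed two-module PKS validates cleanly", {
  cl <- one_sub_cluster("ok",
    load_at("prop"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mmal"),
        new_domain("KR", kr_type = "B1"), new_domain("ACP"),
        new_domain("TE", release_mode = "hydrolysis")))
  rep <- validate_cluster(cl)
  expect_true(is_valid(rep))
  expect_identical(nrow(rep$errors), 0L)
})

test_that("carrier uniqueness and substrate resolution are enforced per module", {
  # module with both ACP and PCP
  cl <- one_sub_cluster("two-carriers",
    load_at("prop"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mal"),
        new_domain("ACP"), new_domain("PCP")))
  rep <- validate_cluster(cl)
  expect_false(is_valid(rep))
  expect_identical(sum(grepl("exactly one carrier", rep$errors$message)), 1L)
  expect_identical(rep$errors$module[grepl("carrier", rep$errors$message)],
                   1L)

  # unresolvable AT substrate
  cl2 <- one_sub_cluster("bad-sub",
    load_at("prop"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "zzz"),
        new_domain("ACP")))
  rep2 <- validate_cluster(cl2)
  expect_identical(nrow(rep2$errors), 1L)
  expect_match(rep2$errors$message, "unresolved extender code 'zzz'")
})

test_that("module-composition rules catch the documented layouts", {
  # trans-AT (KS without AT) is rejected
  cl <- one_sub_cluster("trans-at",
    load_at("ace"),
    mod(new_domain("KS"), new_domain("KR", kr_type = "A1"),
        new_domain("ACP")))
  expect_match(validate_cluster(cl)$errors$message, "requires KS and AT")

  # NRPS module missing the A domain
  cl2 <- one_sub_cluster("no-a",
    load_a("gly"),
    mod(new_domain("C", c_type = "LCL"), new_domain("PCP")))
  expect_match(validate_cluster(cl2)$errors$message,
               "requires \\(C or Cy\\)")

  # release domain not in the final module
  cl3 <- one_sub_cluster("early-te",
    load_at("ace"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mal"),
        new_domain("ACP"), new_domain("TE", release_mode = "hydrolysis")),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mal"),
        new_domain("ACP")))
  expect_match(validate_cluster(cl3)$errors$message,
               "must be in the final module")

  # Cy with a residue lacking a side-chain nucleophile
  cl4 <- one_sub_cluster("cy-gly",
    load_at("ace"),
    mod(new_domain("Cy"), new_domain("A", substrate_code = "gly"),
        new_domain("PCP")))
  expect_match(validate_cluster(cl4)$errors$message, "cys/ser/thr")

  # azoline redox annotated without a Cy in the module: warning, not error
  cl5 <- one_sub_cluster("redox-no-cy",
    load_a("gly"),
    mod(new_domain("C", c_type = "LCL"),
        new_domain("A", substrate_code = "ala",
                   modification = "oxidation"),
        new_domain("PCP")))
  rep5 <- validate_cluster(cl5)
  expect_true(is_valid(rep5))
  expect_match(rep5$warnings$message, "Cy-formed azoline")
})

test_that("domain constructors reject malformed attribute records", {
  expect_error(new_domain("QQ"), "unknown domain kind")
  expect_error(new_domain("KR", kr_type = "Z9"), "kr_type")
  expect_error(new_domain("AT"), "requires substrate_code")
  expect_error(new_domain("TE", release_mode = "lactone"),
               "requires ring_site")
  expect_error(new_domain("TE", release_mode = "hydrolysis",
                          ring_site = 1L), "no ring_site")
  expect_error(new_domain("CAL", starter_code = "ace",
                          starter_smiles = "CC(=O)S"), "exactly one")
  expect_error(new_domain("KS", kr_type = "A1"), "does not take")
})

test_that("repair inactivates reductive domains lacking prerequisites", {
  # DH and ER active with no KR at all: both flipped, two records
  cl <- one_sub_cluster("dh-er-no-kr",
    load_at("ace"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mal"),
        new_domain("DH"), new_domain("ER"), new_domain("ACP")))
  rep <- repair_reductive_domains(cl)
  expect_identical(nrow(rep$changes), 2L)
  expect_setequal(rep$changes$domain, c("DH", "ER"))
  kinds_active <- vapply(
    Filter(function(d) d$active, cluster_modules(rep$cluster)[[2]]$domains),
    `[[`, character(1), "kind")
  expect_false(any(c("DH", "ER") %in% kinds_active))

  # ER alone: one record
  cl2 <- one_sub_cluster("er-only",
    load_at("ace"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mal"),
        new_domain("ER"), new_domain("ACP")))
  expect_identical(nrow(repair_reductive_domains(cl2)$changes), 1L)

  # complete loop untouched
  cl3 <- one_sub_cluster("full-loop",
    load_at("ace"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mal"),
        new_domain("KR", kr_type = "B1"), new_domain("DH"),
        new_domain("ER"), new_domain("ACP")))
  expect_identical(nrow(repair_reductive_domains(cl3)$changes), 0L)

  # a non-reducing KR (C1 passthrough) does not license DH
  cl4 <- one_sub_cluster("c1-dh",
    load_at("ace"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mal"),
        new_domain("KR", kr_type = "C1"), new_domain("DH"),
        new_domain("ACP")))
  rep4 <- repair_reductive_domains(cl4)
  expect_identical(rep4$changes$domain, "DH")
})

test_that("repair is idempotent and only ever deactivates", {
  cls <- make_random_clusters(25, seed = 11)
  for (cl in cls) {
    r1 <- repair_reductive_domains(cl)
    r2 <- repair_reductive_domains(r1$cluster)
    expect_identical(r2$cluster, r1$cluster)
    expect_identical(nrow(r2$changes), 0L)
    before <- cluster_modules(cl)
    after <- cluster_modules(r1$cluster)
    for (i in seq_along(before)) {
      expect_identical(vapply(before[[i]]$domains, `[[`, character(1),
                              "kind"),
                       vapply(after[[i]]$domains, `[[`, character(1),
                              "kind"))
      expect_true(all(vapply(after[[i]]$domains, `[[`, logical(1),
                             "active") <=
                      vapply(before[[i]]$domains, `[[`, logical(1),
                             "active")))
    }
  }
})

test_that("architecture tokens serialize active configurations only", {
  cl <- one_sub_cluster("arch",
    load_at("prop"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mmal"),
        new_domain("KR", kr_type = "B1"), new_domain("ACP")))
  expect_identical(architecture_of(cl),
                   c("AT:prop:load", "ACP", "KS", "AT:mmal", "KR:B1",
                     "ACP"))
  # after repair the inactivated DH token disappears
  cl2 <- one_sub_cluster("arch2",
    load_at("ace"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mal"),
        new_domain("DH"), new_domain("ACP")))
  toks <- architecture_of(repair_reductive_domains(cl2)$cluster)
  expect_false("DH" %in% toks)
  # no active DH token without a KR token, across random clusters
  for (cl in make_random_clusters(15, seed = 5)) {
    repaired <- repair_reductive_domains(cl)$cluster
    for (m in cluster_modules(repaired)) {
      kinds <- vapply(Filter(function(d) d$active, m$domains), `[[`,
                      character(1), "kind")
      if ("DH" %in% kinds) expect_true("KR" %in% kinds)
      if ("ER" %in% kinds) expect_true(all(c("KR", "DH") %in% kinds))
    }
  }
})

test_that("A-domain configuration differences give distinct tokens", {
  d1 <- new_domain("A", substrate_code = "cys", modification = "oxidation")
  d2 <- new_domain("A", substrate_code = "cys", modification = "reduction")
  d3 <- new_domain("A", substrate_code = "cys")
  toks <- vapply(list(d1, d2, d3), megasynth:::.domain_token, character(1))
  expect_identical(length(unique(toks)), 3L)
})
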