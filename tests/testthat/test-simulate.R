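# Whole-cluster simulation: pipeline behavior and cross-cutting invariants
# on randomized clusters.

test_that("the triketide pipeline composes extension, reduction and release", {
  cl <- make_named_fixture("triketide")
  res <- simulate_cluster(cl)
  expect_identical(res$product, canon("CC[C@@H](O)[C@@H](C)C(=O)O"))
  expect_identical(molecular_formula(res$product), "C6H12O3")
  expect_identical(nrow(res$intermediates), 2L)
  expect_identical(res$intermediates$module_index, c(0L, 1L))
})

test_that("a one-module aminoacyl loading with TE releases the free amino acid", {
  cl <- one_sub_cluster("gly-only",
    mod(new_domain("A", substrate_code = "gly"), new_domain("PCP"),
        new_domain("TE", release_mode = "hydrolysis"), loading = TRUE))
  res <- simulate_cluster(cl)
  expect_identical(res$product, canon("NCC(=O)O"))
})

test_that("repair inside simulation removes unsupported dehydration", {
  cl <- make_named_fixture("dh-no-kr")
  res <- simulate_cluster(cl)
  expect_identical(nrow(res$repair_changes), 1L)
  expect_identical(res$repair_changes$domain, "DH")
  expect_match(res$log, "repair: module 1: inactivated DH", all = FALSE)
  # product keeps the beta-ketone: no unsaturation was introduced
  expect_identical(res$product, canon("CC(=O)CC(=O)O"))
  expect_identical(count_smarts(res$product, "C=C"), 0L)
})

test_that("clusters failing validation are rejected with module context", {
  cl <- one_sub_cluster("bad",
    load_at("prop"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "zzz"),
        new_domain("ACP")))
  expect_error(simulate_cluster(cl), "failed validation.*module 1")
})

test_that("every intermediate and product of random clusters is chemically valid", {
  cls <- make_random_clusters(25, seed = 23)
  for (cl in cls) {
    res <- simulate_cluster(cl)
    for (smi in res$intermediates$smiles) {
      expect_identical(canonical_smiles(smi), smi)
      expect_match(molecular_formula(smi), "^C")
    }
    if (!is.na(res$product))
      expect_identical(canonical_smiles(res$product), res$product)
    # one intermediate per loading or elongating module
    expect_identical(nrow(res$intermediates),
                     length(cluster_modules(cl)))
  }
})

test_that("product formulas agree with the independent delta bookkeeping", {
  cls <- make_random_clusters(30, seed = 31)
  for (cl in cls) {
    res <- simulate_cluster(cl)
    target <- if (!is.na(res$product)) res$product
              else utils::tail(res$intermediates$smiles, 1L)
    expect_identical(molecular_formula(target), ledger_formula(cl),
                     label = cl$id)
  }
})

test_that("simulate(repair(c)) equals simulate(c)", {
  for (cl in make_random_clusters(10, seed = 41)) {
    r1 <- simulate_cluster(cl)
    r2 <- simulate_cluster(repair_reductive_domains(cl)$cluster)
    expect_identical(r1$intermediates, r2$intermediates)
    expect_identical(r1$product, r2$product)
  }
})

test_that("removing a downstream KR leaves upstream intermediates unchanged", {
  cl <- one_sub_cluster("kr-drop",
    load_at("prop"),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mmal"),
        new_domain("KR", kr_type = "B1"), new_domain("ACP")),
    mod(new_domain("KS"), new_domain("AT", substrate_code = "mal"),
        new_domain("KR", kr_type = "A1"), new_domain("DH"),
        new_domain("ACP"),
        new_domain("TE", release_mode = "hydrolysis")))
  res_full <- simulate_cluster(cl)
  # drop module 2's KR; repair then also kills its DH
  cl2 <- cl
  cl2$subunits[[1]]$modules[[3]]$domains <-
    Filter(function(d) d$kind != "KR",
           cl2$subunits[[1]]$modules[[3]]$domains)
  res_cut <- simulate_cluster(cl2)
  expect_identical(res_full$intermediates$smiles[1:2],
                   res_cut$intermediates$smiles[1:2])
  expect_false(identical(res_full$product, res_cut$product))
})

test_that("X contributes provenance only and AOX loads like an A domain", {
  cl <- one_sub_cluster("aox-x",
    load_at("ace"),
    mod(new_domain("C", c_type = "LCL"),
        new_domain("AOX", substrate_code = "gly"),
        new_domain("X"), new_domain("PCP"),
        new_domain("TE", release_mode = "hydrolysis")))
  res <- simulate_cluster(cl)
  expect_identical(res$product, canon("CC(=O)NCC(=O)O"))
  expect_match(res$log, "AOX: monooxygenation not modeled", all = FALSE)
  expect_match(res$log, "X: oxygenase recruitment", all = FALSE)
})

test_that("simulation results serialize to TSV and SMILES files", {
  res <- simulate_cluster(make_named_fixture("triketide"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_simulation_tsv(res, tsv, header = "test run")
  lines <- readLines(tsv)
  expect_match(lines[1], "^# test run")
  expect_identical(sum(grepl("^intermediate", lines)), 2L)
  expect_identical(sum(grepl("^product", lines)), 1L)
  smi <- withr::local_tempfile(fileext = ".smi")
  write_simulation_smi(res, smi)
  expect_identical(length(readLines(smi)), 3L)
})
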