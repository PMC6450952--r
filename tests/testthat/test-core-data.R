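write_tsv_text <- function(lines, path) writeLines(lines, path)

test_that("gene table parsing handles sets, empties, and bad labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  header <- "gene_id\tmendelian_socs\tgwas_socs\tconstrained\texpression_breadth"
  write_tsv_text(c(header, "G1\tHeart;Blood\t\t1\tenriched"), path)
  genes <- read_gene_table(path)
  expect_equal(nrow(genes), 1)
  expect_setequal(genes$mendelian_socs[[1]], c("Heart", "Blood"))
  expect_length(genes$gwas_socs[[1]], 0)
  expect_true(genes$constrained[1])

  write_tsv_text(header, path)
  expect_equal(nrow(read_gene_table(path)), 0)

  write_tsv_text(c(header, "G1\tCardiac\t\t0\tall"), path)
  expect_error(read_gene_table(path), "Cardiac")

  write_tsv_text(c(header, "G1\tHeart\t\t0\tall", "G1\tBlood\t\t0\tall"), path)
  expect_error(read_gene_table(path), "Duplicate gene_id")
})

test_that("drug table parsing validates modality, routes, and targets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  header <- "drug_id\ttargets\tmodality\troutes\tindications\tside_effects"
  write_tsv_text(c(header, "D1\tG1;G2\tsmall_molecule\tenteral\tHeart\tSkin;Heart"), path)
  drugs <- read_drug_table(path)
  expect_equal(drugs$targets[[1]], c("G1", "G2"))
  expect_equal(drugs$indications[[1]], "Heart")
  expect_setequal(drugs$side_effects[[1]], c("Skin", "Heart"))

  write_tsv_text(c(header, "D1\tG1\tsmall_molecule\toral\tHeart\tSkin"), path)
  expect_error(read_drug_table(path), "route")

  write_tsv_text(c(header, "D1\t\tsmall_molecule\tenteral\tHeart\tSkin"), path)
  expect_error(read_drug_table(path), "zero targets")

  fx <- fixture_small()
  write_tsv_text(c(header, "D1\tgX\tsmall_molecule\tenteral\tHeart\tSkin"), path)
  expect_error(read_drug_table(path, genes = fx$genes), "gX")
})

test_that("catalog writers and readers are mutually inverse", {
  fx <- fixture_small()
  gpath <- withr::local_tempfile(fileext = ".tsv")
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(fx$genes, gpath)
  write_drug_table(fx$drugs, dpath)
  expect_equal(as.data.frame(read_gene_table(gpath)), as.data.frame(fx$genes))
  expect_equal(as.data.frame(read_drug_table(dpath, genes = fx$genes)), as.data.frame(fx$drugs))
  # byte-level round trip of the serialised form
  g2 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(read_gene_table(gpath), g2)
  expect_identical(readLines(gpath), readLines(g2))
})

test_that("genetic support follows the match/mismatch/no-info definition", {
  genes <- gene_catalog(
    c("g1", "g2"),
    mendelian_socs = list("Heart", character(0)),
    gwas_socs = list(character(0), character(0))
  )
  d_match <- drug_catalog("d", list("g1"))
  d_both <- drug_catalog("d", list(c("g1", "g2")))
  d_none <- drug_catalog("d", list("g2"))
  expect_equal(derive_genetic_support(d_match, genes, "Heart", "mendelian"), "MATCH")
  expect_equal(derive_genetic_support(d_both, genes, "Blood", "mendelian"), "MISMATCH")
  expect_equal(derive_genetic_support(d_none, genes, "Heart", "mendelian"), "NO_INFO")
  expect_error(derive_genetic_support(drug_catalog("d", list("gX")), genes, "Heart"), "gX")
})

test_that("observation construction yields 21 rows per drug and honours mode", {
  fx <- fixture_small()
  obs_all <- build_observations(fx$drugs, fx$genes, "all")
  expect_equal(nrow(obs_all), 21 * nrow(fx$drugs))
  obs_off <- build_observations(fx$drugs, fx$genes, "off_indication")
  expect_false(any(obs_off$on_indication))
  n_ind <- sum(lengths(fx$drugs$indications))
  expect_equal(nrow(obs_all) - nrow(obs_off), n_ind)
  # single drug indicated in Heart: off-indication mode leaves 20 rows
  solo <- drug_catalog("dx", list("g1"), indications = list("Heart"))
  obs1 <- build_observations(solo, fx$genes, "off_indication")
  expect_equal(nrow(obs1), 20)
  expect_false("Heart" %in% obs1$soc)
})

test_that("fixture observation flags match the hand enumeration", {
  fx <- fixture_small()
  obs <- build_observations(fx$drugs, fx$genes)
  row_of <- function(id, soc) obs[obs$drug_id == id & obs$soc == soc, ]
  # d1 targets g1 (Mendelian Heart+Blood, no GWAS)
  expect_equal(row_of("d1", "Heart")$mendelian, "MATCH")
  expect_true(row_of("d1", "Heart")$on_indication)
  expect_true(row_of("d1", "Heart")$side_effect)
  expect_equal(row_of("d1", "Blood")$mendelian, "MATCH")
  expect_equal(row_of("d1", "Nervous")$mendelian, "MISMATCH")
  expect_equal(row_of("d1", "Skin")$gwas, "NO_INFO")
  expect_false(row_of("d1", "Skin")$any_support)
  # d3 targets g2 (GWAS Nervous) and g3 (Mendelian+GWAS Skin)
  expect_equal(row_of("d3", "Skin")$mendelian, "MATCH")
  expect_equal(row_of("d3", "Nervous")$gwas, "MATCH")
  expect_equal(row_of("d3", "Heart")$mendelian, "MISMATCH")
  expect_true(row_of("d3", "Heart")$all_targets_informative)
  # d4 targets the uninformative g4
  d4 <- obs[obs$drug_id == "d4", ]
  expect_true(all(d4$mendelian == "NO_INFO"))
  expect_true(all(d4$gwas == "NO_INFO"))
  expect_false(any(d4$all_targets_informative))
  expect_false(any(d4$any_support))
  # d5 combines g1 and g5: any support over Heart, Blood, Endocrine
  expect_setequal(
    obs$soc[obs$drug_id == "d5" & obs$any_support],
    c("Heart", "Blood", "Endocrine")
  )
})

test_that("adding a phenotype never demotes genetic support", {
  set.seed(11)
  socs <- soc_categories()
  for (i in 1:20) {
    cats <- random_catalogs()
    before <- build_observations(cats$drugs, cats$genes)
    g <- sample(nrow(cats$genes), 1)
    add <- sample(socs, 1)
    cats$genes$mendelian_socs[[g]] <- union(cats$genes$mendelian_socs[[g]], add)
    after <- build_observations(cats$drugs, cats$genes)
    demoted <- before$mendelian == "MATCH" & after$mendelian != "MATCH"
    expect_false(any(demoted))
  }
})

test_that("observation tables round-trip through the flat layout", {
  fx <- fixture_small()
  obs <- build_observations(fx$drugs, fx$genes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_observation_table(obs, path)
  back <- read_observation_table(path)
  expect_equal(as.data.frame(back), as.data.frame(obs))
})

test_that("common side-effect terms are removed at the frequency threshold", {
  drugs <- drug_catalog(paste0("d", 1:10), as.list(rep("g1", 10)),
                        genes = gene_catalog("g1", list("Heart"), list(character(0))))
  terms <- c(
    lapply(1:6, function(i) c("headache", "nausea")),
    lapply(7:10, function(i) "nausea")
  )
  names(terms) <- drugs$drug_id
  out <- remove_common_side_effects(drugs, terms, threshold = 0.60)
  # headache in 6/10 drugs meets the 60% threshold; nausea (10/10) too
  expect_setequal(out$removed, c("headache", "nausea"))
  expect_false(any(vapply(out$terms, function(x) "headache" %in% x, logical(1))))
  out_loose <- remove_common_side_effects(drugs, terms, threshold = 0.65)
  expect_setequal(out_loose$removed, "nausea")
  expect_true(all(vapply(out_loose$terms[1:6], function(x) "headache" %in% x, logical(1))))

  # 20 drugs x 5 terms with known counts: removed iff count >= 2
  drugs20 <- drug_catalog(paste0("d", 1:20), as.list(rep("g1", 20)),
                          genes = gene_catalog("g1", list("Heart"), list(character(0))))
  tset <- list(
    t1 = paste0("d", 1:5), t2 = paste0("d", 1:2), t3 = "d1",
    t4 = paste0("d", 10:12), t5 = character(0)
  )
  terms20 <- lapply(drugs20$drug_id, function(id) names(tset)[vapply(tset, function(v) id %in% v, logical(1))])
  names(terms20) <- drugs20$drug_id
  out20 <- remove_common_side_effects(drugs20, terms20, threshold = 0.10)
  expect_setequal(out20$removed, c("t1", "t2", "t4"))
})
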