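vocab <- load_vocabulary()

test_that("class detection assigns columns through their term domains", {
  tab <- tiny_table("occ",
    occurrenceID = "O1", scientificName = "Quercus alba",
    decimalLatitude = "40.0", eventDate = "2013-06-01")
  a <- detect_classes(tab, vocab)
  expect_setequal(a$classes, expand_iri(c(
    "dwc:Occurrence", "dwc:Taxon", "dcterms:Location", "dwc:Event")))
  expect_equal(names(a$id_columns), expand_iri("dwc:Occurrence"))
  expect_equal(unname(a$id_columns), "occurrenceID")

  # unknown columns are not an error, just unassigned
  tab2 <- tiny_table("x", foo = "1", bar = "2")
  a2 <- detect_classes(tab2, vocab)
  expect_length(a2$classes, 0L)
  expect_setequal(a2$unassigned, c("foo", "bar"))

  # record-level terms assigned to Occurrence pull the class in
  tab3 <- tiny_table("codes", institutionCode = "MVZ", catalogNumber = "123")
  a3 <- detect_classes(tab3, vocab)
  expect_equal(a3$classes, expand_iri("dwc:Occurrence"))

  # domainless record-level terms stay unassigned
  tab4 <- tiny_table("lang", language = "en", occurrenceID = "O1")
  a4 <- detect_classes(tab4, vocab)
  expect_true("language" %in% a4$unassigned)
})

test_that("normalization splits classes, deduplicates, and keeps row links", {
  tab <- tiny_table("occ",
    occurrenceID = c("O1", "O2", "O3", "O4"),
    locality = rep("Boulder Creek", 4L),
    country = rep("United States", 4L))
  nd <- normalize(tab, vocab = vocab)
  loc <- expand_iri("dcterms:Location"); occ <- expand_iri("dwc:Occurrence")
  expect_equal(nrow(nd$instance_tables[[loc]]), 1L)
  expect_equal(nrow(nd$instance_tables[[occ]]), 4L)
  expect_equal(nrow(nd$link_table), 4L)
  expect_equal(length(unique(nd$link_table[[loc]])), 1L)
  expect_equal(nd$report$duplicates_removed[[loc]], 3L)

  # single class: the instance table is the deduplicated projection
  tab1 <- tiny_table("t", scientificName = c("A", "B", "A"))
  nd1 <- normalize(tab1, vocab = vocab)
  expect_equal(nrow(nd1$instance_tables[[expand_iri("dwc:Taxon")]]), 2L)

  # zero data rows: everything empty
  tab0 <- source_table("empty", data.frame(occurrenceID = character(),
                                           scientificName = character()))
  nd0 <- normalize(tab0, vocab = vocab)
  expect_equal(nrow(nd0$instance_tables[[expand_iri("dwc:Occurrence")]]), 0L)
  expect_equal(nrow(nd0$link_table), 0L)

  # undetectable tables are an error advising manual configuration
  expect_error(normalize(tiny_table("x", foo = "1"), vocab = vocab),
               "mapping file")
})

test_that("rows whose class projection is empty produce no instance", {
  tab <- tiny_table("occ",
    occurrenceID = c("O1", "O2", "O3"),
    scientificName = c("Quercus alba", "", "Picea abies"))
  nd <- normalize(tab, vocab = vocab)
  taxon <- expand_iri("dwc:Taxon")
  expect_equal(nrow(nd$instance_tables[[taxon]]), 2L)
  expect_true(is.na(nd$link_table[[taxon]][2L]))
})

test_that("explicit-ID conflicts warn and keep first-seen literals", {
  tab <- tiny_table("occ",
    occurrenceID = c("O1", "O1"),
    catalogNumber = c("100", "999"))
  expect_warning(nd <- normalize(tab, vocab = vocab), "reused with differing")
  occ <- expand_iri("dwc:Occurrence")
  expect_equal(nrow(nd$instance_tables[[occ]]), 1L)
  expect_equal(nd$instance_tables[[occ]]$catalogNumber, "100")
  expect_error(suppressWarnings(normalize(tab, vocab = vocab, strict = TRUE)),
               "reused")
})

test_that("local integer identifiers number instances in first-appearance order", {
  tab <- tiny_table("t", scientificName = c("B", "A", "B"))
  nd <- assign_local_ids(normalize(tab, vocab = vocab))
  taxon <- expand_iri("dwc:Taxon")
  inst <- nd$instance_tables[[taxon]]
  expect_equal(inst$id, c("1", "2"))
  expect_equal(inst$scientificName, c("B", "A"))
  expect_equal(nd$link_table[[taxon]], c("1", "2", "1"))
  expect_equal(nd$id_column[[taxon]], "localID")

  # explicit-ID classes are untouched
  tab2 <- tiny_table("occ", occurrenceID = c("X9", "X1"))
  nd2 <- assign_local_ids(normalize(tab2, vocab = vocab))
  expect_equal(nd2$instance_tables[[expand_iri("dwc:Occurrence")]]$id,
               c("X9", "X1"))
})

test_that("normalization conserves cells and is duplicate-stable and deterministic", {
  spec <- fixture_spec(n_rows = 30L,
                       classes = c("Occurrence", "Taxon", "Event", "Location"),
                       duplicate_fraction = c(Taxon = 0.5, Location = 0.5),
                       seed = 3L)
  zip <- tempfile(fileext = ".zip")
  man <- generate_dwca(spec, zip)$manifest
  arc <- read_dwca(zip)
  nd <- normalize(arc, vocab = vocab)

  for (cls in names(nd$instance_tables)) {
    short <- tolower(dwctriplify:::split_iri(cls)[["local"]])
    expect_equal(nrow(nd$instance_tables[[cls]]),
                 man$instance_counts[[short]],
                 info = short)
    # cell conservation: non-empty literal cells on deduplicated instances
    lit <- nd$instance_tables[[cls]][, -1L, drop = FALSE]
    expect_equal(sum(lit != ""), man$literal_cell_counts[[short]],
                 info = short)
  }

  # appending an exact copy of every row changes no instance table
  doubled <- arc$core$data[rep(seq_len(nrow(arc$core$data)), 2L), ]
  tab2 <- source_table("core2", doubled, arc$core$terms)
  nd2 <- normalize(tab2, vocab = vocab)
  for (cls in names(nd$instance_tables)) {
    expect_equal(nrow(nd2$instance_tables[[cls]]),
                 nrow(nd$instance_tables[[cls]]))
  }
  expect_equal(nrow(nd2$link_table), 2L * nrow(nd$link_table))

  # byte-identical input, identical normalized output
  nd3 <- normalize(read_dwca(zip), vocab = vocab)
  expect_identical(nd$instance_tables, nd3$instance_tables)
  expect_identical(nd$link_table, nd3$link_table)
})

test_that("normalizing an already-normalized single-class table is the identity", {
  tab <- tiny_table("t", scientificName = c("B", "A"), family = c("F1", "F2"))
  nd1 <- assign_local_ids(normalize(tab, vocab = vocab))
  taxon <- expand_iri("dwc:Taxon")
  inst1 <- nd1$instance_tables[[taxon]]
  # re-normalize the instance table's literal columns
  nd2 <- assign_local_ids(normalize(
    source_table("t2", inst1[, -1L, drop = FALSE]), vocab = vocab))
  inst2 <- nd2$instance_tables[[taxon]]
  expect_equal(inst2[, -1L], inst1[, -1L])
})

test_that("archive extensions merge into the dataset through the core id", {
  write_zip <- dwctriplify:::write_stored_zip
  meta <- paste0(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">\n',
    '  <core fieldsTerminatedBy="," ignoreHeaderLines="1"',
    ' rowType="http://rs.tdwg.org/dwc/terms/Occurrence">\n',
    '    <files><location>occurrence.txt</location></files>\n',
    '    <id index="0"/>\n',
    '    <field index="0" term="http://rs.tdwg.org/dwc/terms/occurrenceID"/>\n',
    '    <field index="1" term="http://rs.tdwg.org/dwc/terms/scientificName"/>\n',
    '  </core>\n',
    '  <extension fieldsTerminatedBy="," ignoreHeaderLines="1"',
    ' rowType="http://rs.tdwg.org/dwc/terms/Identification">\n',
    '    <files><location>ident.txt</location></files>\n',
    '    <coreid index="0"/>\n',
    '    <field index="1" term="http://rs.tdwg.org/dwc/terms/identifiedBy"/>\n',
    '  </extension>\n</archive>\n')
  zip <- tempfile(fileext = ".zip")
  write_zip(list(
    "meta.xml" = charToRaw(meta),
    "occurrence.txt" = charToRaw(
      "occurrenceID,scientificName\nO1,Quercus alba\nO2,Picea abies\n"),
    "ident.txt" = charToRaw(
      "coreid,identifiedBy\nO1,J. Smith\nO2,J. Smith\n")), zip)
  nd <- normalize(read_dwca(zip), vocab = vocab)
  ident <- expand_iri("dwc:Identification")
  occ <- expand_iri("dwc:Occurrence")
  expect_equal(nrow(nd$instance_tables[[ident]]), 1L)  # same person, deduped
  ext_rows <- !is.na(nd$link_table[[ident]])
  expect_equal(sum(ext_rows), 2L)
  expect_setequal(nd$link_table[[occ]][ext_rows], c("O1", "O2"))
})
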