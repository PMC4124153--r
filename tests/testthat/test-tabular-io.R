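write_zip <- dwctriplify:::write_stored_zip

make_archive <- function(meta, data_files, path = tempfile(fileext = ".zip")) {
  files <- c(list("meta.xml" = charToRaw(meta)),
             lapply(data_files, charToRaw))
  write_zip(files, path)
  path
}

simple_meta <- function(sep = ",", skip = 1L, extra_field_index = NULL) {
  fields <- paste0(
    '    <field index="1" term="http://rs.tdwg.org/dwc/terms/scientificName"/>\n',
    '    <field index="2" term="http://rs.tdwg.org/dwc/terms/eventDate"/>\n',
    if (!is.null(extra_field_index)) {
      paste0('    <field index="', extra_field_index,
             '" term="http://rs.tdwg.org/dwc/terms/locality"/>\n')
    })
  paste0(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">\n',
    '  <core encoding="UTF-8" fieldsTerminatedBy="', sep,
    '" fieldsEnclosedBy="" ignoreHeaderLines="', skip,
    '" rowType="http://rs.tdwg.org/dwc/terms/Occurrence">\n',
    '    <files><location>occurrence.txt</location></files>\n',
    '    <id index="0"/>\n', fields,
    '  </core>\n</archive>\n')
}

test_that("format detection classifies by content, not just extension", {
  zip <- make_archive(simple_meta(), list("occurrence.txt" = "id\n"))
  expect_equal(detect_format(zip), "dwca")

  csv <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", csv)
  expect_equal(detect_format(csv), "csv")

  pdf <- tempfile(fileext = ".pdf")
  writeLines("%PDF-1.4", pdf)
  expect_error(detect_format(pdf), "supported formats")

  # a zip that is neither a DwC-A nor a workbook
  stray <- tempfile(fileext = ".zip")
  write_zip(list("readme.txt" = charToRaw("hi")), stray)
  expect_error(detect_format(stray), "supported formats")
})

test_that("CSV reading follows RFC 4180 and validates headers", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("occurrenceID,scientificName", "O1,Quercus alba",
               "O2,Picea abies"), path)
  tab <- read_csv_table(path)
  expect_s3_class(tab, "source_table")
  expect_equal(ncol(tab$data), 2L)
  expect_equal(nrow(tab$data), 2L)
  expect_equal(tab$name, tools::file_path_sans_ext(basename(path)))

  # quoted comma stays inside one cell
  writeLines(c("a,b", '"x, y",z'), path)
  tab <- read_csv_table(path)
  expect_equal(tab$data$a, "x, y")

  # duplicate headers rejected
  writeLines(c("taxonID,taxonID", "1,2"), path)
  expect_error(read_csv_table(path), "duplicate column headers")

  # empty file rejected
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_csv_table(empty), "empty input")
})

test_that("ragged CSV rows pad with a warning, or fail under strict", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3", "4,5"), path)
  expect_warning(tab <- read_csv_table(path), "ragged")
  expect_equal(unname(unlist(tab$data[2L, ])), c("4", "5", ""))
  expect_error(read_csv_table(path, strict = TRUE), "ragged")
})

test_that("CSV reading is lossless on cells", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "x,y", "x,", "q,y"), path)
  tab <- read_csv_table(path)
  cells <- unname(unlist(tab$data))
  expect_equal(sort(cells[nzchar(cells)]), sort(c("x", "y", "x", "q", "y")))
})

test_that("DwC-A parsing honors the descriptor", {
  data <- paste0("id,scientificName,eventDate\n",
                 paste0("O", 1:5, ",Quercus alba,2013-06-0", 1:5,
                        collapse = "\n"), "\n")
  zip <- make_archive(simple_meta(), list("occurrence.txt" = data))
  arc <- read_dwca(zip)
  expect_equal(arc$core_row_type, "http://rs.tdwg.org/dwc/terms/Occurrence")
  expect_equal(ncol(arc$core$data), 3L)
  expect_equal(nrow(arc$core$data), 5L)
  expect_equal(arc$core$terms[2L], "http://rs.tdwg.org/dwc/terms/scientificName")
  expect_equal(arc$core_id_index, 1L)
  expect_equal(arc$core$data$eventDate, paste0("2013-06-0", 1:5))

  # declared tab delimiter: cells split on tab only, not comma
  data_tab <- "id\tscientificName\teventDate\nO1\ta, b\t2013-01-01\n"
  zip2 <- make_archive(simple_meta(sep = "\\t"),
                       list("occurrence.txt" = data_tab))
  arc2 <- read_dwca(zip2)
  expect_equal(arc2$core$data$scientificName, "a, b")

  # zip without meta.xml is not a DwC-A
  stray <- tempfile(fileext = ".zip")
  write_zip(list("occurrence.txt" = charToRaw("id\nO1\n")), stray)
  expect_error(read_dwca(stray), "no meta.xml")

  # field index beyond the data width is a descriptor error
  zip3 <- make_archive(simple_meta(extra_field_index = 9L),
                       list("occurrence.txt" = "id,a,b\nO1,x,y\n"))
  expect_error(read_dwca(zip3), "out of range")

  # referenced data file missing
  zip4 <- make_archive(simple_meta(), list("other.txt" = "x\n"))
  expect_error(read_dwca(zip4), "missing from archive")
})

test_that("DwC-A extensions join to the core and orphans warn", {
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
    '    <files><location>identification.txt</location></files>\n',
    '    <coreid index="0"/>\n',
    '    <field index="1" term="http://rs.tdwg.org/dwc/terms/identifiedBy"/>\n',
    '  </extension>\n</archive>\n')
  zip <- make_archive(meta, list(
    "occurrence.txt" = "occurrenceID,scientificName\nO1,Quercus alba\nO2,Picea abies\n",
    "identification.txt" = "coreid,identifiedBy\nO1,J. Smith\nO2,A. Garcia\n"))
  arc <- read_dwca(zip)
  expect_length(arc$extensions, 1L)
  expect_equal(arc$extensions[[1L]]$row_type,
               "http://rs.tdwg.org/dwc/terms/Identification")
  expect_equal(arc$extensions[[1L]]$coreid_index, 1L)

  zip_orphan <- make_archive(meta, list(
    "occurrence.txt" = "occurrenceID,scientificName\nO1,Quercus alba\n",
    "identification.txt" = "coreid,identifiedBy\nO9,J. Smith\n"))
  expect_warning(read_dwca(zip_orphan), "no matching core row")
})

test_that("generated archives round-trip through the DwC-A reader", {
  spec <- fixture_spec(n_rows = 8L, classes = c("Occurrence", "Taxon", "Event"),
                       seed = 11L)
  zip <- tempfile(fileext = ".zip")
  generate_dwca(spec, zip)
  arc <- read_dwca(zip)
  expect_equal(arc$core_row_type, "http://rs.tdwg.org/dwc/terms/Occurrence")
  expect_equal(nrow(arc$core$data), 8L)
  expect_true("http://rs.tdwg.org/dwc/terms/eventDate" %in% arc$core$terms)
  # cells survive the round trip
  expect_true(all(nzchar(arc$core$data$occurrenceID)))
})

test_that("xlsx workbooks read through the spreadsheet reader", {
  xlsx <- tempfile(fileext = ".xlsx")
  code <- paste(
    "import sys",
    "from openpyxl import Workbook",
    "wb = Workbook()",
    "ws = wb.active",
    "ws.append(['occurrenceID', 'scientificName'])",
    "ws.append(['O1', 'Quercus alba'])",
    "ws.append(['O2', 'Picea abies'])",
    "wb.save(sys.argv[1])",
    sep = "\n")
  status <- system2(python_bin(), c("-c", shQuote(code), shQuote(xlsx)))
  expect_equal(status, 0L)
  expect_equal(detect_format(xlsx), "xlsx")
  tabs <- read_source(xlsx)
  expect_length(tabs, 1L)
  expect_equal(names(tabs[[1L]]$data), c("occurrenceID", "scientificName"))
  expect_equal(tabs[[1L]]$data$scientificName, c("Quercus alba", "Picea abies"))
})

test_that("ods workbooks read through the spreadsheet reader", {
  content <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<office:document-content',
    ' xmlns:office="urn:oasis:names:tc:opendocument:xmlns:office:1.0"',
    ' xmlns:table="urn:oasis:names:tc:opendocument:xmlns:table:1.0"',
    ' xmlns:text="urn:oasis:names:tc:opendocument:xmlns:text:1.0">\n',
    '<office:body><office:spreadsheet><table:table table:name="Sheet1">\n',
    '<table:table-row><table:table-cell><text:p>occurrenceID</text:p>',
    '</table:table-cell><table:table-cell><text:p>locality</text:p>',
    '</table:table-cell></table:table-row>\n',
    '<table:table-row><table:table-cell><text:p>O1</text:p>',
    '</table:table-cell><table:table-cell><text:p>Boulder Creek</text:p>',
    '</table:table-cell></table:table-row>\n',
    '</table:table></office:spreadsheet></office:body>',
    '</office:document-content>\n')
  ods <- tempfile(fileext = ".ods")
  write_zip(list(
    "mimetype" = charToRaw("application/vnd.oasis.opendocument.spreadsheet"),
    "content.xml" = charToRaw(content)), ods)
  expect_equal(detect_format(ods), "ods")
  tabs <- read_source(ods)
  expect_equal(tabs[[1L]]$data$locality, "Boulder Creek")
})

test_that("reader plugins can be registered without touching existing code", {
  register_reader("fwf-test", function(path, ...) {
    lines <- readLines(path)
    source_table("fwf", data.frame(a = substr(lines, 1, 2),
                                   b = substr(lines, 3, 4)))
  })
  path <- tempfile()
  writeLines(c("x1y1", "x2y2"), path)
  tabs <- read_source(path, format = "fwf-test")
  expect_equal(tabs$data$b, c("y1", "y2"))
  expect_error(read_source(path, format = "nope"), "no reader registered")
})
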