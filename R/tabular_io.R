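# Reading source data: CSV files, spreadsheet workbooks and Darwin Core
# Archives, all mapped onto one rectangular-table model.

#' Construct a source table
#'
#' The uniform rectangular-table model all readers produce: a named table of
#' text cells with unique, non-empty column headers and, optionally, a term
#' URI attached to each column (as Darwin Core Archives declare).
#'
#' @param name table name (for CSV files, the file stem).
#' @param data data frame of character cells (`""` = empty cell).
#' @param terms optional character vector of term URIs, one per column
#'   (`NA` where no term is declared).
#' @return object of class `source_table`.
#' @export
source_table <- function(name, data, terms = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE, check.names = FALSE)
  data[] <- lapply(data, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  headers <- names(data)
  if (any(!nzchar(trimws(headers)))) stop("empty column header in table '", name, "'")
  dup <- unique(headers[duplicated(headers)])
  if (length(dup)) {
    stop("duplicate column headers in table '", name, "': ",
         paste(dup, collapse = ", "))
  }
  if (is.null(terms)) terms <- rep(NA_character_, ncol(data))
  stopifnot(length(terms) == ncol(data))
  structure(list(name = name, data = data, terms = as.character(terms)),
            class = "source_table")
}

#' @export
print.source_table <- function(x, ...) {
  cat("Source table '", x$name, "': ", nrow(x$data), " rows x ",
      ncol(x$data), " columns\n", sep = "")
  cat("  columns:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

zip_entries <- function(path) {
  tryCatch(utils::unzip(path, list = TRUE, unzip = "internal")$Name,
           error = function(e) NULL)
}

#' Detect the format of an input file
#'
#' Classifies by extension and content sniffing. Zip containers are
#' inspected: an archive holding `meta.xml` is a Darwin Core Archive, one
#' holding `xl/workbook.xml` an Excel workbook, one holding an
#' OpenDocument `mimetype` an ODS workbook.
#'
#' @param path path to an existing file.
#' @return one of `"dwca"`, `"csv"`, `"xlsx"`, `"ods"`.
#' @export
detect_format <- function(path) {
  stopifnot(file.exists(path))
  magic <- readBin(path, "raw", 4L)
  if (length(magic) == 4L && identical(magic, as.raw(c(0x50, 0x4b, 0x03, 0x04)))) {
    entries <- zip_entries(path)
    if (any(basename(entries) == "meta.xml")) return("dwca")
    if (any(startsWith(entries, "xl/"))) return("xlsx")
    if ("mimetype" %in% entries) return("ods")
    stop("unsupported zip input: ", path,
         " (supported formats: dwca, csv, xlsx, ods)")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "txt", "tsv")) return("csv")
  stop("unsupported input format: ", path,
       " (supported formats: dwca, csv, xlsx, ods)")
}

#' Read a delimited text file into a source table
#'
#' RFC 4180 semantics by default: comma-separated, double-quote quoting,
#' first row as headers. Ragged rows are padded with empty cells to the
#' header width with a warning, or rejected when `strict = TRUE`.
#'
#' @param path file path (UTF-8; a leading BOM is tolerated).
#' @param sep field separator.
#' @param quote quoting character (`""` disables quoting).
#' @param header does the first row carry column names?
#' @param strict reject ragged rows instead of padding.
#' @param name table name; default is the file stem.
#' @return a [source_table()].
#' @export
read_csv_table <- function(path, sep = ",", quote = "\"", header = TRUE,
                           strict = FALSE, name = NULL) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) stop("empty input file: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))

  nfields <- tryCatch(
    utils::count.fields(path, sep = sep, quote = quote, comment.char = "",
                        blank.lines.skip = TRUE),
    warning = function(w) stop("malformed delimited file ", path, ": ",
                               conditionMessage(w))
  )
  nfields <- nfields[!is.na(nfields)]
  if (length(nfields) == 0L) stop("empty input file: ", path)
  width <- nfields[1L]
  ragged <- which(nfields != width)
  if (length(ragged)) {
    msg <- paste0("ragged rows in ", path, " (expected ", width,
                  " fields): lines ", paste(utils::head(ragged, 5L), collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; padding with empty cells")
  }

  dt <- data.table::fread(path, sep = sep, quote = quote, header = FALSE,
                          colClasses = "character", fill = TRUE,
                          blank.lines.skip = TRUE, encoding = "UTF-8",
                          na.strings = NULL, strip.white = FALSE,
                          showProgress = FALSE)
  df <- as.data.frame(dt, stringsAsFactors = FALSE)
  if (header) {
    headers <- vapply(df[1L, ], as.character, character(1))
    headers <- sub("^﻿", "", headers)  # UTF-8 BOM on first header
    df <- df[-1L, , drop = FALSE]
  } else {
    headers <- paste0("V", seq_len(ncol(df)))
  }
  dup <- unique(headers[duplicated(headers)])
  if (length(dup)) {
    stop("duplicate column headers in ", path, ": ", paste(dup, collapse = ", "))
  }
  names(df) <- headers
  rownames(df) <- NULL
  source_table(name, df)
}

#' Read a spreadsheet workbook into source tables
#'
#' Excel workbooks are read through readxl with all cells as text;
#' OpenDocument spreadsheets through a minimal `content.xml` reader. Each
#' sheet becomes one source table named `<file stem>` (first sheet) or
#' `<file stem>.<sheet>`.
#'
#' @param path `.xlsx` or `.ods` file.
#' @param sheets sheet indices to read (default: all).
#' @return list of [source_table()] objects.
#' @export
read_spreadsheet <- function(path, sheets = NULL) {
  fmt <- detect_format(path)
  stem <- tools::file_path_sans_ext(basename(path))
  if (fmt == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package")
    }
    sheet_names <- readxl::excel_sheets(path)
    idx <- if (is.null(sheets)) seq_along(sheet_names) else sheets
    out <- lapply(idx, function(i) {
      df <- readxl::read_excel(path, sheet = i, col_types = "text",
                               .name_repair = "minimal")
      nm <- if (i == 1L) stem else paste0(stem, ".", sheet_names[i])
      source_table(nm, as.data.frame(df, check.names = FALSE))
    })
    return(out)
  }
  if (fmt == "ods") return(read_ods_tables(path, stem, sheets))
  stop("not a spreadsheet workbook: ", path)
}

# Minimal ODS reader: sheet cells from content.xml.  Handles
# number-columns-repeated; keeps all cells as text.
read_ods_tables <- function(path, stem, sheets = NULL) {
  tmp <- tempfile("ods"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, files = "content.xml", exdir = tmp, unzip = "internal")
  doc <- xml2::read_xml(file.path(tmp, "content.xml"))
  tables <- xml2::xml_find_all(doc, ".//*[local-name()='table']")
  idx <- if (is.null(sheets)) seq_along(tables) else sheets
  lapply(idx, function(i) {
    tb <- tables[[i]]
    sheet_name <- xml2::xml_attr(tb, "name")
    rows <- xml2::xml_find_all(tb, "./*[local-name()='table-row']")
    cells <- lapply(rows, function(r) {
      vals <- character(0)
      for (cell in xml2::xml_find_all(r, "./*[local-name()='table-cell']")) {
        rep_n <- xml2::xml_attr(cell, "number-columns-repeated")
        rep_n <- if (is.na(rep_n)) 1L else min(as.integer(rep_n), 1024L)
        txt <- paste(xml2::xml_text(
          xml2::xml_find_all(cell, "./*[local-name()='p']")), collapse = "\n")
        vals <- c(vals, rep(txt, rep_n))
      }
      vals
    })
    # drop trailing all-empty rows and columns (ODS pads the grid)
    nonempty <- vapply(cells, function(v) any(nzchar(v)), logical(1))
    if (!any(nonempty)) stop("empty spreadsheet: ", path)
    cells <- cells[seq_len(max(which(nonempty)))]
    width <- max(vapply(cells, function(v) {
      w <- which(nzchar(v)); if (length(w)) max(w) else 0L
    }, integer(1)))
    mat <- t(vapply(cells, function(v) {
      out <- character(width); out[seq_len(min(length(v), width))] <-
        v[seq_len(min(length(v), width))]; out
    }, character(width)))
    headers <- mat[1L, ]
    df <- as.data.frame(mat[-1L, , drop = FALSE], stringsAsFactors = FALSE)
    names(df) <- headers
    nm <- if (i == 1L) stem else paste0(stem, ".", sheet_name)
    source_table(nm, df)
  })
}

# decode meta.xml attribute escapes (\t, \n, \r)
decode_meta_escape <- function(x, default) {
  if (is.na(x) || !nzchar(x)) return(default)
  x <- gsub("\\\\t", "\t", x, fixed = FALSE)
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\r", "\r", x)
  x
}

read_dwca_file <- function(node, dir, what) {
  loc <- xml2::xml_text(xml2::xml_find_first(node, "./files/location"))
  if (is.na(loc)) stop("DwC-A descriptor: <", what, "> has no <files><location>")
  fpath <- file.path(dir, loc)
  if (!file.exists(fpath)) stop("DwC-A data file missing from archive: ", loc)

  sep <- decode_meta_escape(xml2::xml_attr(node, "fieldsTerminatedBy"), ",")
  quote <- decode_meta_escape(xml2::xml_attr(node, "fieldsEnclosedBy"), "")
  skip <- xml2::xml_attr(node, "ignoreHeaderLines")
  skip <- if (is.na(skip)) 0L else as.integer(skip)
  enc <- xml2::xml_attr(node, "encoding")
  enc <- if (is.na(enc) || !nzchar(enc)) "UTF-8" else enc

  lines <- readLines(fpath, encoding = enc, warn = FALSE)
  header_line <- if (skip >= 1L && length(lines) >= 1L) lines[1L] else NA_character_
  if (skip > 0L) lines <- lines[-seq_len(min(skip, length(lines)))]
  lines <- lines[nzchar(lines)]

  split_line <- function(line) {
    if (nzchar(quote)) {
      scan(text = line, what = character(), sep = sep, quote = quote,
           quiet = TRUE, na.strings = character(0))
    } else {
      strsplit(line, sep, fixed = TRUE)[[1L]]
    }
  }

  fields <- xml2::xml_find_all(node, "./field")
  f_index <- as.integer(xml2::xml_attr(fields, "index"))
  f_term <- xml2::xml_attr(fields, "term")
  keep <- !is.na(f_index)  # fields with a <field default=...> but no index are constants; skip
  f_index <- f_index[keep]; f_term <- f_term[keep]
  id_node <- xml2::xml_find_first(node, "./id | ./coreid")
  id_index <- if (inherits(id_node, "xml_missing")) NA_integer_ else
    as.integer(xml2::xml_attr(id_node, "index"))

  ncol_decl <- max(c(f_index, id_index), na.rm = TRUE) + 1L
  cells <- lapply(lines, split_line)
  ncol_data <- if (length(cells)) max(lengths(cells)) else ncol_decl
  width <- max(ncol_decl, 1L)
  if (ncol_decl > ncol_data && length(cells)) {
    stop("DwC-A descriptor error: field index ", ncol_decl - 1L,
         " out of range for data file ", loc, " (", ncol_data, " columns)")
  }
  mat <- matrix("", nrow = length(cells), ncol = width)
  for (i in seq_along(cells)) {
    v <- cells[[i]]
    mat[i, seq_len(min(length(v), width))] <- v[seq_len(min(length(v), width))]
  }

  terms <- rep(NA_character_, width)
  terms[f_index + 1L] <- f_term
  headers <- rep(NA_character_, width)
  if (!is.na(header_line)) {
    hv <- split_line(sub("^﻿", "", header_line))
    headers[seq_len(min(length(hv), width))] <- hv[seq_len(min(length(hv), width))]
  }
  fallback <- paste0("col", seq_len(width))
  has_term <- !is.na(terms)
  fallback[has_term] <- vapply(terms[has_term],
                               function(u) split_iri(u)[["local"]], character(1))
  headers <- ifelse(is.na(headers) | !nzchar(headers), fallback, headers)
  if (!is.na(id_index) && (is.na(terms[id_index + 1L]) || !nzchar(headers[id_index + 1L]))) {
    if (!nzchar(headers[id_index + 1L])) headers[id_index + 1L] <- "id"
  }
  headers <- make.unique(headers, sep = "_")

  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- headers
  tab <- source_table(tools::file_path_sans_ext(basename(loc)), df, terms)
  list(table = tab,
       row_type = xml2::xml_attr(node, "rowType"),
       id_index = if (is.na(id_index)) NA_integer_ else id_index + 1L)
}

#' Read a Darwin Core Archive
#'
#' Unpacks the archive, parses `meta.xml` for the core and extension file
#' descriptors (row types, field indices and term URIs, declared
#' delimiters, header lines to skip), and reads each data file accordingly.
#' Declared term URIs are attached to the columns of the resulting tables.
#'
#' @param path a DwC-A zip file.
#' @return object of class `dwc_archive`: list with `core`
#'   (a [source_table()]), `core_row_type`, `core_id_index`, and
#'   `extensions` (list of `list(table, row_type, coreid_index)`).
#' @export
read_dwca <- function(path) {
  stopifnot(file.exists(path))
  entries <- zip_entries(path)
  meta_entry <- entries[basename(entries) == "meta.xml"]
  if (length(meta_entry) == 0L) {
    stop("not a Darwin Core Archive (no meta.xml): ", path)
  }
  tmp <- tempfile("dwca"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, exdir = tmp, unzip = "internal")
  dir <- file.path(tmp, dirname(meta_entry[1L]))
  doc <- xml2::read_xml(file.path(dir, "meta.xml"))
  xml2::xml_ns_strip(doc)

  core_node <- xml2::xml_find_first(doc, "./core")
  if (inherits(core_node, "xml_missing")) {
    stop("DwC-A descriptor has no <core> element: ", path)
  }
  core <- read_dwca_file(core_node, dir, "core")
  if (is.na(core$id_index)) core$id_index <- 1L

  exts <- lapply(xml2::xml_find_all(doc, "./extension"), function(node) {
    e <- read_dwca_file(node, dir, "extension")
    if (is.na(e$id_index)) stop("DwC-A extension without <coreid>: ", path)
    list(table = e$table, row_type = e$row_type, coreid_index = e$id_index)
  })

  core_ids <- core$table$data[[core$id_index]]
  for (e in exts) {
    ids <- e$table$data[[e$coreid_index]]
    orphan <- setdiff(ids[nzchar(ids)], core_ids)
    if (length(orphan)) {
      warning("DwC-A extension '", e$table$name, "' has ", length(orphan),
              " coreid value(s) with no matching core row")
    }
  }

  structure(list(core = core$table, core_row_type = core$row_type,
                 core_id_index = core$id_index, extensions = exts),
            class = "dwc_archive")
}

#' @export
print.dwc_archive <- function(x, ...) {
  cat("Darwin Core Archive\n  core row type: ", x$core_row_type, "\n", sep = "")
  cat("  core: ", nrow(x$core$data), " rows x ", ncol(x$core$data),
      " columns\n  extensions: ", length(x$extensions), "\n", sep = "")
  invisible(x)
}

#' Reader registry
#'
#' Maps format tags to reader functions. New input formats can be supported
#' by registering a reader (`path -> source_table list` or `dwc_archive`)
#' without modifying existing code.
#'
#' @return an environment mapping format tag to reader function.
#' @export
reader_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) {
      reg <<- new.env(parent = emptyenv())
      assign("csv", function(path, ...) list(read_csv_table(path, ...)), reg)
      assign("xlsx", function(path, ...) read_spreadsheet(path), reg)
      assign("ods", function(path, ...) read_spreadsheet(path), reg)
      assign("dwca", function(path, ...) read_dwca(path), reg)
    }
    reg
  }
})

#' Register a reader plugin
#'
#' @param tag format tag (as returned by [detect_format()] or passed via
#'   the CLI `--format` flag).
#' @param reader function taking a path and returning a list of
#'   [source_table()]s or a `dwc_archive`.
#' @export
register_reader <- function(tag, reader) {
  stopifnot(is.character(tag), length(tag) == 1L, is.function(reader))
  assign(tag, reader, reader_registry())
  invisible(tag)
}

#' Read any supported input
#'
#' @param path input file.
#' @param format format tag, or `"auto"` to sniff with [detect_format()].
#' @param ... passed to the selected reader.
#' @return list of [source_table()]s, or a `dwc_archive` for DwC-A input.
#' @export
read_source <- function(path, format = "auto", ...) {
  if (identical(format, "auto")) format <- detect_format(path)
  reg <- reader_registry()
  if (!exists(format, reg, inherits = FALSE)) {
    stop("no reader registered for format '", format, "' (have: ",
         paste(sort(ls(reg)), collapse = ", "), ")")
  }
  get(format, reg)(path, ...)
}
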