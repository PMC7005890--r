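## RCC lane files are plain text with <Tag>...</Tag> sections; the
## Code_Summary section holds comma-separated CodeClass,Name,Accession,Count
## rows. Parsing is locale-independent: the field separator is always a comma
## and counts are plain integers.

parse_rcc_sections <- function(lines) {
  open <- grep("^<[A-Za-z_]+>\\s*$", lines)
  sections <- list()
  for (i in open) {
    tag <- sub("^<([A-Za-z_]+)>\\s*$", "\\1", lines[i])
    close <- grep(paste0("^</", tag, ">\\s*$"), lines)
    close <- close[close > i]
    if (length(close) == 0)
      stop("RCC section <", tag, "> is never closed", call. = FALSE)
    sections[[tag]] <- lines[seq(i + 1, close[1] - 1)]
  }
  sections
}

rcc_kv <- function(section_lines) {
  parts <- strsplit(section_lines, ",", fixed = TRUE)
  keys <- vapply(parts, function(p) p[1], "")
  vals <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
  stats::setNames(vals, keys)
}

#' Read one NanoString RCC lane file
#'
#' Parses the `<Header>` / `<Sample_Attributes>` / `<Lane_Attributes>` /
#' `<Code_Summary>` sections of an RCC lane file into a single sample record.
#' Unknown sections are skipped with a warning (forward compatibility);
#' a missing `Code_Summary` is an error.
#'
#' @param path path to an `.RCC` file.
#' @return a list of class `sample_record` with elements `sample_id`,
#'   `probes` (data.frame `probe_id`, `code_class`, `accession`) and `counts`
#'   (named integer vector).
#' @export
read_rcc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sections <- parse_rcc_sections(lines)

  known <- c("Header", "Sample_Attributes", "Lane_Attributes",
             "Code_Summary", "Messages")
  unknown <- setdiff(names(sections), known)
  if (length(unknown))
    warning("skipping unknown RCC section(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  if (is.null(sections$Code_Summary))
    stop("RCC file has no Code_Summary section: ", path, call. = FALSE)

  sample_id <- NA_character_
  if (!is.null(sections$Sample_Attributes)) {
    kv <- rcc_kv(sections$Sample_Attributes)
    if (!is.na(kv["ID"]) && nzchar(kv["ID"])) sample_id <- unname(kv["ID"])
  }
  if (is.na(sample_id)) sample_id <- sub("\\.[Rr][Cc][Cc]$", "", basename(path))

  body <- sections$Code_Summary
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  if (length(parts) < 2)
    stop("empty Code_Summary in ", path, call. = FALSE)
  header <- tolower(trimws(parts[[1]]))
  need <- c("codeclass", "name", "accession", "count")
  idx <- match(need, header)
  if (anyNA(idx))
    stop("Code_Summary header must contain CodeClass,Name,Accession,Count",
         call. = FALSE)
  rows <- parts[-1]
  get <- function(k) vapply(rows, function(p) {
    if (length(p) < idx[k]) "" else trimws(p[idx[k]])
  }, "", USE.NAMES = FALSE)

  name <- get(2)
  if (anyDuplicated(name))
    stop("duplicate probe name in Code_Summary: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  count_chr <- get(4)
  if (any(!grepl("^[0-9]+$", count_chr)))
    stop("non-integer count in Code_Summary: ",
         paste(utils::head(count_chr[!grepl("^[0-9]+$", count_chr)], 3),
               collapse = ", "), call. = FALSE)
  counts <- as.integer(count_chr)

  probes <- data.frame(probe_id = name,
                       code_class = normalize_code_class(get(1)),
                       accession = get(3),
                       stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, probes = probes,
                 counts = stats::setNames(counts, name)),
            class = "sample_record")
}

#' Write one sample of a count matrix as an RCC lane file
#'
#' @param matrix a `count_matrix`.
#' @param sample_id one sample id present in `matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(matrix, sample_id, path) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (!sample_id %in% matrix$samples$sample_id)
    stop("unknown sample id: ", sample_id, call. = FALSE)
  lane <- match(sample_id, matrix$samples$sample_id)
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
    "<Sample_Attributes>", paste0("ID,", sample_id), "Owner,", "Comments,",
    "Date,", "GeneRLF,miRNA_panel", "SystemAPF,n6_vDV1", "</Sample_Attributes>",
    "<Lane_Attributes>", paste0("ID,", lane), "FovCount,555",
    "FovCounted,550", "BindingDensity,0.5", "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    paste(matrix$probes$code_class, matrix$probes$probe_id,
          matrix$probes$accession,
          format(matrix$counts[, sample_id], scientific = FALSE, trim = TRUE),
          sep = ","),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Assemble RCC sample records into a count matrix
#'
#' @param records list of `sample_record` objects sharing one panel.
#' @param sample_sheet data.frame with columns `sample_id`, `group`,
#'   `fraction`, optional `rin`, covering exactly the records.
#' @return a `count_matrix` with samples in sheet order.
#' @export
rcc_to_count_matrix <- function(records, sample_sheet) {
  ids <- vapply(records, function(r) r$sample_id, "")
  if (anyDuplicated(ids)) stop("duplicate sample ids across lanes", call. = FALSE)
  if (!setequal(ids, sample_sheet$sample_id))
    stop("sample sheet does not match the lane files read", call. = FALSE)
  probes <- records[[1]]$probes
  counts <- matrix(0L, nrow(probes), length(records),
                   dimnames = list(probes$probe_id, sample_sheet$sample_id))
  for (r in records) {
    if (!identical(r$probes$probe_id, probes$probe_id))
      stop("lane ", r$sample_id, " uses a different codeset", call. = FALSE)
    counts[, r$sample_id] <- r$counts[probes$probe_id]
  }
  count_matrix(counts, probes, sample_sheet)
}

table_sep <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read a probe-by-sample count table plus sample sheet
#'
#' The count table is CSV/TSV with columns `probe_id`, `code_class`, optional
#' `accession`, then one column per sample. The sample sheet maps `sample_id`
#' to `group`, `fraction` and optional `rin`.
#'
#' @param path count table path (`.csv` or `.tsv`).
#' @param sample_sheet sample sheet path (`.csv` or `.tsv`).
#' @return a `count_matrix` with samples in sheet order.
#' @export
read_count_table <- function(path, sample_sheet) {
  tab <- utils::read.table(path, header = TRUE, sep = table_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  sheet <- read_sample_sheet(sample_sheet)
  meta_cols <- intersect(c("probe_id", "code_class", "accession"), names(tab))
  if (!all(c("probe_id", "code_class") %in% meta_cols))
    stop("count table must have probe_id and code_class columns", call. = FALSE)
  sample_cols <- setdiff(names(tab), meta_cols)
  if (!setequal(sample_cols, sheet$sample_id))
    stop("samples in count table and sample sheet disagree: table has {",
         paste(setdiff(sample_cols, sheet$sample_id), collapse = ", "),
         "}, sheet has {",
         paste(setdiff(sheet$sample_id, sample_cols), collapse = ", "), "}",
         call. = FALSE)
  vals <- as.matrix(tab[, sheet$sample_id, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (any(is.na(num))) stop("non-numeric count in table", call. = FALSE)
  if (any(num < 0)) stop("negative count in table", call. = FALSE)
  probes <- data.frame(probe_id = tab$probe_id, code_class = tab$code_class,
                       accession = if ("accession" %in% meta_cols) tab$accession else "",
                       stringsAsFactors = FALSE)
  dimnames(num) <- list(probes$probe_id, sheet$sample_id)
  count_matrix(num, probes, sheet)
}

#' Read a sample sheet
#'
#' @param path CSV/TSV with columns `sample_id`, `group`, `fraction`,
#'   optional `rin`.
#' @return data.frame, validated and with canonical labels.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = table_sep(path),
                             stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(sheet))
    stop("sample sheet must have a sample_id column", call. = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet
}

#' Write a count matrix (and its sample sheet) as deterministic text tables
#'
#' Rows follow annotation order and columns sheet order; counts are written as
#' plain integers, so the same matrix always produces byte-identical files.
#'
#' @param matrix a `count_matrix`.
#' @param path output count table path (`.csv` or `.tsv`).
#' @param sample_sheet optional path to also write the sample sheet.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(matrix, path, sample_sheet = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  sep <- table_sep(path)
  tab <- data.frame(probe_id = matrix$probes$probe_id,
                    code_class = matrix$probes$code_class,
                    accession = matrix$probes$accession,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in matrix$samples$sample_id)
    tab[[s]] <- format(matrix$counts[, s], scientific = FALSE, trim = TRUE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE,
                     eol = "\n")
  if (!is.null(sample_sheet)) {
    sh <- matrix$samples
    utils::write.table(sh, sample_sheet, sep = table_sep(sample_sheet),
                       quote = FALSE, row.names = FALSE, eol = "\n", na = "")
  }
  invisible(path)
}
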