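# Reading thermocycler result exports.
#
# QuantStudio-style exports carry a variable-length metadata preamble before
# the results header; the header itself varies between instruments ("CT" vs
# "Cq", "Target Name" vs "Gene"). We scan for the first line that matches all
# mandatory canonical fields and treat everything above it as preamble.

# canonical field -> aliases searched in normalized (lowercase alphanumeric)
# header cells; mandatory fields first
.canonical_aliases <- list(
  well     = "well",
  sample   = "sample",
  target   = c("target", "gene"),
  ct       = c("ct", "cq"),
  task     = "task",
  quantity = "quantity",
  group    = "group"
)
.mandatory_fields <- c("well", "sample", "target", "ct")

.ct_sentinels <- c("undetermined", "n/a", "na", "")

.normalize_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Map result-table header cells to canonical fields
#'
#' Binds each canonical field (`well`, `sample`, `target`, `task`, `ct`,
#' `quantity`, `group`) to a header cell. Matching is case-insensitive and
#' tolerant of whitespace and punctuation: a cell matches if its normalized
#' form (lowercase, alphanumerics only) equals -- or failing that, contains --
#' one of the field's aliases (`target` also matches "gene", `ct` also
#' matches "Cq"). Each cell can be claimed by at most one field.
#'
#' @param header_cells Character vector of header cell contents.
#' @param overrides Optional named character vector/list mapping canonical
#'   field names to exact header names; overrides win over alias matching.
#' @return Named character vector: canonical field -> header cell. Optional
#'   fields with no match are absent.
#' @export
#' @examples
#' map_columns(c("Well", "Sample Name", "Target Name", "Task", "CT"))
map_columns <- function(header_cells, overrides = NULL) {
  stopifnot(length(header_cells) > 0)
  norm <- .normalize_header(header_cells)
  claimed <- rep(FALSE, length(header_cells))
  out <- character(0)

  for (field in names(.canonical_aliases)) {
    idx <- NA_integer_
    if (!is.null(overrides) && field %in% names(overrides)) {
      idx <- match(overrides[[field]], header_cells)
      if (is.na(idx)) {
        stop(sprintf("override for '%s' names header '%s' not present in file",
                     field, overrides[[field]]), call. = FALSE)
      }
    } else {
      aliases <- .canonical_aliases[[field]]
      exact <- which(!claimed & norm %in% aliases)
      if (length(exact)) {
        idx <- exact[1L]
      } else {
        for (a in aliases) {
          hit <- which(!claimed & grepl(a, norm, fixed = TRUE))
          if (length(hit)) { idx <- hit[1L]; break }
        }
      }
    }
    if (!is.na(idx)) {
      if (claimed[idx]) {
        stop(sprintf("header cell '%s' matched by two canonical fields",
                     header_cells[idx]), call. = FALSE)
      }
      claimed[idx] <- TRUE
      out[field] <- header_cells[idx]
    }
  }

  missing <- setdiff(.mandatory_fields, names(out))
  if (length(missing)) {
    stop(sprintf(
      "could not locate mandatory column(s) %s in header [%s]; aliases tried: %s",
      paste(missing, collapse = ", "),
      paste(header_cells, collapse = ", "),
      paste(vapply(missing, function(f)
        paste0(f, "<-{", paste(.canonical_aliases[[f]], collapse = "|"), "}"),
        character(1)), collapse = "; ")), call. = FALSE)
  }
  out
}

.parse_ct <- function(x, lines = seq_along(x)) {
  x <- trimws(x)
  ct <- rep(NA_real_, length(x))
  sentinel <- is.na(x) | tolower(x) %in% .ct_sentinels
  num <- suppressWarnings(as.numeric(x))
  bad <- !sentinel & is.na(num)
  if (any(bad)) {
    comma <- grepl("^-?[0-9]+,[0-9]+$", x[bad])
    if (any(comma)) {
      stop(sprintf(
        "CT value '%s' on line %d uses a comma decimal separator; convert the export to dot-decimal",
        x[bad][comma][1], lines[bad][comma][1]), call. = FALSE)
    }
    stop(sprintf("CT value '%s' on line %d is neither numeric nor a known sentinel",
                 x[bad][1], lines[bad][1]), call. = FALSE)
  }
  ct[!sentinel] <- num[!sentinel]
  ct
}

.parse_task <- function(x) {
  u <- toupper(trimws(x))
  dplyr::case_when(
    grepl("STANDARD|\\bSTD\\b", u) ~ "STANDARD",
    grepl("NTC", u) ~ "NTC",
    grepl("UNKNOWN|UNKN", u) ~ "UNKNOWN",
    u == "" ~ "UNKNOWN",
    TRUE ~ "OTHER"
  )
}

.split_line <- function(line, sep) {
  scan(text = line, what = character(), sep = sep, quote = "\"",
       quiet = TRUE, strip.white = TRUE, blank.lines.skip = FALSE)
}

.detect_sep <- function(lines, delimiter) {
  if (delimiter == "csv") return(",")
  if (delimiter == "tab") return("\t")
  # auto: whichever separator is more frequent across candidate lines
  if (sum(grepl("\t", lines)) >= sum(grepl(",", lines))) "\t" else ","
}

#' Read a thermocycler results export
#'
#' Reads a delimited (comma or tab) results table, skipping any metadata
#' preamble: the first line whose cells match all mandatory canonical fields
#' (well, sample, target, ct) is taken as the header. CT cells that are empty
#' or a sentinel ("Undetermined", "N/A") become `NA` ("missing") with a
#' warning; they are excluded from replicate groups downstream.
#'
#' @param path Path to a csv/txt export.
#' @param delimiter One of "auto", "csv", "tab".
#' @param overrides Optional column-name overrides, see [map_columns()].
#' @return A tibble of well records (one row per well) with columns `well`,
#'   `sample_name`, `target_name`, `task`, `ct`, `quantity`, `group`,
#'   `source_file`, and attributes `column_map` and
#'   `n_skipped_preamble_lines`.
#' @export
read_results_table <- function(path, delimiter = c("auto", "csv", "tab"),
                               overrides = NULL) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readr::read_lines(path)
  sep <- .detect_sep(lines, delimiter)

  # locate header: first line matching every mandatory field
  header_idx <- NA_integer_
  cmap <- NULL
  for (i in seq_along(lines)) {
    cells <- tryCatch(.split_line(lines[i], sep), error = function(e) character(0))
    if (length(cells) < length(.mandatory_fields)) next
    cmap_try <- tryCatch(map_columns(cells, overrides), error = function(e) NULL)
    if (!is.null(cmap_try)) { header_idx <- i; cmap <- cmap_try; break }
  }
  if (is.na(header_idx)) {
    # rerun on the most plausible line to surface the informative error
    widths <- vapply(lines, function(l) length(.split_line(l, sep)), integer(1))
    best <- if (length(widths)) which.max(widths) else 1L
    map_columns(.split_line(lines[best], sep), overrides)
    stop("no header line matches all mandatory fields", call. = FALSE)
  }

  body <- lines[-seq_len(header_idx)]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_lineno <- (header_idx + seq_along(keep))[keep]

  if (length(body) == 0) {
    df <- stats::setNames(
      as.data.frame(matrix(character(0), 0, length(cmap))), unname(cmap))
  } else {
    df <- utils::read.table(
      text = body, sep = sep, header = FALSE, quote = "\"",
      colClasses = "character", stringsAsFactors = FALSE,
      fill = TRUE, comment.char = "", strip.white = TRUE)
    hdr <- .split_line(lines[header_idx], sep)
    names(df)[seq_along(hdr)] <- hdr
  }

  get_col <- function(field) {
    if (field %in% names(cmap)) df[[cmap[[field]]]] else NULL
  }

  n <- nrow(df)
  task_raw <- get_col("task")
  if (is.null(task_raw) && n > 0) {
    warning(sprintf("%s: no Task column found; all wells treated as UNKNOWN",
                    basename(path)), call. = FALSE)
  }
  qty_raw <- get_col("quantity")
  quantity <- rep(NA_real_, n)
  if (!is.null(qty_raw)) {
    quantity <- suppressWarnings(as.numeric(qty_raw))
    nonpos <- !is.na(quantity) & quantity <= 0
    if (any(nonpos)) {
      warning(sprintf("%s: %d non-positive quantity value(s) treated as absent",
                      basename(path), sum(nonpos)), call. = FALSE)
      quantity[nonpos] <- NA_real_
    }
  }

  ct <- if (n > 0) .parse_ct(get_col("ct"), body_lineno) else numeric(0)
  n_missing <- sum(is.na(ct))
  if (n_missing > 0) {
    warning(sprintf("%s: %d well(s) with missing/undetermined CT", basename(path),
                    n_missing), call. = FALSE)
  }

  grp <- get_col("group")
  out <- tibble::tibble(
    well = if (n > 0) as.character(get_col("well")) else character(0),
    sample_name = if (n > 0) as.character(get_col("sample")) else character(0),
    target_name = if (n > 0) as.character(get_col("target")) else character(0),
    task = if (is.null(task_raw)) rep("UNKNOWN", n) else .parse_task(task_raw),
    ct = ct,
    quantity = quantity,
    group = if (is.null(grp)) rep(NA_character_, n) else as.character(grp),
    source_file = rep(basename(path), n)
  )
  attr(out, "column_map") <- cmap
  attr(out, "n_skipped_preamble_lines") <- header_idx - 1L
  out
}

#' Merge plate tables from several input files
#'
#' For the relative and stability models every record keeps a per-file
#' `partition` key so reference-gene normalization never crosses files (the
#' values of reference genes are calculated separately for each input file).
#' For the absolute model all files pool into one analysis set -- each gene
#' typically arrives in its own file and the endogenous controls apply across
#' all of them.
#'
#' @param tables List of tibbles from [read_results_table()] (or one tibble).
#' @param model One of "absolute", "relative_dct", "relative_ddct",
#'   "stability".
#' @return One combined tibble with an added `partition` column.
#' @export
merge_batches <- function(tables, model) {
  model <- match.arg(model, c("absolute", "relative_dct", "relative_ddct", "stability"))
  if (inherits(tables, "data.frame")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  combined <- dplyr::bind_rows(tables)
  dup <- duplicated(combined[, c("source_file", "well", "target_name")])
  if (any(dup)) {
    d <- combined[dup, ][1, ]
    stop(sprintf("duplicate well collision: well %s (target %s) appears twice in %s",
                 d$well, d$target_name, d$source_file), call. = FALSE)
  }
  combined$partition <- if (model == "absolute") "pooled" else combined$source_file
  combined
}
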