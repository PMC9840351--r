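# File formats: per-site call tables, BED intervals, sample sheets.
# All internal coordinates are 0-based, half-open; a CpG site occupies a
# single position `pos` (strand-collapsed, one record per CpG).

#' The 15 chromatin-state labels
#'
#' Vocabulary of the 15-state blood-cell chromatin segmentation used for
#' annotation labels (active/flanking/bivalent TSS, transcription,
#' enhancer classes, ZNF/repeats, heterochromatin, Polycomb-repressed and
#' quiescent states).
#'
#' @return Character vector of the 15 state abbreviations.
#' @export
#' @examples
#' chromatin_states()
chromatin_states <- function() {
  c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh",
    "ZNF/Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC",
    "ReprPCWk", "Quies")
}

.valid_marks <- c("mc", "hmc")

.stop_line <- function(line, msg) {
  stop(sprintf("malformed row at line %d: %s", line, msg), call. = FALSE)
}

.check_int <- function(x) grepl("^-?[0-9]+$", x)

#' Read a per-CpG site call table
#'
#' Reads per-site modification calls in one of two dialects:
#' \describe{
#'   \item{`tsv_freq`}{Tab-delimited with a header row and columns
#'     `chrom`, `pos`, `called_sites`, `called_modified` and (optionally)
#'     `modified_fraction`.  `pos` is the 0-based CpG position.}
#'   \item{`bedmethyl`}{Headerless bedMethyl-style BED: column 1 chromosome,
#'     column 2 the 0-based start (the CpG position), column 3 the exclusive
#'     end, column 10 the valid coverage and column 11 the percent modified
#'     (0--100), following the community bedMethyl layout.}
#' }
#' Records with `called_sites = 0` are retained with `modified_fraction`
#' set to `NA` (they carry no information and are excluded from all
#' downstream averages).
#'
#' @param path Path to the call table.
#' @param dialect `"tsv_freq"` or `"bedmethyl"`.
#' @param mark Modification mark carried by the table: `"mc"` (5-mC) or
#'   `"hmc"` (5-hmC).
#' @return A data.frame with columns `chrom`, `pos`, `mark`,
#'   `called_sites`, `called_modified`, `modified_fraction`.
#' @seealso [write_site_calls()]
#' @export
read_site_calls <- function(path, dialect = c("tsv_freq", "bedmethyl"),
                            mark = c("mc", "hmc")) {
  dialect <- match.arg(dialect)
  mark <- match.arg(mark)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv_freq") {
    raw <- read.delim(path, colClasses = "character", check.names = FALSE)
    req <- c("chrom", "pos", "called_sites", "called_modified")
    miss <- setdiff(req, names(raw))
    if (length(miss) > 0L)
      stop("tsv_freq file missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    n <- nrow(raw)
    if (n == 0L) {
      return(data.frame(chrom = character(), pos = integer(),
                        mark = character(), called_sites = integer(),
                        called_modified = integer(),
                        modified_fraction = numeric(),
                        stringsAsFactors = FALSE))
    }
    for (col in c("pos", "called_sites", "called_modified")) {
      bad <- which(!.check_int(raw[[col]]))
      if (length(bad) > 0L)
        .stop_line(bad[1L] + 1L, paste0("non-integer ", col))
    }
    pos <- as.integer(raw$pos)
    cs <- as.integer(raw$called_sites)
    cm <- as.integer(raw$called_modified)
    bad <- which(cm < 0L | cs < 0L | cm > cs)
    if (length(bad) > 0L)
      .stop_line(bad[1L] + 1L, "called_modified outside [0, called_sites]")
    frac <- ifelse(cs > 0L, cm / cs, NA_real_)
    if ("modified_fraction" %in% names(raw)) {
      stated <- suppressWarnings(as.numeric(raw$modified_fraction))
      chk <- which(cs > 0L & !is.na(stated) & abs(stated - frac) > 1e-9)
      if (length(chk) > 0L)
        .stop_line(chk[1L] + 1L,
                   "modified_fraction inconsistent with call counts")
    }
    out <- data.frame(chrom = raw$chrom, pos = pos, mark = mark,
                      called_sites = cs, called_modified = cm,
                      modified_fraction = frac, stringsAsFactors = FALSE)
  } else {
    raw <- tryCatch(
      read.delim(path, header = FALSE, colClasses = "character"),
      error = function(e) NULL)
    if (is.null(raw)) {
      return(data.frame(chrom = character(), pos = integer(),
                        mark = character(), called_sites = integer(),
                        called_modified = integer(),
                        modified_fraction = numeric(),
                        stringsAsFactors = FALSE))
    }
    if (ncol(raw) < 11L)
      stop("bedmethyl file needs at least 11 columns (got ", ncol(raw), ")",
           call. = FALSE)
    bad <- which(!.check_int(raw[[2L]]) | !.check_int(raw[[3L]]) |
                   !.check_int(raw[[10L]]))
    if (length(bad) > 0L)
      .stop_line(bad[1L], "non-integer coordinate or coverage")
    s <- as.integer(raw[[2L]]); e <- as.integer(raw[[3L]])
    if (any(e <= s)) .stop_line(which(e <= s)[1L], "end <= start")
    pct <- suppressWarnings(as.numeric(raw[[11L]]))
    bad <- which(is.na(pct) | pct < 0 | pct > 100)
    if (length(bad) > 0L)
      .stop_line(bad[1L], "percent modified outside [0, 100]")
    cs <- as.integer(raw[[10L]])
    cm <- as.integer(round(cs * pct / 100))
    out <- data.frame(chrom = raw[[1L]], pos = s, mark = mark,
                      called_sites = cs, called_modified = cm,
                      modified_fraction = ifelse(cs > 0L, cm / cs, NA_real_),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Write a per-CpG site call table (tsv_freq dialect)
#'
#' Writes the five-column tab-delimited dialect read by
#' [read_site_calls()].  `modified_fraction` is re-derived from the call
#' counts so write/read round-trips are exact.
#'
#' @param x Data.frame of site calls (as returned by [read_site_calls()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_site_calls <- function(x, path) {
  stopifnot(all(c("chrom", "pos", "called_sites", "called_modified")
                %in% names(x)))
  frac <- ifelse(x$called_sites > 0L,
                 sprintf("%.10g", x$called_modified / x$called_sites), "NA")
  out <- data.frame(chrom = x$chrom, pos = x$pos,
                    called_sites = x$called_sites,
                    called_modified = x$called_modified,
                    modified_fraction = frac, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' Reads a 3+ column BED file.  Coordinates are 0-based half-open, as in
#' the BED standard: an interval `[start, end)` contains positions
#' `start, ..., end - 1`.  Overlapping intervals are retained unmerged.
#'
#' @param path Path to the BED file.
#' @return Data.frame with columns `chrom`, `start`, `end`, `name`
#'   (`"."` when absent).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(read.delim(path, header = FALSE, colClasses = "character"),
                  error = function(e) NULL)
  if (is.null(raw)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(raw) < 3L)
    stop("BED file needs at least 3 columns", call. = FALSE)
  bad <- which(!.check_int(raw[[2L]]) | !.check_int(raw[[3L]]))
  if (length(bad) > 0L)
    .stop_line(bad[1L], "non-integer coordinates")
  s <- as.integer(raw[[2L]]); e <- as.integer(raw[[3L]])
  bad <- which(s >= e)
  if (length(bad) > 0L)
    .stop_line(bad[1L], sprintf("degenerate interval (start %d >= end %d)",
                                s[bad[1L]], e[bad[1L]]))
  name <- if (ncol(raw) >= 4L) raw[[4L]] else rep(".", nrow(raw))
  data.frame(chrom = raw[[1L]], start = s, end = e, name = name,
             stringsAsFactors = FALSE)
}

#' Read a chromatin-state annotation BED
#'
#' BED4 where column 4 carries the chromatin-state label.  Labels are
#' validated against a vocabulary (the 15-state abbreviations by default).
#'
#' @param path Path to the BED file.
#' @param cell_type Cell type the annotation track describes (e.g. "PBMC").
#' @param vocabulary Allowed labels; `NULL` disables validation.
#' @return Data.frame with columns `chrom`, `start`, `end`, `label`,
#'   `cell_type`.
#' @export
read_annotations <- function(path, cell_type,
                             vocabulary = chromatin_states()) {
  bed <- read_bed(path)
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(bed$name), vocabulary)
    if (length(bad) > 0L)
      stop("unknown chromatin-state label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             label = bed$name, cell_type = cell_type,
             stringsAsFactors = FALSE)
}

#' Read a transcription-factor binding-site BED
#'
#' BED4 where column 4 carries the transcription factor name.
#'
#' @param path Path to the BED file.
#' @return Data.frame with columns `chrom`, `start`, `end`, `tf_name`.
#' @export
read_tf_sites <- function(path) {
  bed <- read_bed(path)
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             tf_name = bed$name, stringsAsFactors = FALSE)
}

#' Write intervals as BED4
#'
#' @param x Data.frame with `chrom`, `start`, `end` and a name column
#'   (`label`, `tf_name` or `name`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  name_col <- intersect(c("label", "tf_name", "name"), names(x))[1L]
  if (is.na(name_col)) stop("no name column found", call. = FALSE)
  out <- data.frame(x$chrom, x$start, x$end, x[[name_col]])
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `mutation_status` (`carrier`/`control`),
#' `lymphoma_status` (`affected`/`unaffected`) and `timepoint_months`.
#' In strict mode timepoints must be 0, 6 or 12 (the study's sampling
#' design); `(sample_id, timepoint_months)` pairs must be unique.
#'
#' @param path Path to the CSV sample sheet.
#' @param strict Enforce timepoints in \{0, 6, 12\}.
#' @return Data.frame, one row per (sample, timepoint).
#' @export
read_sample_sheet <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character")
  req <- c("sample_id", "mutation_status", "lymphoma_status",
           "timepoint_months")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0L)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(raw$mutation_status), c("carrier", "control"))
  if (length(bad) > 0L)
    stop("unknown mutation_status token(s): ", paste(bad, collapse = ", "),
         "; allowed: carrier, control", call. = FALSE)
  bad <- setdiff(unique(raw$lymphoma_status), c("affected", "unaffected"))
  if (length(bad) > 0L)
    stop("unknown lymphoma_status token(s): ", paste(bad, collapse = ", "),
         "; allowed: affected, unaffected", call. = FALSE)
  if (any(!.check_int(raw$timepoint_months)))
    stop("non-integer timepoint_months", call. = FALSE)
  tp <- as.integer(raw$timepoint_months)
  if (strict && any(!tp %in% c(0L, 6L, 12L)))
    stop("timepoint_months outside {0, 6, 12}: ",
         paste(unique(tp[!tp %in% c(0L, 6L, 12L)]), collapse = ", "),
         " (use strict = FALSE to allow)", call. = FALSE)
  key <- paste(raw$sample_id, tp)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, timepoint_months) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  data.frame(sample_id = raw$sample_id,
             mutation_status = raw$mutation_status,
             lymphoma_status = raw$lymphoma_status,
             timepoint_months = tp, stringsAsFactors = FALSE)
}

#' Write a sample sheet
#'
#' @param x Sample sheet data.frame (see [read_sample_sheet()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(x, path) {
  write.csv(x[, c("sample_id", "mutation_status", "lymphoma_status",
                  "timepoint_months")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
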