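# Expression matrix container, delimited-text and GDS SOFT readers,
# availability mask, complete/incomplete gene split.

#' Construct an ExpressionMatrix
#'
#' The central container of the package: an \eqn{N \times M} matrix of
#' expression values (genes in rows, samples in columns) in which missing
#' entries are encoded as `NA`.  Sample columns are numeric by default; a
#' column may be declared categorical, in which case its cells hold integer
#' codes into the column's level set.
#'
#' @param values Numeric matrix, genes x samples; `NA` marks a missing cell.
#'   For categorical columns the cells are integer codes (1-based) into the
#'   corresponding entry of `levels`.
#' @param gene_ids Character vector of row identifiers.  Duplicates are
#'   allowed (GEO probe tables contain them) but provoke a warning; all
#'   operations key on row index, never on id.
#' @param sample_ids Character vector of unique column identifiers.
#' @param attr_kinds Character vector, one of `"numeric"` or `"categorical"`
#'   per column.
#' @param levels List with one entry per column: `NULL` for numeric columns,
#'   a character vector of category labels for categorical ones.
#' @return An object of class `ExpressionMatrix` (a list with the fields
#'   above).
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              attr_kinds = NULL,
                              levels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  m <- ncol(values)
  if (n < 1L || m < 1L) {
    stop_si("ExpressionMatrix needs at least one gene and one sample",
            "invalid_input")
  }
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(m))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != n || length(sample_ids) != m) {
    stop_si("id vectors do not match matrix dimensions", "invalid_input")
  }
  if (anyDuplicated(gene_ids)) {
    warning("duplicate gene ids present; operations key on row index")
  }
  if (anyDuplicated(sample_ids)) {
    stop_si("sample ids must be unique", "invalid_input")
  }
  if (is.null(attr_kinds)) attr_kinds <- rep("numeric", m)
  if (!all(attr_kinds %in% c("numeric", "categorical"))) {
    stop_si("attr_kinds must be 'numeric' or 'categorical'", "invalid_input")
  }
  if (is.null(levels)) levels <- vector("list", m)
  for (j in seq_len(m)) {
    if (attr_kinds[j] == "categorical") {
      if (is.null(levels[[j]])) {
        stop_si(sprintf("categorical column %d has no level set", j),
                "invalid_input")
      }
      cj <- values[, j]
      ok <- is.na(cj) | (cj == round(cj) & cj >= 1 & cj <= length(levels[[j]]))
      if (!all(ok)) {
        stop_si(sprintf("categorical column %d holds codes outside its levels", j),
                "invalid_input")
      }
    }
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         attr_kinds = attr_kinds, levels = levels),
    class = "ExpressionMatrix"
  )
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  d <- dim(x$values)
  nmiss <- sum(is.na(x$values))
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, %d missing cells (%.2f%%)\n",
              d[1], d[2], nmiss, 100 * nmiss / prod(d)))
  ncat <- sum(x$attr_kinds == "categorical")
  if (ncat > 0) cat(sprintf("  %d categorical sample column(s)\n", ncat))
  invisible(x)
}

# internal condition helper: all package errors carry class
# "spectralimpute_error" plus a specific subclass
stop_si <- function(msg, subclass) {
  stop(errorCondition(msg,
                      class = c(paste0("si_", subclass),
                                "spectralimpute_error", "error", "condition")))
}

#' Read a delimited expression table
#'
#' Reads a genes-x-samples table whose first column holds gene identifiers
#' and whose header row (if present) holds sample identifiers.  Cells equal
#' to any of the `missing_markers` become missing (`NA`).  Any other cell
#' of a numeric column that does not parse as a finite real is a parse
#' error naming the offending cell.
#'
#' @param path Path to the file.
#' @param missing_markers Character vector of tokens treated as missing.
#' @param delimiter Single field-separator character.
#' @param header Logical; does the first line carry sample ids?
#' @param categorical Integer vector of sample-column positions (after the
#'   id column) to treat as categorical.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path,
                        missing_markers = c("?", "NA", "null", ""),
                        delimiter = "\t",
                        header = TRUE,
                        categorical = integer(0)) {
  if (!file.exists(path)) stop_si(paste0("file not found: ", path), "io")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
  if (length(lines) == 0L) stop_si("empty file", "parse")
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  start <- 1L
  if (header) {
    sample_ids <- fields[[1L]][-1L]
    start <- 2L
  } else {
    sample_ids <- paste0("s", seq_len(length(fields[[1L]]) - 1L))
  }
  m <- length(sample_ids)
  if (m < 1L) stop_si("no sample columns found", "parse")
  body <- fields[seq(start, length(fields))]
  n <- length(body)
  if (n < 1L) stop_si("no data rows found", "parse")
  gene_ids <- character(n)
  vals <- matrix(NA_real_, n, m)
  kinds <- rep("numeric", m)
  kinds[categorical] <- "categorical"
  cat_raw <- if (length(categorical)) matrix(NA_character_, n, m) else NULL
  for (r in seq_len(n)) {
    f <- body[[r]]
    line_no <- r + start - 1L
    if (length(f) != m + 1L) {
      stop_si(sprintf("line %d has %d fields, expected %d",
                      line_no, length(f), m + 1L), "parse")
    }
    gene_ids[r] <- f[1L]
    cells <- f[-1L]
    is_miss <- cells %in% missing_markers
    for (j in seq_len(m)) {
      if (is_miss[j]) next
      if (kinds[j] == "categorical") {
        cat_raw[r, j] <- cells[j]
      } else {
        v <- suppressWarnings(as.numeric(cells[j]))
        if (is.na(v) || !is.finite(v)) {
          stop_si(sprintf("cell (line %d, sample '%s'): cannot parse '%s' as numeric",
                          line_no, sample_ids[j], cells[j]), "parse")
        }
        vals[r, j] <- v
      }
    }
  }
  lv <- vector("list", m)
  for (j in categorical) {
    lv[[j]] <- sort(unique(cat_raw[!is.na(cat_raw[, j]), j]))
    vals[, j] <- match(cat_raw[, j], lv[[j]])
  }
  expression_matrix(vals, gene_ids, sample_ids, kinds, lv)
}

#' Write an expression table
#'
#' Inverse of [read_matrix()]: finite reals are written with 17 significant
#' digits so a read-back reproduces them bit-for-bit; categorical codes are
#' written as their labels; missing cells as `missing_marker`.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @param missing_marker Token written for missing cells.
#' @param delimiter Field separator.
#' @export
write_matrix <- function(m, path, missing_marker = "NA", delimiter = "\t") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  nr <- nrow(m$values)
  out <- character(nr + 1L)
  out[1L] <- paste(c("gene_id", m$sample_ids), collapse = delimiter)
  cells <- matrix(missing_marker, nr, ncol(m$values))
  for (j in seq_len(ncol(m$values))) {
    obs <- !is.na(m$values[, j])
    if (m$attr_kinds[j] == "categorical") {
      cells[obs, j] <- m$levels[[j]][m$values[obs, j]]
    } else {
      cells[obs, j] <- sprintf("%.17g", m$values[obs, j])
    }
  }
  for (r in seq_len(nr)) {
    out[r + 1L] <- paste(c(m$gene_ids[r], cells[r, ]), collapse = delimiter)
  }
  writeLines(out, path)
  invisible(path)
}

#' Availability mask
#'
#' Boolean matrix H with `h[i, j] = TRUE` exactly where cell (i, j) of the
#' expression matrix is observed.
#'
#' @param m An [expression_matrix()].
#' @return Logical matrix of the same shape.
#' @export
availability_mask <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  !is.na(m$values)
}

#' Split genes into complete and incomplete sets
#'
#' A gene is complete when every sample value is observed; incomplete when
#' at least one is missing.  The two index sets partition `1..N`.
#'
#' @param m An [expression_matrix()].
#' @param h Availability mask; computed from `m` when omitted.
#' @return List with integer vectors `complete` and `incomplete`.
#' @export
split_complete_incomplete <- function(m, h = availability_mask(m)) {
  stopifnot(all(dim(h) == dim(m$values)))
  full <- rowSums(h) == ncol(h)
  list(complete = which(full), incomplete = which(!full))
}

#' Read the data table of a GEO GDS SOFT file
#'
#' Parses only the `!dataset_table_begin` ... `!dataset_table_end` block of
#' a GDS-dialect SOFT file.  Rows are probes (ID_REF), columns the GSM
#' sample columns; `null` and empty cells become missing.
#'
#' @param path Path to an uncompressed (or gz; `readLines` transparently
#'   decompresses) SOFT file.
#' @param missing_markers Tokens treated as missing.
#' @return An [expression_matrix()].
#' @export
read_gds_soft <- function(path, missing_markers = c("null", "NA", "")) {
  if (!file.exists(path)) stop_si(paste0("file not found: ", path), "io")
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!dataset_table_begin", lines)
  end <- grep("^!dataset_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop_si("no !dataset_table_begin/!dataset_table_end block found", "format")
  }
  tab <- lines[(beg + 1L):(end - 1L)]
  hdr <- strsplit(tab[1L], "\t", fixed = TRUE)[[1L]]
  gsm <- grep("^GSM", hdr)
  if (length(gsm) == 0L) stop_si("no GSM sample columns in table header", "format")
  idc <- which(hdr == "ID_REF")
  if (length(idc) == 0L) idc <- 1L
  body <- strsplit(tab[-1L], "\t", fixed = TRUE)
  n <- length(body)
  vals <- matrix(NA_real_, n, length(gsm))
  ids <- character(n)
  for (r in seq_len(n)) {
    f <- body[[r]]
    ids[r] <- f[idc[1L]]
    cells <- f[gsm]
    cells[is.na(cells)] <- ""          # short rows: trailing fields absent
    keep <- !(cells %in% missing_markers)
    v <- suppressWarnings(as.numeric(cells[keep]))
    vals[r, keep] <- v                  # unparseable -> NA (SOFT is permissive)
  }
  suppressWarnings(expression_matrix(vals, ids, hdr[gsm]))
}
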