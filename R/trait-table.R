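#' Construct a trait table
#'
#' A trait table is a data frame of observations (species-level means or
#' individual measurements) with a designated species column and a log-state
#' flag per trait column. Columns flagged as logged hold values on the
#' `log_base` scale; raw values can be recovered with [raw_values()].
#'
#' @param data a data frame with one row per observation.
#' @param species_col name of the column holding species labels.
#' @param log_cols character vector of numeric columns to log-transform in
#'   place. Values must be strictly positive.
#' @param log_base base of the logarithm, 10 (default) or `exp(1)`.
#' @param id_col optional column of unique observation ids; row names are
#'   used when absent.
#' @return a `trait_table`: a data frame with attributes `species_col`,
#'   `log_flags` (named character, `"raw"` or `"log"`) and `log_base`.
#' @examples
#' tt <- trait_table(
#'   data.frame(species = c("a", "b"), esa = c(100, 200), fsa = c(10, 15)),
#'   species_col = "species", log_cols = c("esa", "fsa")
#' )
#' raw_values(tt, "esa")
#' @export
trait_table <- function(data, species_col = "species", log_cols = character(),
                        log_base = 10, id_col = NULL) {
  stopifnot(is.data.frame(data))
  if (!species_col %in% names(data)) {
    stop("species column '", species_col, "' not found in table", call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!is.null(id_col)) {
    if (!id_col %in% names(data)) {
      stop("id column '", id_col, "' not found", call. = FALSE)
    }
    ids <- as.character(data[[id_col]])
  } else {
    ids <- rownames(data)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate observation ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rownames(data) <- ids

  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  missing_lc <- setdiff(log_cols, names(data))
  if (length(missing_lc)) {
    stop("log_cols not present in table: ",
         paste(missing_lc, collapse = ", "), call. = FALSE)
  }
  for (cl in log_cols) {
    v <- data[[cl]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop("non-positive value in log column '", cl, "' at row(s) ",
           paste(rownames(data)[bad], collapse = ", "),
           "; cannot log-transform", call. = FALSE)
    }
    data[[cl]] <- log(v, base = log_base)
  }
  flags <- stats::setNames(rep("raw", length(num_cols)), num_cols)
  flags[log_cols] <- "log"

  structure(data,
            species_col = species_col,
            log_flags = flags,
            log_base = log_base,
            class = c("trait_table", "data.frame"))
}

#' Read a trait table from delimited text
#'
#' Reads a CSV or TSV file (delimiter inferred from the extension, or set
#' explicitly) with a header row, and builds a [trait_table()]. Columns named
#' in `log_cols` are log-transformed on read and flagged; rows with missing
#' values are retained (models drop them per-fit, reporting the n used).
#'
#' @inheritParams trait_table
#' @param path path to a delimited text file with a header row.
#' @param sep field delimiter; guessed from the file extension when `NULL`.
#' @return a `trait_table`.
#' @export
read_trait_table <- function(path, species_col = "species",
                             log_cols = character(), log_base = 10,
                             id_col = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  trait_table(raw, species_col = species_col, log_cols = log_cols,
              log_base = log_base, id_col = id_col)
}

#' @export
print.trait_table <- function(x, ...) {
  flags <- attr(x, "log_flags")
  logged <- names(flags)[flags == "log"]
  cat("Trait table: ", nrow(x), " observations, ",
      length(unique(species_of(x))), " species\n", sep = "")
  if (length(logged)) {
    cat("Log-", format(attr(x, "log_base")), " columns: ",
        paste(logged, collapse = ", "), "\n", sep = "")
  }
  print(as.data.frame(utils::head(x, 10)))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Species labels of a trait table
#' @param table a `trait_table`.
#' @return character vector, one label per row.
#' @export
species_of <- function(table) {
  as.character(table[[attr(table, "species_col")]])
}

#' Recover raw-scale values of a trait column
#'
#' Back-transforms a log-flagged column to the raw measurement scale;
#' raw-flagged columns are returned unchanged.
#'
#' @param table a `trait_table`.
#' @param col a column name.
#' @return numeric vector on the raw scale.
#' @export
raw_values <- function(table, col) {
  if (!col %in% names(table)) stop("column '", col, "' not found", call. = FALSE)
  v <- table[[col]]
  flags <- attr(table, "log_flags")
  if (!is.null(flags) && identical(unname(flags[col]), "log")) {
    attr(table, "log_base")^v
  } else {
    v
  }
}

#' Log-scale values of a trait column
#'
#' Returns the column on the log scale of the table's `log_base`, logging a
#' raw-flagged column on the fly (values must then be positive).
#'
#' @inheritParams raw_values
#' @return numeric vector on the log scale.
#' @export
log_values <- function(table, col) {
  if (!col %in% names(table)) stop("column '", col, "' not found", call. = FALSE)
  v <- table[[col]]
  flags <- attr(table, "log_flags")
  if (!is.null(flags) && identical(unname(flags[col]), "log")) return(v)
  if (any(v <= 0, na.rm = TRUE)) {
    stop("column '", col, "' has non-positive values; cannot log", call. = FALSE)
  }
  log(v, base = attr(table, "log_base") %||% 10)
}

# keep trait_table attributes through [ subsetting
#' @export
`[.trait_table` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "species_col") <- attr(x, "species_col")
    fl <- attr(x, "log_flags")
    attr(out, "log_flags") <- fl[names(fl) %in% names(out)]
    attr(out, "log_base") <- attr(x, "log_base")
    class(out) <- c("trait_table", "data.frame")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
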