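#' Construct an abundance table
#'
#' An abundance table is a tibble with a `sample_id` column followed by one
#' numeric column per OTU, carrying a `kind` attribute that records whether
#' the values are read counts, relative abundances (per-sample proportions)
#' or absolute abundances (cells per volume, i.e. proportions scaled by a
#' total-density estimate). Samples are always rows; a file whose rows are
#' OTUs must be read with an explicit orientation flag (see
#' [read_abundance_table()]) — orientation is declared, never guessed.
#'
#' @param x A matrix with sample row names and OTU column names, or a data
#'   frame containing a `sample_id` column plus numeric OTU columns.
#' @param kind One of `"counts"`, `"relative"`, `"absolute"`.
#' @return A tibble of class `abund_tbl` with attribute `kind`.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2")))
#' abundance_table(m, "counts")
#' @export
abundance_table <- function(x, kind = c("counts", "relative", "absolute")) {
  kind <- match.arg(kind)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("matrix input must have sample row names and OTU column names",
           call. = FALSE)
    }
    df <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
    df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), df)
  } else {
    df <- tibble::as_tibble(x)
    if (!"sample_id" %in% names(df)) {
      stop("data frame input must contain a `sample_id` column", call. = FALSE)
    }
    df <- dplyr::relocate(df, "sample_id")
  }
  validate_abundance(df, kind)
  new_abund_tbl(df, kind)
}

new_abund_tbl <- function(df, kind) {
  structure(df,
            class = c("abund_tbl", "tbl_df", "tbl", "data.frame"),
            kind = kind)
}

validate_abundance <- function(df, kind) {
  sid <- df$sample_id
  oid <- setdiff(names(df), "sample_id")
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(oid)) {
    stop("duplicate OTU ids: ",
         paste(unique(oid[duplicated(oid)]), collapse = ", "), call. = FALSE)
  }
  for (j in oid) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      stop("non-numeric abundance column: ", j, call. = FALSE)
    }
    bad <- which(!is.na(v) & v < 0)
    if (length(bad)) {
      stop(sprintf("negative abundance at sample '%s', OTU '%s'",
                   sid[bad[1]], j), call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing abundance value in column: ", j, call. = FALSE)
    }
  }
  if (kind == "relative") {
    rs <- rowSums(as.matrix(df[oid]))
    if (any(rs > 1 + 1e-9)) {
      stop("relative abundance rows must sum to at most 1", call. = FALSE)
    }
  }
  invisible(df)
}

#' Abundance-table accessors
#'
#' `abundance_kind()` returns the `kind` attribute; `abund_matrix()` returns
#' the numeric samples-by-OTUs matrix with sample ids as row names;
#' `otu_ids()` and `sample_ids()` return the id vectors in table order.
#'
#' @param x An `abund_tbl`.
#' @return See description.
#' @export
abundance_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) "counts" else k
}

#' @rdname abundance_kind
#' @export
abund_matrix <- function(x) {
  oid <- setdiff(names(x), "sample_id")
  m <- as.matrix(as.data.frame(x)[oid])
  rownames(m) <- x$sample_id
  m
}

#' @rdname abundance_kind
#' @export
otu_ids <- function(x) setdiff(names(x), "sample_id")

#' @rdname abundance_kind
#' @export
sample_ids <- function(x) x$sample_id

#' @export
print.abund_tbl <- function(x, ...) {
  cat(sprintf("# Abundance table (%s): %d samples x %d OTUs\n",
              abundance_kind(x), nrow(x), length(otu_ids(x))))
  NextMethod()
}

#' Keep a subset of OTU columns
#'
#' @param x An `abund_tbl`.
#' @param ids Character vector of OTU ids to keep (order preserved from `x`).
#' @return An `abund_tbl` of the same kind.
#' @export
keep_otus <- function(x, ids) {
  missing <- setdiff(ids, otu_ids(x))
  if (length(missing)) {
    stop("unknown OTU ids: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(otu_ids(x), ids)
  new_abund_tbl(dplyr::select(tibble::as_tibble(x), "sample_id",
                              dplyr::all_of(keep)),
                abundance_kind(x))
}

detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Read an abundance table from delimited text
#'
#' Reads a TSV or CSV file with one header row of ids and one id column.
#' The delimiter is auto-detected between tab and comma unless given.
#' Values are validated to be numeric and non-negative; errors name the
#' offending cell.
#'
#' @param path File path.
#' @param orientation `"samples_rows"` (default) if rows are samples,
#'   `"otus_rows"` if rows are OTUs (the table is transposed on read).
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @return An `abund_tbl` with `kind = "counts"`.
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_rows", "otus_rows"),
                                 delim = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  id_col <- names(raw)[1]
  row_ids <- raw[[id_col]]
  if (anyDuplicated(row_ids)) {
    stop("duplicate row ids in ", path, call. = FALSE)
  }
  if (anyDuplicated(names(raw)[-1])) {
    stop("duplicate column ids in ", path, call. = FALSE)
  }
  vals <- as.data.frame(raw[-1])
  for (j in names(vals)) {
    num <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(num) & !is.na(vals[[j]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   vals[[j]][bad[1]], row_ids[bad[1]], j), call. = FALSE)
    }
    neg <- which(num < 0)
    if (length(neg)) {
      stop(sprintf("negative value at row '%s', column '%s'",
                   row_ids[neg[1]], j), call. = FALSE)
    }
    vals[[j]] <- num
  }
  m <- as.matrix(vals)
  rownames(m) <- row_ids
  if (orientation == "otus_rows") m <- t(m)
  abundance_table(m, "counts")
}

#' Write an abundance table to delimited text
#'
#' Samples are written as rows with a leading `sample_id` column. The `kind`
#' attribute is not stored in the file; [read_abundance_table()] always
#' returns `kind = "counts"`, so re-tag relative/absolute tables after
#' reading if needed.
#'
#' @param x An `abund_tbl`.
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, delim = "\t") {
  readr::write_delim(tibble::as_tibble(x), path, delim = delim)
  invisible(path)
}

#' Current selection regime of a sample
#'
#' Microcosms in the RK group are r-selected (pulse feeding) up to and
#' including day 28 and K-selected (continuous feeding) from day 29 on;
#' KR microcosms are the mirror image. The regime is a pure function of the
#' selection group and the sampling day, with the switch strictly between
#' days 28 and 29.
#'
#' @param selection_group Character vector of `"RK"` / `"KR"`.
#' @param day Integer vector of sampling days (>= 1).
#' @return Character vector of `"r"` / `"K"`.
#' @examples
#' current_regime(c("RK", "RK", "KR"), c(28, 29, 1))
#' @export
current_regime <- function(selection_group, day) {
  stopifnot(all(selection_group %in% c("RK", "KR")), all(day >= 1))
  letter <- ifelse(day <= 28,
                   substr(selection_group, 1, 1),
                   substr(selection_group, 2, 2))
  ifelse(letter == "R", "r", "K")
}

#' Add the derived current_regime column to sample metadata
#'
#' @param metadata A tibble with columns `selection_group` and `day`.
#' @return The tibble with a `current_regime` column (`"r"`/`"K"`).
#' @export
add_current_regime <- function(metadata) {
  dplyr::mutate(metadata,
                current_regime = current_regime(.data$selection_group,
                                                .data$day))
}

validate_metadata <- function(meta) {
  need <- c("sample_id", "microcosm_id", "day", "selection_group",
            "resource_supply", "replicate")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("metadata missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(meta$selection_group), c("RK", "KR"))
  if (length(bad_group)) {
    stop("unknown selection_group token: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  bad_supply <- setdiff(unique(meta$resource_supply), c("H", "L"))
  if (length(bad_supply)) {
    stop("unknown resource_supply token: ", paste(bad_supply, collapse = ", "),
         call. = FALSE)
  }
  if (any(meta$day < 1 | meta$day != as.integer(meta$day))) {
    stop("day must be a positive integer", call. = FALSE)
  }
  if (!all(meta$replicate %in% 1:3)) {
    stop("replicate must be 1, 2 or 3", call. = FALSE)
  }
  key <- paste(meta$microcosm_id, meta$day)
  if (anyDuplicated(key)) {
    stop("duplicate (microcosm_id, day) pair: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  invisible(meta)
}

#' Read per-sample metadata
#'
#' Expects columns `sample_id`, `microcosm_id`, `day`, `selection_group`
#' (RK/KR), `resource_supply` (H/L) and `replicate` (1-3). Unknown enum
#' tokens and duplicate (microcosm, day) pairs are hard errors. A complete
#' factorial design is not required: missing (microcosm, day) combinations
#' are tolerated.
#'
#' @param path File path (TSV or CSV, delimiter auto-detected).
#' @param delim Optional explicit delimiter.
#' @return A tibble with the metadata columns plus derived `current_regime`.
#' @export
read_sample_metadata <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  meta <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    sample_id = readr::col_character(),
    microcosm_id = readr::col_character(),
    day = readr::col_integer(),
    selection_group = readr::col_character(),
    resource_supply = readr::col_character(),
    replicate = readr::col_integer()), progress = FALSE)
  validate_metadata(meta)
  add_current_regime(meta)
}

#' Read a per-sample total cell density table
#'
#' @param path File path with columns `sample_id` and `density`
#'   (cells per volume, flow-cytometry-style totals).
#' @param delim Optional explicit delimiter.
#' @return A tibble with columns `sample_id`, `density`.
#' @export
read_density_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  d <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    sample_id = readr::col_character(),
    density = readr::col_double()), progress = FALSE)
  if (any(d$density <= 0)) stop("densities must be positive", call. = FALSE)
  d
}

#' Read an OTU taxonomy table
#'
#' First column must be `otu_id`; remaining columns are ranked labels
#' (e.g. domain ... genus). Any rank may be missing for an OTU.
#'
#' @param path File path.
#' @param delim Optional explicit delimiter.
#' @return A tibble keyed by `otu_id`.
#' @export
read_taxonomy_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  tax <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (names(tax)[1] != "otu_id") {
    stop("taxonomy table must have `otu_id` as first column", call. = FALSE)
  }
  if (anyDuplicated(tax$otu_id)) {
    stop("duplicate otu_id in taxonomy table", call. = FALSE)
  }
  tax
}
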