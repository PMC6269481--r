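#' Read a feature-by-sample expression matrix
#'
#' Reads a tab-separated expression matrix with feature identifiers in the
#' first column and sample identifiers in the first (header) row.  Values are
#' expected to be already-normalized, log-scale expression; the reader is
#' strict: duplicate identifiers, missing cells and non-numeric cells are
#' load errors, never silently coerced or imputed (the downstream rank
#' transform is undefined on missing data).
#'
#' Identifiers are trimmed of surrounding whitespace and matched
#' case-sensitively everywhere in the package.
#'
#' @param path Path to a tab-separated text file.  The header row may carry
#'   either one field per sample or an extra leading label for the
#'   feature-id column.
#' @param transpose If `TRUE`, the file is read with samples in rows and
#'   features in columns and transposed on load.
#' @return A numeric matrix (features x samples) with unique `rownames`
#'   (feature ids) and `colnames` (sample ids).
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  header <- trimws(strsplit(readLines(path, n = 1L, encoding = "UTF-8",
                                      warn = FALSE), "\t", fixed = TRUE)[[1L]])
  body <- utils::read.delim(path, header = FALSE, sep = "\t", skip = 1L,
                            colClasses = "character", quote = "",
                            comment.char = "", blank.lines.skip = TRUE)
  if (nrow(body) < 2L)
    stop("expression matrix needs a header row and at least 2 feature rows: ", path)
  feature_ids <- trimws(body[[1L]])
  n_fields <- ncol(body)
  # header may or may not carry a corner label over the feature-id column
  sample_ids <- if (length(header) == n_fields) header[-1L]
                else if (length(header) == n_fields - 1L) header
                else stop("header has ", length(header), " fields but data rows have ",
                          n_fields, " in ", path)
  .check_unique(feature_ids, "feature id")
  .check_unique(sample_ids, "sample id")
  values <- matrix(NA_real_, nrow = nrow(body), ncol = n_fields - 1L,
                   dimnames = list(feature_ids, sample_ids))
  for (j in seq_len(n_fields - 1L)) {
    cell <- trimws(body[[j + 1L]])
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.finite(num))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric or missing expression value at feature '%s', sample '%s' (value '%s')",
        feature_ids[bad[1L]], sample_ids[j], cell[bad[1L]]))
    }
    values[, j] <- num
  }
  if (transpose) {
    values <- t(values)
  }
  validate_expression_matrix(values)
  values
}

#' Write an expression matrix to tab-separated text
#'
#' @param mat Numeric matrix with feature-id rownames and sample-id colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  validate_expression_matrix(mat)
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate an expression matrix
#'
#' Enforces the container invariants assumed by every downstream operation:
#' a finite numeric matrix with unique row (feature) and column (sample)
#' identifiers, at least 2 features and at least 1 sample.
#'
#' @param mat Object to validate.
#' @return `mat`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must carry feature rownames and sample colnames")
  if (nrow(mat) < 2L) stop("expression matrix needs at least 2 features")
  if (ncol(mat) < 1L) stop("expression matrix needs at least 1 sample")
  .check_unique(rownames(mat), "feature id")
  .check_unique(colnames(mat), "sample id")
  if (!all(is.finite(mat)))
    stop("expression matrix contains non-finite or missing values")
  invisible(mat)
}

.check_unique <- function(ids, what) {
  if (any(ids == "")) stop("empty ", what, " not allowed")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s: %s", what, paste(dup, collapse = ", ")))
  invisible(ids)
}

#' Construct a directional signature
#'
#' A directional signature is a named pair of disjoint feature-id sets:
#' members expected high ("up") and members expected low ("down") in the
#' phenotype the signature describes.
#'
#' @param up,down Character vectors of feature ids (either may be empty, not
#'   both).  Duplicates are dropped; ids are whitespace-trimmed.
#' @param name Signature name.
#' @return An object of class `directional_signature` with elements `name`,
#'   `up` and `down`.
#' @export
directional_signature <- function(up = character(), down = character(),
                                  name = "signature") {
  up <- unique(trimws(as.character(up)))
  down <- unique(trimws(as.character(down)))
  up <- up[up != ""]
  down <- down[down != ""]
  both <- intersect(up, down)
  if (length(both))
    stop("features listed in both directions: ", paste(both, collapse = ", "))
  if (!length(up) && !length(down))
    stop("signature must have at least one member")
  structure(list(name = as.character(name)[1L], up = up, down = down),
            class = "directional_signature")
}

#' @export
print.directional_signature <- function(x, ...) {
  cat(sprintf("Directional signature '%s': %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Read a directional signature from two-column TSV
#'
#' Expected format: tab-separated lines `feature_id<TAB>direction` with
#' direction `up` or `down`.  A header line `feature_id  direction` is
#' tolerated and skipped.
#'
#' @param path Path to the signature file.
#' @param name Name for the signature; defaults to the file name.
#' @return A [directional_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signature file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, trimws)
  if (tolower(fields[[1L]][1L]) == "feature_id") fields <- fields[-1L]
  if (!length(fields)) stop("signature file has no data rows: ", path)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop("signature line ", bad[1L], " does not have 2 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  dir <- tolower(vapply(fields, `[[`, "", 2L))
  unknown <- setdiff(unique(dir), c("up", "down"))
  if (length(unknown))
    stop("unknown direction token(s): ", paste(unknown, collapse = ", "),
         " (expected 'up' or 'down')")
  directional_signature(up = ids[dir == "up"], down = ids[dir == "down"],
                        name = if (is.null(name)) basename(path) else name)
}

#' Write a directional signature as two-column TSV
#'
#' @param sig A [directional_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "directional_signature"))
  df <- data.frame(
    feature_id = c(sig$up, sig$down),
    direction = c(rep("up", length(sig$up)), rep("down", length(sig$down))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged embryonic-stem-cell miRNA signature
#'
#' Loads the 60-member directional ESC miRNA signature shipped with the
#' package (33 miRNAs up-regulated and 27 down-regulated in embryonic stem
#' cells relative to differentiated tissue, including the full miR-302/367
#' cluster among the up members and the let-7 family among the down
#' members).  High rank-sum scores against this signature mark samples with
#' an ESC-like expression state.
#'
#' @return A [directional_signature()] with 33 up and 27 down members.
#' @examples
#' sig <- esc_mirna_signature()
#' length(sig$up) + length(sig$down)  # 60
#' @export
esc_mirna_signature <- function() {
  path <- system.file("extdata", "esc_mirna_signature.tsv",
                      package = "stemscore", mustWork = TRUE)
  read_signature(path, name = "ESC_miRNA_signature")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.  The description field
#' is discarded.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- lapply(strsplit(lines, "\t", fixed = TRUE), trimws)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields (name, description, members)")
  nm <- vapply(fields, `[[`, "", 1L)
  .check_unique(nm, "gene-set name")
  sets <- lapply(fields, function(f) unique(f[-(1:2)][f[-(1:2)] != ""]))
  names(sets) <- nm
  empty <- nm[vapply(sets, length, 1L) == 0L]
  if (length(empty)) stop("empty gene set(s): ", paste(empty, collapse = ", "))
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled `"na"` by default).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  .check_unique(names(sets), "gene-set name")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    if (!length(members)) stop("empty gene set: ", nm)
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.clinical_columns <- c("sample_id", "os_time", "os_event",
                       "mycn_amplified", "stage4", "age_ge_1y")

#' Read a clinical annotation table
#'
#' Tab-separated table with a header naming the six fields `sample_id`,
#' `os_time` (overall-survival time in years), `os_event` (1 = dead of
#' disease, 0 = censored), and the binary risk covariates `mycn_amplified`,
#' `stage4` (stage 4 vs other stage) and `age_ge_1y` (age at diagnosis at or
#' above 1 year).  Empty strings encode missing covariates; survival time
#' and event status must be present and valid for every sample.
#'
#' @param path Path to the clinical TSV.
#' @return A `data.frame` with the six validated columns.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  names(df) <- trimws(names(df))
  missing_cols <- setdiff(.clinical_columns, names(df))
  if (length(missing_cols))
    stop("clinical table missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, .clinical_columns]
  df[] <- lapply(df, trimws)
  out <- data.frame(
    sample_id = df$sample_id,
    os_time = suppressWarnings(as.numeric(df$os_time)),
    os_event = suppressWarnings(as.integer(df$os_event)),
    mycn_amplified = .parse_binary(df$mycn_amplified, "mycn_amplified"),
    stage4 = .parse_binary(df$stage4, "stage4"),
    age_ge_1y = .parse_binary(df$age_ge_1y, "age_ge_1y"),
    stringsAsFactors = FALSE)
  validate_clinical_table(out)
  out
}

.parse_binary <- function(x, what) {
  out <- rep(NA_integer_, length(x))
  filled <- !is.na(x) & x != ""
  val <- suppressWarnings(as.integer(x[filled]))
  if (any(is.na(val) | !(val %in% c(0L, 1L))))
    stop(what, " must be 0, 1 or empty (missing)")
  out[filled] <- val
  out
}

#' Validate a clinical table
#'
#' @param clinical A `data.frame` with the six clinical columns.
#' @return `clinical`, invisibly, if valid.
#' @export
validate_clinical_table <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  missing_cols <- setdiff(.clinical_columns, names(clinical))
  if (length(missing_cols))
    stop("clinical table missing column(s): ", paste(missing_cols, collapse = ", "))
  .check_unique(clinical$sample_id, "sample id")
  if (any(!is.finite(clinical$os_time)))
    stop("os_time must be a finite number for every sample")
  if (any(clinical$os_time < 0)) stop("negative os_time not allowed")
  if (any(is.na(clinical$os_event)) || !all(clinical$os_event %in% c(0L, 1L)))
    stop("os_event must be 0 or 1 for every sample")
  for (cov in c("mycn_amplified", "stage4", "age_ge_1y")) {
    v <- clinical[[cov]]
    if (!all(is.na(v) | v %in% c(0L, 1L)))
      stop(cov, " must be 0, 1 or missing")
  }
  invisible(clinical)
}

#' Write a clinical table to TSV
#'
#' Missing covariates are written as empty strings.
#'
#' @param clinical Validated clinical `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  validate_clinical_table(clinical)
  out <- clinical[, .clinical_columns]
  for (cov in c("mycn_amplified", "stage4", "age_ge_1y")) {
    out[[cov]] <- ifelse(is.na(out[[cov]]), "", as.character(out[[cov]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}
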