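#' Read positive-test counts from JSON or TSV
#'
#' JSON input is an object `{"m": int, "S": int, "s_star": [int, ...]}`.
#' TSV input is a two-column table (`perm_index`, `count`) holding only the
#' permuted counts, in which case `m` and `S` must be supplied.
#'
#' @param path File path; format detected from the `.json` extension (or a
#'   leading `{`), otherwise TSV.
#' @param m,S Totals required for TSV input; ignored for JSON.
#' @return A [positive_counts()] object.
#' @export
read_counts <- function(path, m = NULL, S = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE) ||
    grepl("^\\s*\\{", first)
  if (is_json) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (fld in c("m", "S", "s_star")) {
      if (is.null(obj[[fld]])) {
        stop("counts JSON is missing field `", fld, "`", call. = FALSE)
      }
    }
    positive_counts(obj$m, obj$S, obj$s_star)
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t")
    if (ncol(tab) < 2L) {
      stop("counts TSV must have two columns (perm_index, count)",
           call. = FALSE)
    }
    if (is.null(m) || is.null(S)) {
      stop("TSV counts input requires `m` and `S`", call. = FALSE)
    }
    positive_counts(m, S, tab[[2L]])
  }
}

#' Write positive-test counts as JSON
#'
#' @param counts A [positive_counts()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- as_positive_counts(counts)
  jsonlite::write_json(
    list(m = counts$m, S = counts$S, s_star = counts$s_star),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Serialize an FDR estimate as a flat JSON record
#'
#' Full double precision; logical flags as JSON booleans.
#'
#' @param estimate An [estimate_full()] result.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_estimate_json <- function(estimate, path = NULL) {
  stopifnot(inherits(estimate, "fdr_estimate"))
  rec <- unclass(estimate)
  if (is.null(path)) {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
  }
}

#' Read a single-column p-value TSV (with header)
#'
#' @param path File path.
#' @return Numeric vector of p-values.
#' @export
read_pvalues <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t")
  as.numeric(tab[[1L]])
}

#' Read permuted p-values from a wide TSV or a directory
#'
#' A wide TSV has one header row and columns `perm_1 ... perm_B`; a
#' directory is read as one single-column TSV per permutation (sorted by
#' file name).
#'
#' @param path File or directory path.
#' @return Numeric matrix, m rows x B columns.
#' @export
read_permuted_pvalues <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    if (length(files) == 0L) stop("empty permutation directory: ", path,
                                  call. = FALSE)
    cols <- lapply(files, read_pvalues)
    lens <- lengths(cols)
    if (length(unique(lens)) != 1L) {
      bad <- which(lens != lens[1L])[1L]
      stop("permutation file ", basename(files[bad]), " has ", lens[bad],
           " rows; expected ", lens[1L], call. = FALSE)
    }
    matrix(unlist(cols), ncol = length(cols))
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    as.matrix(utils::read.delim(path, header = TRUE, sep = "\t"))
  }
}

#' Write an FDR table (or scenario summary) as TSV
#'
#' Tab-separated with a header row; numeric columns carry 15 significant
#' digits so a read-back reproduces values to working precision.
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(table, path) {
  out <- as.data.frame(table)
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE,
                                scientific = NA))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a TSV written by [write_table_tsv()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t")
}

#' Build a run manifest
#'
#' A small JSON-serializable record tying a run's outputs to its inputs:
#' command name, configuration echo, master seed, MD5 digests of input
#' files, package version, and a timestamp.
#'
#' @param command Subcommand or function name.
#' @param config List of configuration values (echoed verbatim).
#' @param seed Master seed used (or `NULL`).
#' @param inputs Character vector of input file paths to digest.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = list(), seed = NULL,
                         inputs = character()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    NULL
  }
  structure(
    list(
      command = command,
      config = config,
      seed = seed,
      input_digests = digests,
      package_version = as.character(utils::packageVersion("permfdr")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}
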