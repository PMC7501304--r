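#' RR-interval series
#'
#' Container for one patient's raw inter-beat (RR) intervals in
#' milliseconds, together with the patient identifier and clinical class
#' label. The class labels follow the usual Holter-cohort convention:
#' `"H"` (healthy), `"AF"` (atrial fibrillation), `"CD"` (cardiac
#' decompensation / congestive heart failure), or `"UNKNOWN"`.
#'
#' @param intervals numeric vector of strictly positive RR intervals (ms).
#' @param patient_id character scalar identifying the patient.
#' @param class_label one of `"H"`, `"AF"`, `"CD"`, `"UNKNOWN"`.
#'
#' @return An object of class `"rr_series"`: a list with elements
#'   `intervals`, `patient_id`, `class_label` and `n` (number of beats).
#' @examples
#' rr <- rr_series(c(800, 1000), "p1", "H")
#' rr$n
#' @export
rr_series <- function(intervals, patient_id = "unknown",
                      class_label = c("UNKNOWN", "H", "AF", "CD")) {
  class_label <- match.arg(toupper(class_label), c("UNKNOWN", "H", "AF", "CD"))
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L)
    stop("an RR series needs at least 2 beats, got ", length(intervals))
  if (anyNA(intervals) || any(!is.finite(intervals)))
    stop("RR intervals must be finite and non-missing")
  if (any(intervals <= 0))
    stop("RR intervals must be strictly positive (ms); offending index ",
         which(intervals <= 0)[1L])
  structure(
    list(intervals = intervals,
         patient_id = as.character(patient_id)[1L],
         class_label = class_label,
         n = length(intervals)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series '%s' [%s]: %d beats, mean %.1f ms, sd %.1f ms\n",
              x$patient_id, x$class_label, x$n,
              mean(x$intervals), stats::sd(x$intervals)))
  invisible(x)
}

#' Read an RR-interval file
#'
#' Reads a plain-text tachogram: one RR interval (milliseconds) per line,
#' lines starting with `#` ignored. This is the interchange format used
#' throughout the package, compatible with common tachogram exports.
#'
#' @param path path to the text file.
#' @param patient_id identifier to attach; defaults to the file stem.
#' @param class_label clinical class label (see [rr_series()]).
#'
#' @return An [rr_series()] object with intervals in file order.
#' @seealso [write_rr()] for the inverse operation.
#' @export
read_rr <- function(path, patient_id = NULL,
                    class_label = "UNKNOWN") {
  if (!file.exists(path)) stop("RR file not found: ", path)
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (length(vals) == 0L) stop("empty RR file: ", path)
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop("non-numeric RR interval at line ", bad, " of ", path)
  }
  if (any(vals <= 0)) {
    bad <- which(keep)[which(vals <= 0)[1L]]
    stop("nonpositive RR interval at line ", bad, " of ", path)
  }
  rr_series(vals, patient_id = patient_id, class_label = class_label)
}

#' Write an RR-interval file
#'
#' @param rr an [rr_series()] object (or numeric vector of intervals).
#' @param path output file path.
#' @param header optional comment line (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path, header = NULL) {
  vals <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  writeLines(format(vals, digits = 17, scientific = FALSE, trim = TRUE), con)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with header `patient_id,class,path` assigning each
#' patient file a clinical class. Paths are resolved relative to the
#' manifest's directory unless absolute.
#'
#' @param path manifest CSV path.
#' @param check_paths verify that every referenced RR file exists.
#' @return A `"dataset_manifest"`: data frame of records with attributes
#'   `class_counts` (named integer vector over H/AF/CD/UNKNOWN).
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "class", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  df$class <- toupper(df$class)
  bad <- setdiff(unique(df$class), c("H", "AF", "CD", "UNKNOWN"))
  if (length(bad))
    stop("unknown class token(s) in manifest: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in manifest: ",
         df$patient_id[anyDuplicated(df$patient_id)])
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  if (check_paths) {
    missing <- df$path[!file.exists(df$path)]
    if (length(missing))
      stop("manifest references missing file(s): ",
           paste(utils::head(missing, 3), collapse = ", "))
  }
  counts <- vapply(c(H = "H", AF = "AF", CD = "CD", UNKNOWN = "UNKNOWN"),
                   function(cl) sum(df$class == cl), integer(1))
  structure(df, class_counts = counts,
            class = c("dataset_manifest", "data.frame"))
}

#' Write a dataset manifest
#'
#' @param records data frame with columns `patient_id`, `class`, `path`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  utils::write.csv(records[, c("patient_id", "class", "path")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load every RR series of one class from a manifest
#'
#' @param manifest a `"dataset_manifest"` from [read_manifest()].
#' @param class_label class to select (`"H"`, `"AF"`, `"CD"`), or `NULL`
#'   for all records.
#' @return list of [rr_series()] objects.
#' @export
load_class_series <- function(manifest, class_label = NULL) {
  df <- as.data.frame(manifest)
  if (!is.null(class_label)) df <- df[df$class == toupper(class_label), ]
  if (nrow(df) == 0L)
    stop("no series of class '", class_label, "' in manifest")
  lapply(seq_len(nrow(df)), function(i)
    read_rr(df$path[i], df$patient_id[i], df$class[i]))
}
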