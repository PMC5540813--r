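#' Read and validate a per-site subject table
#'
#' Expected CSV schema (comma-separated, UTF-8, "." decimal, header
#' mandatory): `subject_id`, `sex` (M/F), `age_years`, `handedness`
#' (L/R/empty), `icv_mm3`, then `{structure}_L_mm3` and `{structure}_R_mm3`
#' for each structure present. Unknown columns warn; missing required
#' columns or out-of-vocabulary codes error with the offending name/row.
#'
#' @param path CSV file path.
#' @param structures structures expected (default: any of the canonical
#'   seven found in the header; at least one pair required).
#' @param site_id optional site label (default: file name without
#'   extension).
#' @param fs_version optional software-version label attached as attribute.
#' @return A validated subject table (data.frame) with attributes `site_id`
#'   and `fs_version`.
#' @export
read_site_table <- function(path, structures = NULL, site_id = NULL,
                            fs_version = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (is.null(site_id)) site_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(structures)) {
    structures <- ai_structures()[paste0(ai_structures(), "_L_mm3") %in% names(tab)]
    if (length(structures) == 0L)
      stop("no {structure}_L_mm3 columns found in ", path)
  }
  if (is.null(fs_version) && "fs_version" %in% names(tab))
    fs_version <- as.character(tab$fs_version[1])
  attr(tab, "site_id") <- site_id
  attr(tab, "fs_version") <- fs_version
  validate_site_table(tab, structures)
  tab
}

#' Validate a subject table against the schema
#'
#' @param tab data.frame to check.
#' @param structures structures whose volume columns must be present.
#' @return `tab` invisibly; stops with the offending column/row on failure.
#' @export
validate_site_table <- function(tab, structures = ai_structures()) {
  required <- c("subject_id", "sex", "age_years", "icv_mm3",
                paste0(rep(structures, each = 2), c("_L_mm3", "_R_mm3")))
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  known <- c(required, "handedness", "fs_version",
             paste0(rep(ai_structures(), each = 2), c("_L_mm3", "_R_mm3")))
  extra <- setdiff(names(tab), known)
  if (length(extra))
    warning("unknown column(s) ignored: ", paste(extra, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id within site")
  bad <- which(!tab$sex %in% c("M", "F"))
  if (length(bad))
    stop("invalid sex code ", dQuote(tab$sex[bad[1]]), " in row ", bad[1],
         " (expected M or F)")
  if ("handedness" %in% names(tab)) {
    bad <- which(!is.na(tab$handedness) & !tab$handedness %in% c("L", "R"))
    if (length(bad))
      stop("invalid handedness code ", dQuote(tab$handedness[bad[1]]),
           " in row ", bad[1], " (expected L, R or empty)")
  } else tab$handedness <- NA_character_
  if (any(tab$age_years < 0, na.rm = TRUE)) stop("negative age_years")
  if (any(tab$icv_mm3 <= 0, na.rm = TRUE)) stop("non-positive icv_mm3")
  for (s in structures) for (side in c("_L_mm3", "_R_mm3")) {
    v <- tab[[paste0(s, side)]]
    if (any(v < 0, na.rm = TRUE)) stop("negative volume in ", s, side)
  }
  invisible(tab)
}

#' Write a subject table to CSV
#'
#' @param tab subject table.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_site_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a dataset-summary (or any result) table to CSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_summary <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a pedigree file
#'
#' Whitespace-delimited linkage-style layout with a header:
#' `family_id individual_id father_id mother_id sex` (parent id 0 for
#' founders; sex 1 = male, 2 = female). Rows may list children before
#' parents; structural validity (both parents or none, acyclicity) is
#' checked by [kinship_from_pedigree()] when used.
#'
#' @param path file path.
#' @return Pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  missing <- setdiff(need, names(ped))
  if (length(missing))
    stop("pedigree file missing column(s): ", paste(missing, collapse = ", "))
  ped
}

#' Write a pedigree file
#'
#' @param ped pedigree data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
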