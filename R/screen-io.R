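# Plate-table I/O and design validation.
#
# The on-disk format is plain CSV, one well per row, with explicit dose-unit
# columns (primaries are dosed in nM, secondaries in uM; silent unit mix-ups
# are the classic screen-analysis failure mode). Vehicle wells carry
# primary = "vehicle", secondary = "none" and both doses 0.

WELL_COLUMNS <- c("plate_id", "well", "line", "primary", "primary_dose",
                  "primary_dose_unit", "secondary", "secondary_dose",
                  "secondary_dose_unit", "replicate", "rfu")

#' Write a well table to CSV
#'
#' @param wells A `well_table` data frame (see [generate_screen()] or
#'   [read_well_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(wells, path) {
  stopifnot(is.data.frame(wells), all(WELL_COLUMNS %in% names(wells)))
  write.csv(as.data.frame(wells)[WELL_COLUMNS], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read and validate a well table
#'
#' Parses a one-well-per-row CSV plate table and validates every row: well
#' coordinates must address the 8x12 grid (A1..H12), fluorescence must be
#' positive, (plate, well) pairs must be unique, and vehicle wells must have
#' both doses at zero. Errors cite the offending row number.
#'
#' @param path CSV file with the columns written by [write_well_table()].
#' @return A `well_table` data frame.
#' @export
read_well_table <- function(path) {
  if (!file.exists(path)) {
    stop_blisshit("well table '%s' does not exist", path,
                  class = "blisshit_io_error")
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(WELL_COLUMNS, names(tab))
  if (length(missing)) {
    stop_blisshit("well table is missing column(s): %s",
                  paste(missing, collapse = ", "),
                  class = "blisshit_validation_error")
  }
  tab[c("primary_dose_unit", "secondary_dose_unit")] <-
    lapply(tab[c("primary_dose_unit", "secondary_dose_unit")],
           function(x) ifelse(is.na(x), "", as.character(x)))
  validate_wells(tab)
  structure(tab, class = c("well_table", "data.frame"))
}

validate_wells <- function(tab) {
  row_err <- function(rows, fmt, ...) {
    stop_blisshit(paste0(fmt, " (row %s)"), ...,
                  paste(utils::head(rows, 5), collapse = ", "),
                  class = "blisshit_validation_error")
  }
  bad <- which(!grepl("^[A-H](1[0-2]|[1-9])$", tab$well))
  if (length(bad)) row_err(bad, "malformed well id '%s' in field 'well'",
                           tab$well[bad[1]])
  bad <- which(!is.finite(tab$rfu) | tab$rfu <= 0)
  if (length(bad)) row_err(bad, "non-positive rfu")
  dup <- which(duplicated(tab[c("plate_id", "well")]))
  if (length(dup)) row_err(dup, "duplicate (plate_id, well) '%s/%s'",
                           tab$plate_id[dup[1]], tab$well[dup[1]])
  bad <- which(!is.finite(tab$primary_dose) | tab$primary_dose < 0 |
                 !is.finite(tab$secondary_dose) | tab$secondary_dose < 0)
  if (length(bad)) row_err(bad, "negative or missing dose")
  veh <- tab$primary == "vehicle" & tab$secondary == "none"
  bad <- which(veh & (tab$primary_dose != 0 | tab$secondary_dose != 0))
  if (length(bad)) row_err(bad, "vehicle well with non-zero dose")
  bad <- which((tab$primary == "vehicle" & tab$primary_dose != 0) |
                 (tab$secondary == "none" & tab$secondary_dose != 0))
  if (length(bad)) row_err(bad, "dose given for absent drug")
  invisible(tab)
}

#' Assemble a drug-library table
#'
#' @param entries Data frame with columns `drug`, `role` ("primary" or
#'   "secondary"), `target` (free-text annotation), `doses` (semicolon-joined
#'   numeric dose levels), `dose_unit`.
#' @return A `drug_library` data frame; drug ids must be unique and primaries
#'   must carry at least one dose level.
#' @export
drug_library <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("drug", "role", "doses", "dose_unit") %in% names(entries)))
  if (anyDuplicated(entries$drug)) {
    stop_blisshit("duplicate drug id '%s'",
                  entries$drug[duplicated(entries$drug)][1],
                  class = "blisshit_validation_error")
  }
  if (!all(entries$role %in% c("primary", "secondary"))) {
    stop_blisshit("role must be 'primary' or 'secondary'",
                  class = "blisshit_validation_error")
  }
  ndose <- lengths(strsplit(as.character(entries$doses), ";"))
  if (any(entries$role == "primary" & ndose < 1)) {
    stop_blisshit("primary drugs need at least one dose level",
                  class = "blisshit_validation_error")
  }
  if (!"target" %in% names(entries)) entries$target <- ""
  structure(entries, class = c("drug_library", "data.frame"))
}

#' Drug library implied by a screen truth
#'
#' @param truth A [screen_truth()] object.
#' @return A [drug_library()] data frame.
#' @export
library_from_truth <- function(truth) {
  stopifnot(inherits(truth, "screen_truth"))
  prim <- data.frame(
    drug = names(truth$primaries), role = "primary", target = "MAPK pathway",
    doses = vapply(truth$primaries,
                   function(d) paste(signif(d, 6), collapse = ";"), ""),
    dose_unit = "nM")
  sec <- data.frame(
    drug = names(truth$secondaries), role = "secondary", target = "",
    doses = as.character(signif(unname(truth$secondaries), 6)),
    dose_unit = "uM")
  drug_library(rbind(prim, sec))
}

#' Summarize and check a screen design
#'
#' Confirms that every cell line has vehicle wells (without which cytotoxicity
#' cannot be normalized) and a complete primary-dose x secondary combination
#' grid, and reports the design dimensions. Missing grid cells raise a warning
#' listing the absent (primary dose, secondary) pairs; a line with no vehicle
#' wells is an error.
#'
#' @param wells A `well_table` data frame.
#' @param library Optional [drug_library()]; when given, drugs in the wells
#'   must appear in the library with the right role.
#' @return A list summarizing lines, primaries and their dose counts,
#'   secondaries, replicate count, and any missing grid cells.
#' @export
validate_design <- function(wells, library = NULL) {
  stopifnot(is.data.frame(wells))
  if (nrow(wells) == 0) {
    stop_blisshit("empty well table", class = "blisshit_validation_error")
  }
  lines <- sort(unique(wells$line))
  veh <- wells$primary == "vehicle" & wells$secondary == "none"
  no_vehicle <- setdiff(lines, unique(wells$line[veh]))
  if (length(no_vehicle)) {
    stop_blisshit(
      "line(s) %s lack vehicle wells: cytotoxicity cannot be normalized",
      paste(no_vehicle, collapse = ", "), class = "blisshit_validation_error")
  }
  prim <- unique(wells[wells$primary != "vehicle", c("primary", "primary_dose")])
  sec <- unique(wells$secondary[wells$secondary != "none"])
  if (!is.null(library)) {
    known_p <- library$drug[library$role == "primary"]
    known_s <- library$drug[library$role == "secondary"]
    unknown <- c(setdiff(unique(prim$primary), known_p), setdiff(sec, known_s))
    if (length(unknown)) {
      stop_blisshit("drug(s) not in library (or wrong role): %s",
                    paste(unknown, collapse = ", "),
                    class = "blisshit_validation_error")
    }
  }
  expected <- merge(merge(data.frame(line = lines), prim, by = NULL),
                    data.frame(secondary = sec), by = NULL)
  combo <- wells[wells$primary != "vehicle" & wells$secondary != "none", ]
  key <- function(d) paste(d$line, d$primary, d$primary_dose, d$secondary,
                           sep = "\r")
  absent <- expected[!key(expected) %in% key(combo), ]
  if (nrow(absent)) {
    warning(sprintf(
      "design grid incomplete: %d missing cell(s), e.g. line %s, %s @ %g with %s",
      nrow(absent), absent$line[1], absent$primary[1], absent$primary_dose[1],
      absent$secondary[1]), call. = FALSE)
  }
  reps <- stats::aggregate(replicate ~ line, combo,
                           function(r) length(unique(r)))
  doses_per_primary <- vapply(split(prim$primary_dose, prim$primary),
                              function(d) length(unique(d)), 1L)
  list(lines = lines,
       primaries = sort(unique(prim$primary)),
       doses_per_primary = doses_per_primary,
       n_secondaries = length(sec),
       replicates = if (nrow(reps)) max(reps$replicate) else 0L,
       n_missing_cells = nrow(absent),
       missing_cells = absent)
}
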