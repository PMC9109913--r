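#' Normalize plate well identifiers
#'
#' Converts well labels such as `"A1"` or `"a01"` to the canonical
#' letter + zero-padded two-digit form (`"A01"`).
#'
#' @param well Character vector of well labels.
#' @return Character vector of normalized well IDs.
#' @examples
#' normalize_well_id(c("A1", "h12"))
#' @export
normalize_well_id <- function(well) {
  well <- trimws(as.character(well))
  ok <- grepl("^[A-Za-z][0-9]{1,2}$", well)
  if (any(!ok, na.rm = TRUE) || anyNA(well)) {
    bad <- unique(well[!ok | is.na(well)])
    abort(sprintf("Invalid well identifier(s): %s", paste(bad, collapse = ", ")))
  }
  row <- toupper(substr(well, 1, 1))
  col <- as.integer(sub("^[A-Za-z]", "", well))
  sprintf("%s%02d", row, col)
}

#' Read a droplet amplitude export
#'
#' Reads a QuantaSoft-style CSV export of per-droplet two-channel
#' fluorescence amplitudes.  Both the combined long format (one file for a
#' whole plate with a well column) and single-well exports (no well column;
#' supply `well`) are supported.  Column names vary between vendor software
#' versions, so the mapping is configurable.
#'
#' @param path Path to a CSV file (or a connection readable by
#'   [readr::read_csv()]).
#' @param col_map Named character vector mapping the internal names
#'   `fam`, `hex` and optionally `well` to the column names used in the
#'   file.  Defaults to the QuantaSoft convention `Ch1 Amplitude` (FAM) /
#'   `Ch2 Amplitude` (HEX) with a `Well` column.
#' @param well Well ID to assign when the file holds a single well and has
#'   no well column.
#' @param decimal_mark Decimal separator used in the file; exports from
#'   some locales use `","`.
#' @return A tibble with columns `well`, `fam`, `hex`, one row per droplet,
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Well,Ch1 Amplitude,Ch2 Amplitude",
#'              "A01,812.5,4201.0", "A01,790.1,980.2"), f)
#' read_amplitudes(f)
#' @export
read_amplitudes <- function(path,
                            col_map = c(well = "Well",
                                        fam = "Ch1 Amplitude",
                                        hex = "Ch2 Amplitude"),
                            well = NULL,
                            decimal_mark = ".") {
  stopifnot(all(c("fam", "hex") %in% names(col_map)))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (ch in c("fam", "hex")) {
    if (!col_map[[ch]] %in% names(raw)) {
      abort(sprintf(
        "Amplitude file is missing the %s channel column '%s' (columns present: %s)",
        toupper(ch), col_map[[ch]], paste(names(raw), collapse = ", ")
      ))
    }
  }
  has_well <- "well" %in% names(col_map) && col_map[["well"]] %in% names(raw)
  if (!has_well && is.null(well)) {
    abort("No well column found and no `well` supplied for a single-well file")
  }
  if (nrow(raw) == 0) {
    warn("Amplitude file contains a header but no droplet rows")
    return(tibble(well = character(), fam = double(), hex = double()))
  }
  parse_channel <- function(column, label) {
    x <- raw[[column]]
    if (decimal_mark != ".") x <- gsub(decimal_mark, ".", x, fixed = TRUE)
    val <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric %s amplitude '%s' at data row %d (file line %d)",
        label, x[bad[1]], bad[1], bad[1] + 1L
      ))
    }
    val
  }
  out <- tibble(
    well = if (has_well) normalize_well_id(raw[[col_map[["well"]]]])
           else rep(normalize_well_id(well), nrow(raw)),
    fam = parse_channel(col_map[["fam"]], "FAM"),
    hex = parse_channel(col_map[["hex"]], "HEX")
  )
  out
}

#' Read a plate configuration
#'
#' Reads per-well sample metadata from CSV or YAML: sample, assay and
#' experiment identifiers, the no-template-control flag, run-level
#' exclusion flags, and the array-CGH-assigned copy number where known.
#'
#' Recognised exclusion flags are `wga` (whole-genome-amplified template),
#' `mosaic` and `other_cnv`; in CSV input multiple flags are separated by
#' `;`.  YAML input is a list of per-well records with the same fields.
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @return A tibble with columns `well`, `sample_id`, `assay_id`,
#'   `experiment_id`, `is_ntc`, `exclusion_flags` (list column of character
#'   vectors) and `acgh_cn`.
#' @export
read_plate_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    entries <- yaml::read_yaml(path)
    rows <- purrr::map(entries, function(e) {
      tibble(
        well = e$well %||% abort("Plate config entry without a well"),
        sample_id = as.character(e$sample_id %||% NA_character_),
        assay_id = as.character(e$assay_id %||% NA_character_),
        experiment_id = as.character(e$experiment_id %||% NA_character_),
        is_ntc = isTRUE(e$is_ntc),
        flags = paste(unlist(e$exclusion_flags), collapse = ";"),
        acgh_cn = if (is.null(e$acgh_cn)) NA_integer_ else as.integer(e$acgh_cn)
      )
    })
    raw <- bind_rows(rows)
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(
      well = readr::col_character(),
      sample_id = readr::col_character(),
      assay_id = readr::col_character(),
      experiment_id = readr::col_character(),
      is_ntc = readr::col_logical(),
      exclusion_flags = readr::col_character(),
      acgh_cn = readr::col_integer()
    ), progress = FALSE)
    raw$flags <- raw$exclusion_flags
    raw$exclusion_flags <- NULL
  }
  raw$well <- normalize_well_id(raw$well)
  if (anyDuplicated(raw$well)) {
    abort(sprintf("Duplicate well entries in plate config: %s",
                  paste(unique(raw$well[duplicated(raw$well)]), collapse = ", ")))
  }
  flags <- purrr::map(raw$flags, function(f) {
    if (is.na(f) || !nzchar(f)) return(character())
    parts <- trimws(strsplit(f, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    unknown <- setdiff(parts, EXCLUSION_FLAGS)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown exclusion flag(s) %s; allowed: %s",
                    paste(unknown, collapse = ", "),
                    paste(EXCLUSION_FLAGS, collapse = ", ")))
    }
    parts
  })
  bad_assay <- !raw$is_ntc & !is.na(raw$assay_id) & !(raw$assay_id %in% ASSAY_IDS)
  if (any(bad_assay)) {
    abort(sprintf("Unknown assay_id '%s'; allowed values: %s",
                  raw$assay_id[bad_assay][1], paste(ASSAY_IDS, collapse = ", ")))
  }
  tibble(
    well = raw$well,
    sample_id = raw$sample_id,
    assay_id = raw$assay_id,
    experiment_id = raw$experiment_id,
    is_ntc = raw$is_ntc %in% TRUE,
    exclusion_flags = flags,
    acgh_cn = raw$acgh_cn
  )
}

#' Read a per-well cluster-count table
#'
#' @param path CSV with columns `well`, `n_pp`, `n_pn`, `n_np`, `n_nn`
#'   (FAM/HEX double-positive, FAM-only, HEX-only, double-negative).
#' @return A tibble with the four counts plus `n_total`.
#' @export
read_cluster_counts <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    n_pp = readr::col_integer(), n_pn = readr::col_integer(),
    n_np = readr::col_integer(), n_nn = readr::col_integer()
  ), progress = FALSE)
  x$well <- normalize_well_id(x$well)
  if (any(x$n_pp < 0 | x$n_pn < 0 | x$n_np < 0 | x$n_nn < 0)) {
    abort("Cluster counts must be non-negative")
  }
  mutate(x, n_total = .data$n_pp + .data$n_pn + .data$n_np + .data$n_nn)
}

#' Write and re-read a results table
#'
#' Results are written as plain CSV.  Numeric fields use the shortest
#' representation that round-trips a double exactly, so
#' `read_results(write_results(x))` reproduces every stored value.
#' List-valued exclusion flags are flattened to `;`-separated strings.
#'
#' @param records A results tibble (e.g. from [quantify_wells()] or
#'   [run_pipeline()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  out <- records
  if ("exclusion_flags" %in% names(out) && is.list(out$exclusion_flags)) {
    out$exclusion_flags <- purrr::map_chr(out$exclusion_flags, paste, collapse = ";")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  if ("exclusion_flags" %in% names(x)) {
    x$exclusion_flags <- purrr::map(as.character(x$exclusion_flags), function(f) {
      if (is.na(f) || !nzchar(f)) character() else strsplit(f, ";", fixed = TRUE)[[1]]
    })
  }
  x
}
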