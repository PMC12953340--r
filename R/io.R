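## Sample data model, delimited-text ingestion, below-LOD substitution,
## home-level aggregation, and SRM recovery QA.
##
## Samples are held in a long (tidy) tibble with one row per
## (home, medium, location, sample, metal):
##   home_id, medium, location_type, sample_id, metal, concentration,
##   below_lod, lod
## `lod` carries a cell-level detection limit when the source file used a
## "<x" token; otherwise the instrument LOD table supplies it.

#' Instrument limit-of-detection tables
#'
#' `lod_table()` builds an LOD table from per-metal detection limits
#' (mg/kg); `lod_vanta_vmw()` and `lod_vanta_vmr()` return the built-in
#' tables for the two pXRF instruments used for garden soil (VMW) and
#' indoor dust (VMR), and `read_lod_table()` reads one from a YAML or JSON
#' config file with fields `instrument_id` and `lods`.
#'
#' @param instrument_id Instrument label.
#' @param lods Named numeric vector of detection limits in mg/kg, one entry
#'   per metal; all values must be strictly positive.
#' @param path Path to a YAML or JSON file.
#' @return A list of class `lod_table` with elements `instrument_id` and
#'   `lods`.
#' @export
#' @examples
#' lod_vanta_vmw()$lods[["As"]]  # 1 mg/kg
lod_table <- function(instrument_id, lods) {
  lods <- unlist(lods)
  if (is.null(names(lods)) || any(!nzchar(names(lods)))) {
    abort("LOD table requires named per-metal entries.")
  }
  bad <- setdiff(names(lods), METALS)
  if (length(bad)) abort(paste0("unknown metal(s) in LOD table: ", toString(bad)))
  if (any(!is.finite(lods)) || any(lods <= 0)) {
    abort("all LODs must be finite and strictly positive.")
  }
  structure(list(instrument_id = instrument_id, lods = lods),
    class = "lod_table"
  )
}

#' @rdname lod_table
#' @export
lod_vanta_vmw <- function() {
  lod_table("Vanta VMW", c(As = 1, Cr = 2, Cu = 2, Mn = 3, Ni = 4, Pb = 1, Zn = 1))
}

#' @rdname lod_table
#' @export
lod_vanta_vmr <- function() {
  lod_table("Vanta VMR", c(As = 1, Cr = 1, Cu = 1, Mn = 3, Ni = 3, Pb = 1, Zn = 1))
}

#' @rdname lod_table
#' @export
read_lod_table <- function(path) {
  cfg <- read_config_file(path)
  lod_table(cfg$instrument_id %||% "unknown", unlist(cfg$lods))
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read a delimited sample table
#'
#' Reads a comma- (default) or tab-delimited table of trace-metal
#' measurements into the long sample tibble the rest of the pipeline
#' consumes. Required columns (case-insensitive): `home_id`, `medium`,
#' `location_type`, plus one column per measured metal. Metal cells may be
#' numeric, blank (missing), or a below-detection token: `"<LOD"`, `"ND"`,
#' or `"<x"` with numeric `x` (which overrides the instrument LOD for that
#' cell). Metals absent from the file are simply not analysed; a message
#' notes them.
#'
#' When `lod` is supplied, half-LOD substitution is applied on the way in
#' (see [substitute_half_lod()]); otherwise below-LOD concentrations are
#' left `NA` with their flag set.
#'
#' @param path Path to the delimited file.
#' @param lod Optional [lod_table()] used to substitute flagged cells.
#' @param delim Field delimiter; `NULL` (default) tries comma then tab.
#' @return A tibble with columns `home_id`, `medium`, `location_type`,
#'   `sample_id`, `metal`, `concentration`, `below_lod`, `lod`.
#' @export
read_samples <- function(path, lod = NULL, delim = NULL) {
  if (!file.exists(path)) abort(paste0("sample file not found: ", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- normalise_names(names(raw))

  required <- c("home_id", "medium", "location_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ", toString(missing_cols)))
  }
  metal_cols <- intersect(METALS, names(raw))
  if (!length(metal_cols)) {
    abort(paste0("no metal columns found; expected some of: ", toString(METALS)))
  }
  absent <- setdiff(METALS, metal_cols)
  if (length(absent)) {
    message("metal column(s) not present, analysis proceeds without them: ",
      toString(absent))
  }
  if (nrow(raw) == 0L) {
    return(empty_samples())
  }

  bad_medium <- setdiff(unique(raw$medium), MEDIA)
  if (length(bad_medium)) {
    abort(paste0("unknown medium value(s): ", toString(bad_medium)))
  }
  bad_loc <- setdiff(unique(raw$location_type), LOCATION_TYPES)
  if (length(bad_loc)) {
    abort(paste0("unknown location_type value(s): ", toString(bad_loc)))
  }

  out <- raw |>
    dplyr::mutate(
      sample_id = if ("sample_id" %in% names(raw)) .data$sample_id else
        paste0("row", dplyr::row_number()),
      .row = dplyr::row_number()
    ) |>
    tidyr::pivot_longer(dplyr::all_of(metal_cols),
      names_to = "metal", values_to = "cell"
    ) |>
    dplyr::mutate(parse_metal_cells(.data$cell, .data$.row)) |>
    dplyr::select(
      "home_id", "medium", "location_type", "sample_id",
      "metal", "concentration", "below_lod", "lod"
    )

  if (!is.null(lod)) out <- substitute_half_lod(out, lod)
  out
}

empty_samples <- function() {
  tibble::tibble(
    home_id = character(), medium = character(), location_type = character(),
    sample_id = character(), metal = character(), concentration = numeric(),
    below_lod = logical(), lod = numeric()
  )
}

normalise_names <- function(nms) {
  nms <- trimws(nms)
  low <- tolower(nms)
  core <- c(home_id = "home_id", medium = "medium",
    location_type = "location_type", sample_id = "sample_id")
  hit_core <- low %in% names(core)
  nms[hit_core] <- core[low[hit_core]]
  hit_metal <- match(low, tolower(METALS))
  nms[!is.na(hit_metal)] <- METALS[hit_metal[!is.na(hit_metal)]]
  nms
}

## Parse metal cells: numeric, blank, "<LOD"/"ND", or "<x".
parse_metal_cells <- function(cell, row) {
  cell <- trimws(cell %||% NA_character_)
  blank <- is.na(cell) | cell == ""
  nd <- !blank & toupper(cell) %in% c("<LOD", "ND")
  lt <- !blank & !nd & grepl("^<\\s*[0-9.eE+-]+$", cell)
  cell_lod <- rep(NA_real_, length(cell))
  cell_lod[lt] <- as.numeric(sub("^<\\s*", "", cell[lt]))
  num <- !blank & !nd & !lt
  conc <- rep(NA_real_, length(cell))
  conc[num] <- suppressWarnings(as.numeric(cell[num]))
  if (any(num & is.na(conc))) {
    bad <- which(num & is.na(conc))[1L]
    abort(paste0("non-numeric concentration '", cell[bad], "' at input row ", row[bad]))
  }
  if (any(conc < 0, na.rm = TRUE)) {
    bad <- which(conc < 0)[1L]
    abort(paste0("negative concentration ", conc[bad], " at input row ", row[bad]))
  }
  if (any(cell_lod <= 0, na.rm = TRUE)) {
    abort("cell-level detection limits in '<x' tokens must be positive.")
  }
  tibble::tibble(
    concentration = conc,
    below_lod = nd | lt,
    lod = cell_lod
  )
}

#' Substitute half the detection limit for below-LOD values
#'
#' Values flagged below the limit of detection are assigned exactly half the
#' corresponding detection limit — the cell-level limit when the source file
#' carried a `"<x"` token, otherwise the instrument LOD for that metal.
#' Unflagged values are never touched and the operation is idempotent.
#'
#' @param samples Long sample tibble from [read_samples()] or
#'   [generate_dataset()].
#' @param lod An [lod_table()] supplying per-metal detection limits.
#' @return The sample tibble with flagged concentrations filled in at LOD/2.
#' @export
substitute_half_lod <- function(samples, lod) {
  stopifnot(inherits(lod, "lod_table"))
  check_samples(samples)
  if (!nrow(samples)) return(samples)
  table_lod <- unname(lod$lods[samples$metal])
  eff_lod <- dplyr::coalesce(samples$lod, table_lod)
  need <- samples$below_lod
  if (any(need & is.na(eff_lod))) {
    missing <- unique(samples$metal[need & is.na(eff_lod)])
    abort(paste0("below-LOD value(s) for metal(s) with no LOD entry: ",
      toString(missing)))
  }
  samples$concentration[need] <- eff_lod[need] / 2
  samples$lod[need] <- eff_lod[need]
  samples
}

check_samples <- function(samples) {
  need <- c("home_id", "medium", "location_type", "metal", "concentration", "below_lod")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(paste0("sample table missing column(s): ", toString(missing_cols)))
  }
  if (!"lod" %in% names(samples)) samples$lod <- NA_real_
  bad <- setdiff(unique(samples$metal), METALS)
  if (length(bad)) abort(paste0("unknown metal(s): ", toString(bad)))
  if (any(samples$concentration < 0, na.rm = TRUE)) {
    abort("concentrations must be non-negative.")
  }
  invisible(samples)
}

#' Aggregate samples to representative home concentrations
#'
#' Averages the samples of each (home, medium) pair — typically the five
#' garden-soil locations of a home — into a single representative
#' concentration per metal. Background-soil records are excluded; pairs
#' whose values are all missing are dropped with a warning.
#'
#' @param samples Long sample tibble (after LOD substitution).
#' @param homes Optional home metadata tibble with `home_id` and e.g.
#'   `home_age_years`, `construction_material`; joined onto the result.
#' @return A tibble with one row per (home_id, medium, metal):
#'   `mean_concentration` (mg/kg) and `n_samples`, plus any metadata
#'   columns.
#' @export
aggregate_homes <- function(samples, homes = NULL) {
  check_samples(samples)
  out <- samples |>
    dplyr::filter(.data$medium != "background_soil") |>
    dplyr::group_by(.data$home_id, .data$medium, .data$metal) |>
    dplyr::summarise(
      mean_concentration = mean(.data$concentration, na.rm = TRUE),
      n_samples = sum(!is.na(.data$concentration)),
      .groups = "drop"
    )
  empty <- out$n_samples == 0L
  if (any(empty)) {
    warn(paste0(sum(empty), " (home, medium, metal) group(s) had no usable ",
      "values and were dropped."))
    out <- out[!empty, , drop = FALSE]
  }
  if (!is.null(homes)) {
    out <- dplyr::left_join(out, homes, by = "home_id")
  }
  out
}

#' Write a sample table as delimited text
#'
#' Inverse of [read_samples()]: pivots the long sample tibble back to one
#' row per specimen with a column per metal. Below-LOD cells are written as
#' the `"<LOD"` token so the substitution rule is re-applied on read.
#'
#' @param samples Long sample tibble.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, delim = ",") {
  check_samples(samples)
  wide <- samples |>
    dplyr::mutate(cell = dplyr::if_else(.data$below_lod, "<LOD",
      format(.data$concentration, trim = TRUE, scientific = FALSE, digits = 10))) |>
    dplyr::select("home_id", "medium", "location_type", "sample_id", "metal", "cell") |>
    tidyr::pivot_wider(names_from = "metal", values_from = "cell")
  readr::write_delim(wide, path, delim = delim, na = "")
  invisible(path)
}

#' Standard reference material recovery report
#'
#' Computes per-metal percent recovery (100 x measured / certified) for a
#' standard reference material, their arithmetic mean, and — when replicate
#' measurements are supplied — the relative standard deviation per metal.
#' Metals absent from either input are omitted.
#'
#' @param measured Named numeric vector of measured concentrations (mg/kg),
#'   or a data frame / matrix of replicates with one column per metal.
#' @param certified Named numeric vector of certified concentrations
#'   (mg/kg); all values must be strictly positive.
#' @param srm_id Optional SRM label (e.g. "NIST 2711a").
#' @return A tibble of class `recovery_report` with columns `metal`,
#'   `measured`, `certified`, `recovery` (percent) and `rsd` (percent,
#'   `NA` without replicates), carrying attributes `mean_recovery` and
#'   `srm_id`.
#' @export
#' @examples
#' compute_recovery(c(Pb = 96), c(Pb = 100))
compute_recovery <- function(measured, certified, srm_id = NA_character_) {
  if (is.data.frame(measured)) measured <- as.matrix(measured)
  if (is.matrix(measured)) {
    reps <- measured
    measured <- colMeans(reps)
    rsd_all <- 100 * apply(reps, 2, sd) / measured
  } else {
    rsd_all <- setNames(rep(NA_real_, length(measured)), names(measured))
  }
  if (is.null(names(measured)) || is.null(names(certified))) {
    abort("measured and certified values must be named by metal.")
  }
  if (any(!is.finite(certified)) || any(certified <= 0)) {
    abort("certified concentrations must be finite and strictly positive.")
  }
  common <- intersect(names(measured), names(certified))
  if (!length(common)) abort("measured and certified metal sets do not overlap.")
  common <- common[order(match(common, METALS))]
  meas <- unname(measured[common])
  cert <- unname(certified[common])
  out <- tibble::tibble(
    metal = common,
    measured = meas,
    certified = cert,
    recovery = 100 * meas / cert,
    rsd = unname(rsd_all[common])
  )
  attr(out, "mean_recovery") <- mean(out$recovery)
  attr(out, "srm_id") <- srm_id
  class(out) <- c("recovery_report", class(out))
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  id <- attr(x, "srm_id")
  cat("SRM recovery report", if (!is.na(id)) paste0(" (", id, ")"), "\n", sep = "")
  NextMethod()
  cat(sprintf("mean recovery: %.1f%%\n", attr(x, "mean_recovery")))
  invisible(x)
}

#' Write a QA/QC recovery report as JSON
#'
#' @param report A `recovery_report` from [compute_recovery()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(report, path) {
  stopifnot(inherits(report, "recovery_report"))
  payload <- list(
    srm_id = attr(report, "srm_id"),
    mean_recovery = attr(report, "mean_recovery"),
    per_metal = as.data.frame(report)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
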