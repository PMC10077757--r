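#' Read a viability screen table
#'
#' Reads a long-format screen table (CSV or TSV, decided by file extension)
#' and validates it against the monotherapy or combination schema. Each row
#' is one well: a cell line treated with a compound at a dose, with the raw
#' readout and a role flag distinguishing sample wells from plate controls
#' (DMSO-treated wells anchor 100% viability, empty or staurosporine-killed
#' wells anchor 0%).
#'
#' Doses are converted to nM on read using the `unit` column (`pM`, `nM`,
#' `uM`/`µM`/`μM`, `mM`, `M` are accepted); the returned table always carries
#' doses in nM.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param schema `"monotherapy"` (columns `cell_line, compound, dose, unit,
#'   replicate, signal, role`) or `"combination"` (additionally
#'   `anchor_compound, anchor_dose`, with `anchor_dose` in the same unit).
#' @return A tibble of validated well records with doses in nM.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "cell_line,compound,dose,unit,replicate,signal,role",
#'   "A673,talazoparib,10,nM,1,5200,sample",
#'   "A673,DMSO,0,nM,1,10100,pos_control",
#'   "A673,empty,0,nM,1,30,neg_control"
#' ), f)
#' read_screen_table(f)
read_screen_table <- function(path, schema = c("monotherapy", "combination")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("screen table not found: ", path))
  }
  tbl <- read_delim_auto(path)

  required <- c("cell_line", "compound", "dose", "unit", "replicate",
                "signal", "role")
  if (schema == "combination") {
    required <- c(required, "anchor_compound", "anchor_dose")
  }
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("schema error: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tbl[required]
  tbl$dose <- as.numeric(tbl$dose)
  tbl$signal <- as.numeric(tbl$signal)
  tbl$replicate <- as.integer(tbl$replicate)

  bad_sig <- which(!is.finite(tbl$signal) | tbl$signal < 0)
  if (length(bad_sig) > 0) {
    abort(paste0("validation error: negative or non-finite signal at row(s) ",
                 paste(head(bad_sig, 5), collapse = ", ")))
  }
  bad_dose <- which(!is.finite(tbl$dose) | tbl$dose < 0)
  if (length(bad_dose) > 0) {
    abort(paste0("validation error: negative or non-finite dose at row(s) ",
                 paste(head(bad_dose, 5), collapse = ", ")))
  }
  bad_role <- setdiff(unique(tbl$role), c("sample", "pos_control", "neg_control"))
  if (length(bad_role) > 0) {
    abort(paste0("validation error: unknown role value(s): ",
                 paste(bad_role, collapse = ", ")))
  }
  ctrl_dosed <- which(tbl$role == "pos_control" & tbl$dose != 0)
  if (length(ctrl_dosed) > 0) {
    abort(paste0("validation error: pos_control wells must carry dose 0 ",
                 "(row(s) ", paste(head(ctrl_dosed, 5), collapse = ", "), ")"))
  }

  fac <- dose_unit_factor(tbl$unit)
  tbl$dose <- tbl$dose * fac
  if (schema == "combination") {
    tbl$anchor_dose <- as.numeric(tbl$anchor_dose) * fac
  }
  tbl$unit <- "nM"
  tibble::as_tibble(tbl)
}

#' Write a screen table
#'
#' Inverse of [read_screen_table()]: writes CSV or TSV by extension with a
#' stable column order, so that write-then-read round-trips records exactly.
#'
#' @param tbl A well-record tibble as returned by [read_screen_table()].
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(tbl, path) {
  if (grepl("\\.tsv$|\\.txt$", path)) {
    readr::write_tsv(tbl, path)
  } else {
    readr::write_csv(tbl, path)
  }
  invisible(path)
}

read_delim_auto <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

dose_unit_factor <- function(unit) {
  lookup <- c(pM = 1e-3, nM = 1, uM = 1e3, mM = 1e6, M = 1e9)
  u <- gsub("µ|μ", "u", unit)  # micro sign / mu -> u
  fac <- lookup[u]
  if (anyNA(fac)) {
    abort(paste0("unknown dose unit(s): ",
                 paste(unique(unit[is.na(fac)]), collapse = ", ")))
  }
  unname(fac)
}

#' Read a GMT set collection
#'
#' Parses the tab-separated GMT dialect (set name, description, then member
#' identifiers). Used both for compound sets (grouped by annotated target or
#' target pathway) and for gene sets.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of unique member vectors, with the per-set
#'   descriptions kept in the `"description"` attribute so [write_gmt()]
#'   round-trips them.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) {
    warn(paste0("skipping ", sum(short), " GMT line(s) with no members"))
    parts <- parts[!short]
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate set name(s) in GMT: ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' Write a GMT set collection
#'
#' @param sets Named list of member vectors (descriptions taken from the
#'   `"description"` attribute when present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Normalize raw signals to fractional viability
#'
#' Converts raw well readouts to viability fractions using the plate
#' controls: the mean DMSO (positive-control) signal defines 100% viability
#' and the mean empty-well (negative-control) signal defines 0%. Values
#' above 1 or below 0 are retained, not clipped, so downstream least-squares
#' fits see the full noise distribution. Replicate wells are then averaged
#' per dose point, keeping the standard error of the mean.
#'
#' Normalization is performed within each `cell_line` group (and `plate`
#' group, if a `plate` column is present), i.e. each group must contain its
#' own controls.
#'
#' @param records Well-record tibble from [read_screen_table()] (monotherapy
#'   or combination schema).
#' @return A tibble of viability points: one row per
#'   `cell_line x compound x dose` (x anchor, for combinations) with columns
#'   `viability` (replicate mean, fraction of control), `sem` and `n_rep`.
#' @export
normalize_viability <- function(records) {
  grp <- intersect(c("plate", "cell_line"), names(records))
  if (!"cell_line" %in% grp) abort("records must carry a cell_line column")
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(~ normalize_one_plate(.x)) |>
    dplyr::ungroup()

  point_cols <- intersect(
    c("cell_line", "compound", "anchor_compound", "anchor_dose", "dose"),
    names(out)
  )
  out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(point_cols))) |>
    dplyr::summarise(
      sem = if (dplyr::n() > 1) sd(.data$viability) / sqrt(dplyr::n()) else NA_real_,
      n_rep = dplyr::n(),
      viability = mean(.data$viability),
      .groups = "drop"
    ) |>
    dplyr::relocate("viability", .before = "sem") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(point_cols)))
}

normalize_one_plate <- function(wells) {
  pos <- wells$signal[wells$role == "pos_control"]
  neg <- wells$signal[wells$role == "neg_control"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("normalization requires at least one pos_control and one neg_control well")
  }
  mu_pos <- mean(pos)
  mu_neg <- mean(neg)
  if (mu_pos <= mu_neg) {
    abort(sprintf(
      "degenerate plate: pos-control mean (%.3g) not above neg-control mean (%.3g)",
      mu_pos, mu_neg
    ))
  }
  smp <- wells[wells$role == "sample", , drop = FALSE]
  smp$viability <- (smp$signal - mu_neg) / (mu_pos - mu_neg)
  smp[setdiff(names(smp), c("signal", "role", "unit"))]
}
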