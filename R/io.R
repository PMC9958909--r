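# On-disk formats: chemical-shift tables (NMR-STAR v3 chemical-shift loop or
# a simple TSV dialect), amide peak lists (TSV), relaxation decay tables
# (CSV), SEC tables (CSV), FASTA, and JSON/TSV result reports.
#
# TSV dialect: tab-separated, '#' starts a comment line, header row required.
# Keyed tables are canonically sorted on load so reader output is independent
# of row order in the file.

# ---- constructors -----------------------------------------------------------

#' Chemical-shift table
#'
#' Per-residue, per-atom chemical shifts in full-length residue numbering.
#' At most one entry per (residue, atom) pair; shifts must be finite.
#'
#' @param residue_number Integer residue numbers (1-based, need not be
#'   contiguous).
#' @param residue_type One-letter amino-acid codes.
#' @param atom_name Atom names such as `"CA"`, `"CB"`, `"H"`, `"N"`.
#' @param shift Chemical shifts in ppm.
#' @return A `shift_table` data frame sorted by residue then atom.
#' @export
shift_table <- function(residue_number, residue_type, atom_name, shift) {
  df <- data.frame(residue_number = as.integer(residue_number),
                   residue_type = toupper(as.character(residue_type)),
                   atom_name = toupper(as.character(atom_name)),
                   shift = as.numeric(shift),
                   stringsAsFactors = FALSE)
  check_residue_types(df$residue_type)
  if (anyNA(df$shift) || any(!is.finite(df$shift)))
    nd_stop("nmrdomain_validation_error", "shifts must be finite")
  key <- paste(df$residue_number, df$atom_name)
  if (anyDuplicated(key))
    nd_stop("nmrdomain_validation_error",
            "duplicate (residue, atom) entries: %s",
            paste(unique(key[duplicated(key)]), collapse = "; "))
  df <- df[order(df$residue_number, df$atom_name), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Amide peak list
#'
#' One (1H, 15N) amide position per residue, with optional peak heights.
#' Strict validation confines 1H to (5, 13) ppm and 15N to (95, 140) ppm;
#' by default out-of-range positions only raise a warning, since folded or
#' aliased peaks occur in practice.
#'
#' @param residue_number Integer residue numbers; one peak per residue.
#' @param residue_type One-letter amino-acid codes.
#' @param h_ppm,n_ppm Amide 1H and 15N positions (ppm).
#' @param height Optional peak heights (arbitrary units).
#' @param strict If `TRUE`, out-of-range positions are an error instead of a
#'   warning.
#' @return A `peak_list` data frame sorted by residue number.
#' @export
peak_list <- function(residue_number, residue_type, h_ppm, n_ppm,
                      height = NULL, strict = FALSE) {
  df <- data.frame(residue_number = as.integer(residue_number),
                   residue_type = toupper(as.character(residue_type)),
                   h_ppm = as.numeric(h_ppm),
                   n_ppm = as.numeric(n_ppm),
                   stringsAsFactors = FALSE)
  if (!is.null(height)) df$height <- as.numeric(height)
  if (nrow(df) > 0L) {
    check_residue_types(df$residue_type)
    if (anyDuplicated(df$residue_number))
      nd_stop("nmrdomain_validation_error", "duplicate residue(s): %s",
              paste(unique(df$residue_number[duplicated(df$residue_number)]),
                    collapse = ", "))
    out <- df$h_ppm <= 5 | df$h_ppm >= 13 | df$n_ppm <= 95 | df$n_ppm >= 140
    if (any(out)) {
      msg <- sprintf("%d peak(s) outside expected amide ranges (1H 5-13, 15N 95-140 ppm)",
                     sum(out))
      if (strict) nd_stop("nmrdomain_validation_error", "%s", msg)
      nd_warn("%s", msg)
    }
  }
  df <- df[order(df$residue_number), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_list", "data.frame")
  df
}

# ---- TSV primitives ---------------------------------------------------------

read_tsv_body <- function(path) {
  if (!file.exists(path))
    nd_stop("nmrdomain_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], numbers = which(keep))
}

parse_tsv <- function(path, required) {
  body <- read_tsv_body(path)
  if (length(body$lines) == 0L)
    nd_stop("nmrdomain_format_error", "%s: no header line", path)
  header <- strsplit(body$lines[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0L)
    nd_stop("nmrdomain_format_error", "%s: missing column(s): %s",
            path, paste(missing, collapse = ", "))
  rows <- lapply(body$lines[-1], function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]])
  bad <- which(vapply(rows, length, 1L) != length(header))
  if (length(bad) > 0L)
    nd_stop("nmrdomain_format_error", "%s: line %d has %d fields, expected %d",
            path, body$numbers[-1][bad[1]],
            length(rows[[bad[1]]]), length(header))
  df <- as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0L)
    df <- as.data.frame(matrix(character(0), 0, length(header)),
                        stringsAsFactors = FALSE)
  names(df) <- header
  attr(df, "line_numbers") <- if (length(rows)) body$numbers[-1] else integer(0)
  df
}

numeric_column <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !(df[[col]] %in% c("NA", "")))
  if (length(bad) > 0L)
    nd_stop("nmrdomain_format_error",
            "%s: line %d: non-numeric value '%s' in column '%s'",
            path, attr(df, "line_numbers")[bad[1]], df[[col]][bad[1]], col)
  x
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  ok <- tryCatch(suppressWarnings({
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(names(out), collapse = "\t"), con)
    if (nrow(out) > 0L)
      writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok))
    nd_stop("nmrdomain_io_error", "cannot write %s: %s",
            path, conditionMessage(ok))
  invisible(path)
}

# ---- shift tables -----------------------------------------------------------

#' Read a chemical-shift table
#'
#' Reads either the simple TSV dialect (columns `residue_number`,
#' `residue_type`, `atom_name`, `shift`) or the `Atom_chem_shift` loop of an
#' NMR-STAR v3 file as deposited at the BMRB.  For NMR-STAR input only the
#' chemical-shift loop is consumed; everything else in the entry is ignored
#' with a notice.
#'
#' @param path Input file.
#' @param format `"auto"` (detect NMR-STAR by content), `"tsv"` or
#'   `"nmrstar"`.
#' @return A [shift_table()].
#' @export
read_shift_table <- function(path, format = c("auto", "tsv", "nmrstar")) {
  format <- match.arg(format)
  if (!file.exists(path))
    nd_stop("nmrdomain_io_error", "file not found: %s", path)
  if (format == "auto") {
    head <- readLines(path, n = 50L, warn = FALSE)
    format <- if (any(grepl("^\\s*(data_|save_|loop_)", head)) ||
                  any(grepl("_Atom_chem_shift", head, fixed = TRUE)))
      "nmrstar" else "tsv"
  }
  if (format == "tsv") {
    df <- parse_tsv(path, c("residue_number", "residue_type",
                            "atom_name", "shift"))
    shift_table(numeric_column(df, "residue_number", path),
                df$residue_type, df$atom_name,
                numeric_column(df, "shift", path))
  } else {
    read_nmrstar_shifts(path)
  }
}

# Minimal NMR-STAR v3 reader for the Atom_chem_shift loop.  Tokens are
# whitespace-separated; '.' and '?' are missing values.  Quoted tokens are
# supported to the extent they occur in shift loops (no embedded blanks
# needed for the consumed tags).
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  in_loop <- FALSE; collecting_tags <- FALSE
  tags <- character(0); values <- character(0)
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (!in_loop) {
      if (l == "loop_") { in_loop <- TRUE; collecting_tags <- TRUE
                          tags <- character(0); values <- character(0) }
      next
    }
    if (collecting_tags) {
      if (startsWith(l, "_")) { tags <- c(tags, l); next }
      collecting_tags <- FALSE
      if (!any(startsWith(tags, "_Atom_chem_shift."))) { in_loop <- FALSE }
      if (!in_loop) next
    }
    if (l == "stop_") {
      if (any(startsWith(tags, "_Atom_chem_shift."))) break
      in_loop <- FALSE; next
    }
    if (l == "" ) next
    values <- c(values, scan(text = l, what = character(), quiet = TRUE))
  }
  if (!any(startsWith(tags, "_Atom_chem_shift.")))
    nd_stop("nmrdomain_format_error",
            "%s: no _Atom_chem_shift loop found", path)
  ncol <- length(tags)
  if (length(values) %% ncol != 0L)
    nd_stop("nmrdomain_format_error",
            "%s: _Atom_chem_shift loop has %d values, not a multiple of %d tags",
            path, length(values), ncol)
  m <- matrix(values, ncol = ncol, byrow = TRUE)
  colnames(m) <- sub("^_Atom_chem_shift\\.", "", tags)
  col <- function(...) {
    for (nm in c(...)) if (nm %in% colnames(m)) return(m[, nm])
    nd_stop("nmrdomain_format_error",
            "%s: _Atom_chem_shift loop lacks tag(s) %s",
            path, paste(c(...), collapse = "/"))
  }
  res <- suppressWarnings(as.integer(col("Seq_ID", "Comp_index_ID")))
  comp <- toupper(col("Comp_ID"))
  atom <- col("Atom_ID")
  val <- suppressWarnings(as.numeric(col("Val")))
  keep <- !is.na(val) & !is.na(res)
  one <- AA_THREE_TO_ONE[comp[keep]]
  if (anyNA(one))
    nd_stop("nmrdomain_format_error", "%s: unknown residue name(s): %s",
            path, paste(unique(comp[keep][is.na(one)]), collapse = ", "))
  message(sprintf("read_shift_table: consumed %d shift rows from the _Atom_chem_shift loop of %s; all other content ignored",
                  sum(keep), basename(path)))
  shift_table(res[keep], unname(one), atom[keep], val[keep])
}

#' Write a shift table in the TSV dialect
#' @param x A [shift_table()].
#' @param path Output file.
#' @export
write_shift_table <- function(x, path)
  write_tsv(as.data.frame(x), path)

# ---- peak lists -------------------------------------------------------------

#' Read an amide peak list (TSV)
#'
#' Expects columns `residue_number`, `residue_type`, `h_ppm`, `n_ppm` and
#' optionally `height`.  A file with only a header yields an empty list.
#'
#' @inheritParams peak_list
#' @param path Input file.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, strict = FALSE) {
  df <- parse_tsv(path, c("residue_number", "residue_type", "h_ppm", "n_ppm"))
  peak_list(numeric_column(df, "residue_number", path),
            df$residue_type,
            numeric_column(df, "h_ppm", path),
            numeric_column(df, "n_ppm", path),
            height = if ("height" %in% names(df))
              numeric_column(df, "height", path),
            strict = strict)
}

#' Write an amide peak list in the TSV dialect
#' @param x A [peak_list()].
#' @param path Output file.
#' @export
write_peaklist <- function(x, path)
  write_tsv(as.data.frame(x), path)

# ---- relaxation / SEC tables ------------------------------------------------

#' Read an intensity-vs-delay relaxation table (CSV)
#'
#' Expects columns `residue`, `delay_ms`, `intensity`.
#'
#' @param path Input CSV.
#' @param experiment `"T1"`, `"T2"` or `"T1rho"`.
#' @param field_proton_mhz Proton Larmor frequency of the spectrometer (MHz).
#' @return A [relaxation_series()].
#' @export
read_relaxation_csv <- function(path, experiment = c("T1", "T2", "T1rho"),
                                field_proton_mhz) {
  if (!file.exists(path))
    nd_stop("nmrdomain_io_error", "file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  missing <- setdiff(c("residue", "delay_ms", "intensity"), names(df))
  if (length(missing) > 0L)
    nd_stop("nmrdomain_format_error", "%s: missing column(s): %s",
            path, paste(missing, collapse = ", "))
  relaxation_series(df, experiment = match.arg(experiment),
                    field_proton_mhz = field_proton_mhz)
}

#' Read SEC standards (CSV: name, mw_kda, ve_ml)
#' @param path Input CSV.
#' @return Data frame with columns `name`, `mw_kda`, `ve_ml`.
#' @export
read_sec_standards <- function(path) {
  if (!file.exists(path))
    nd_stop("nmrdomain_io_error", "file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  missing <- setdiff(c("name", "mw_kda", "ve_ml"), names(df))
  if (length(missing) > 0L)
    nd_stop("nmrdomain_format_error", "%s: missing column(s): %s",
            path, paste(missing, collapse = ", "))
  df
}

#' Read a protein FASTA file
#' @param path Input FASTA.
#' @return Named character vector of upper-case one-letter sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    nd_stop("nmrdomain_io_error", "file not found: %s", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  vapply(seqs, function(s) toupper(as.character(s)[1]), "")
}

# ---- reports ----------------------------------------------------------------

report_fields <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(x[!vapply(x, is.function, TRUE)])
  x
}

#' Write an analysis result to disk
#'
#' JSON reports serialize the full structure; TSV reports require a tabular
#' result (one row per record) or a flat list of scalars (written as
#' key/value rows).  Numbers are written at full precision.
#'
#' @param x Any analysis result from this package.
#' @param path Output file.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  x <- report_fields(x)
  if (format == "json") {
    ok <- tryCatch(suppressWarnings({
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", na = "null", pretty = TRUE)
      TRUE
    }), error = function(e) e)
    if (!isTRUE(ok))
      nd_stop("nmrdomain_io_error", "cannot write %s: %s",
              path, conditionMessage(ok))
  } else {
    if (!is.data.frame(x)) {
      scalar <- vapply(x, function(v)
        is.atomic(v) && length(v) == 1L, TRUE)
      x <- data.frame(key = names(x)[scalar],
                      value = vapply(x[scalar], function(v)
                        format(v, digits = 15), ""),
                      stringsAsFactors = FALSE)
    }
    write_tsv(x, path)
  }
  invisible(path)
}

#' Read back a JSON report
#' @param path JSON file written by [write_report()].
#' @return Parsed list.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    nd_stop("nmrdomain_io_error", "file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# ---- run configuration ------------------------------------------------------

#' Analysis run configuration
#'
#' Bundles the settings shared across pipeline stages: spectrometer proton
#' frequency, the 15N/1H gyromagnetic ratio used to derive the nitrogen
#' Larmor frequency, the CSP significance mode, the random-coil table id,
#' the peak-matching tolerance, strictness, and the RNG seed.
#'
#' @param spectrometer_proton_mhz Proton Larmor frequency (MHz), > 0.
#' @param gamma_ratio |gamma(15N)/gamma(1H)|; must lie in (0.09, 0.11).
#' @param csp_threshold_mode One of `"mean"`, `"two_sd"`, `"mean_plus_two_sd"`.
#' @param rc_table_id Identifier of the bundled random-coil table.
#' @param match_tol Peak matching tolerance (ppm, combined scale).
#' @param strict Treat range violations as errors.
#' @param seed RNG seed or `NULL`.
#' @return A `run_config` list.
#' @export
run_config <- function(spectrometer_proton_mhz = 600,
                       gamma_ratio = 0.10136767,
                       csp_threshold_mode = c("mean_plus_two_sd", "two_sd",
                                              "mean"),
                       rc_table_id = "wishart1995",
                       match_tol = 0.15,
                       strict = FALSE,
                       seed = NULL) {
  if (!is.numeric(spectrometer_proton_mhz) || spectrometer_proton_mhz <= 0)
    nd_stop("nmrdomain_value_error", "proton frequency must be positive")
  if (!is.numeric(gamma_ratio) || gamma_ratio <= 0.09 || gamma_ratio >= 0.11)
    nd_stop("nmrdomain_value_error", "gamma_ratio must lie in (0.09, 0.11)")
  structure(list(spectrometer_proton_mhz = spectrometer_proton_mhz,
                 gamma_ratio = gamma_ratio,
                 csp_threshold_mode = match.arg(csp_threshold_mode),
                 rc_table_id = rc_table_id,
                 match_tol = match_tol,
                 strict = isTRUE(strict),
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    nd_stop("nmrdomain_io_error", "file not found: %s", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}
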