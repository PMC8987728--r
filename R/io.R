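#' Read a signal set from CSV files
#'
#' Two layouts are supported, matching how digitized experimental curves
#' are usually stored:
#'
#' * **per-signal files**: several paths, each a 2-column CSV (`x`, `y`;
#'   header optional). Signal labels default to the file stems.
#' * **one wide file**: a single path whose columns come in pairs
#'   `x1,y1,x2,y2,...`; blank cells end shorter signals. Labels come from
#'   the x-column header of each pair when present.
#'
#' Rows with non-finite values and consecutive duplicate points are dropped
#' with a warning (see [as_signal_set()]).
#'
#' @param paths Character vector of CSV paths; a single path is read as a
#'   wide multi-signal file.
#' @param labels Optional character vector of signal labels overriding the
#'   defaults (must match the number of signals found).
#' @return A validated `signal_set` tibble.
#' @export
read_signal_set <- function(paths, labels = NULL) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("File(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (length(paths) == 1) {
    raw <- read_numeric_csv(paths[[1]])
    if (ncol(raw) < 4) {
      abort(paste0(
        "Need at least 2 signals: a single file must be a wide CSV with ",
        "column pairs x1,y1,x2,y2,... (got ", ncol(raw), " column(s))."
      ))
    }
    if (ncol(raw) %% 2 != 0) {
      warn("Odd number of columns in wide CSV; the last column is ignored.")
      raw <- raw[, seq_len(ncol(raw) - 1), drop = FALSE]
    }
    n_sig <- ncol(raw) / 2
    parts <- purrr::map(seq_len(n_sig), function(k) {
      xcol <- 2 * k - 1
      lab <- names(raw)[xcol]
      if (is.null(lab) || grepl("^(V|X)?[0-9]+$", lab)) {
        lab <- sprintf("signal_%02d", k)
      }
      tibble(signal = lab, x = raw[[xcol]], y = raw[[xcol + 1]]) %>%
        filter(!(is.na(.data$x) & is.na(.data$y)))
    })
    out <- bind_rows(parts)
  } else {
    stems <- sub("\\.[^.]*$", "", basename(paths))
    out <- purrr::map2(paths, stems, function(p, stem) {
      raw <- read_numeric_csv(p)
      if (ncol(raw) < 2) {
        abort(paste0("File ", p, " has fewer than 2 numeric columns."))
      }
      tibble(signal = stem, x = raw[[1]], y = raw[[2]])
    }) %>% bind_rows()
  }
  if (!is.null(labels)) {
    found <- unique(out$signal)
    if (length(labels) != length(found)) {
      abort("`labels` must have one entry per signal found.")
    }
    out$signal <- labels[match(out$signal, found)]
  }
  as_signal_set(out)
}

# Read a CSV whose header row is optional: if every field of the first line
# parses as a number the file is taken to be headerless.
read_numeric_csv <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))) &
    nzchar(trimws(fields)))
  readr::read_csv(
    path,
    col_names = has_header,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
}

#' Write corridor results to disk
#'
#' Writes the characteristic average and the two corridor polylines as
#' 2-column CSVs (`x`, `y`) plus a plain-text `run_metadata.txt` with
#' `key: value` lines recording the run parameters (control points `m`,
#' penalty factor `lambda`, probability `p`, resample count, seed, ...),
#' so that corridors can be reported reproducibly alongside the settings
#' that produced them.
#'
#' @param result A `corridor_result` from [build_corridors()].
#' @param out_dir Output directory (created if absent).
#' @return A tibble manifest with columns `file` and `path`, invisibly
#'   usable for further bookkeeping.
#' @export
write_corridor_result <- function(result, out_dir) {
  stopifnot(inherits(result, "corridor_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    abort(paste0("Output directory not writable: ", out_dir))
  }
  files <- c(
    average = "average.csv",
    inner = "inner_corridor.csv",
    outer = "outer_corridor.csv",
    metadata = "run_metadata.txt"
  )
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)

  readr::write_csv(result$average[, c("x", "y")], paths[["average"]],
    progress = FALSE
  )
  readr::write_csv(result$inner[, c("x", "y")], paths[["inner"]],
    progress = FALSE
  )
  readr::write_csv(result$outer[, c("x", "y")], paths[["outer"]],
    progress = FALSE
  )

  cfg <- result$config
  meta <- c(
    n_signals = n_signals(result$signals),
    n_resample = cfg$n_resample,
    m = cfg$m,
    lambda = cfg$lambda,
    p = cfg$p,
    chi2_value = chi2_quantile_2dof(cfg$p),
    grid_resolution = cfg$grid_resolution,
    margin_fraction = cfg$margin_fraction,
    seed = if (is.null(cfg$seed)) NA else cfg$seed,
    average_points = nrow(result$average),
    score_before = result$registration$score_before,
    score_after = result$registration$score_after
  )
  writeLines(
    paste0(names(meta), ": ", vapply(meta, format, "", digits = 15)),
    paths[["metadata"]]
  )

  tibble(file = unname(files), path = unname(paths))
}
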