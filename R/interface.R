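#' Read a GROMACS XVG time-series file
#'
#' Parses the plain-text XVG dialect written by `gmx energy` and friends:
#' lines starting with `#` are comments, lines starting with `@` are
#' Grace directives (legend directives `@ s0 legend "name"` supply column
#' names), everything else is whitespace-separated numeric data with time
#' (ps) in the first column.
#'
#' @param path path to an existing `.xvg` file.
#' @return a `timeseries_table`: a data frame whose first column is
#'   `time` (ps, strictly increasing), remaining columns named from the
#'   legends when present (else `col1`, `col2`, ...), with header
#'   directives kept in `attr(, "metadata")`.
#' @seealso [read_csv_table()], [read_pressure_trace()]
#' @export
read_xvg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("^\\s+", "", lines)
  is_comment <- startsWith(stripped, "#")
  is_directive <- startsWith(stripped, "@")
  is_blank <- stripped == ""
  is_data <- !(is_comment | is_directive | is_blank)

  legends <- character(0)
  meta <- list(comments = lines[is_comment])
  for (d in stripped[is_directive]) {
    m <- regmatches(d, regexec("^@\\s*s(\\d+)\\s+legend\\s+\"([^\"]*)\"", d))[[1]]
    if (length(m) == 3L) {
      legends[as.integer(m[2]) + 1L] <- m[3]
    } else {
      m2 <- regmatches(d, regexec("^@\\s*(title|xaxis|yaxis)\\s+(?:label\\s+)?\"([^\"]*)\"", d))[[1]]
      if (length(m2) == 3L) meta[[m2[2]]] <- m2[3]
    }
  }

  data_idx <- which(is_data)
  if (length(data_idx) == 0L)
    stop("no data rows in ", path, call. = FALSE)
  toks <- strsplit(stripped[data_idx], "\\s+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L) {
    bad <- data_idx[which(ncols != ncols[1])[1]]
    stop("ragged data: line ", bad, " of ", path,
         " has ", ncols[ncols != ncols[1]][1], " fields, expected ",
         ncols[1], call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / ncols[1])
    stop("non-numeric token in data on line ", data_idx[bad_row],
         " of ", path, call. = FALSE)
  }
  mat <- matrix(vals, ncol = ncols[1], byrow = TRUE)
  nm <- paste0("col", seq_len(ncols[1] - 1L))
  if (length(legends) > 0L) {
    ok <- !is.na(legends) & seq_along(legends) <= length(nm)
    nm[seq_along(legends)[ok]] <- legends[ok]
  }
  df <- as.data.frame(mat)
  names(df) <- c("time", nm)
  as_timeseries_table(df, metadata = meta)
}

#' Read a CSV time series
#'
#' Reads a headered CSV into the same `timeseries_table` structure as
#' [read_xvg()], so CSV and XVG inputs encoding the same numbers are
#' interchangeable downstream. The time column is the one named `time`
#' (case-insensitive) when present, otherwise the first column.
#'
#' @param path path to a CSV file with a header row.
#' @return a `timeseries_table` data frame.
#' @export
read_csv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  tcol <- which(tolower(names(df)) == "time")
  tcol <- if (length(tcol) > 0L) tcol[1] else 1L
  df <- df[, c(tcol, setdiff(seq_along(df), tcol)), drop = FALSE]
  names(df)[1] <- "time"
  as_timeseries_table(df, metadata = list(source = path))
}

#' Construct/validate a time-series table
#'
#' @param df data frame whose first column is time in ps.
#' @param metadata optional list of free-text header information.
#' @return a validated `timeseries_table`.
#' @export
as_timeseries_table <- function(df, metadata = list()) {
  stopifnot(is.data.frame(df), ncol(df) >= 1L)
  if (nrow(df) < 1L) stop("time series must have at least one row", call. = FALSE)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("all time-series columns must be numeric", call. = FALSE)
  if (nrow(df) > 1L && any(diff(df[[1]]) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  names(df)[1] <- "time"
  attr(df, "metadata") <- metadata
  class(df) <- c("timeseries_table", "data.frame")
  df
}

# resolve one requested column against the table: exact name first, then
# case-insensitive match with punctuation stripped; NULL if absent
.match_column <- function(table, name) {
  nms <- names(table)
  if (name %in% nms) return(name)
  canon <- function(s) gsub("[^a-z0-9]", "", tolower(s))
  hit <- which(canon(nms) == canon(name))
  if (length(hit) == 1L) {
    message("column ", sQuote(name), " matched to ", sQuote(nms[hit]),
            " (case-insensitive)")
    return(nms[hit])
  }
  NULL
}

#' Build a pressure trace from a time-series table
#'
#' Maps named columns of a [read_xvg()]/[read_csv_table()] table onto the
#' diagonal pressure-tensor components and box height needed for the
#' surface-tension relation. Defaults target the GROMACS energy names
#' `Pres-XX`, `Pres-YY`, `Pres-ZZ` and `Box-Z`; a `column_map` renames
#' them for other layouts. The box area of a constant-area run is given
#' either as the constant `area` (nm^2) or as an `area` entry of the
#' column map, never both. The GROMACS `#Surf*SurfTen` column (bar nm)
#' can be mapped via `surften` and used later as an alternative tension
#' source.
#'
#' @param table a `timeseries_table`.
#' @param column_map named list overriding any of `Pxx`, `Pyy`, `Pzz`,
#'   `Lz`, `area`, `surften` with column names in `table`.
#' @param area constant box area in nm^2 (constant-area runs).
#' @param Lz constant box height in nm, if not a column.
#' @param label free-text label for the system.
#' @return a `pressure_trace` object.
#' @export
read_pressure_trace <- function(table, column_map = NULL, area = NULL,
                                Lz = NULL, label = "") {
  stopifnot(inherits(table, "timeseries_table"))
  map <- list(Pxx = "Pres-XX", Pyy = "Pres-YY", Pzz = "Pres-ZZ",
              Lz = "Box-Z", area = NULL, surften = "#Surf*SurfTen")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad) > 0L)
      stop("unknown column_map entries: ", paste(bad, collapse = ", "),
           call. = FALSE)
    map[names(column_map)] <- column_map
  }

  fetch <- function(role, required = TRUE) {
    nm <- map[[role]]
    if (is.null(nm)) return(NULL)
    col <- .match_column(table, nm)
    if (is.null(col)) {
      if (required)
        stop("required column ", sQuote(nm), " (", role,
             ") not found in table", call. = FALSE)
      return(NULL)
    }
    table[[col]]
  }

  Pxx <- fetch("Pxx"); Pyy <- fetch("Pyy"); Pzz <- fetch("Pzz")
  if (!is.null(map$area) && !is.null(area))
    stop("supply the box area either as a constant or as a column, not both",
         call. = FALSE)
  A <- if (!is.null(map$area)) fetch("area") else area
  if (is.null(A)) stop("box area missing: give `area` or map a column",
                       call. = FALSE)
  lz <- if (!is.null(Lz)) {
    Lz
  } else {
    col <- .match_column(table, map$Lz)
    if (is.null(col))
      stop("required column ", sQuote(map$Lz),
           " (Lz) not found and no constant Lz given", call. = FALSE)
    table[[col]]
  }
  surften <- if (!is.null(map$surften)) {
    col <- if (map$surften %in% names(table)) map$surften else NULL
    if (!is.null(col)) table[[col]] else NULL
  }

  pressure_trace(time = table$time, Pxx = Pxx, Pyy = Pyy, Pzz = Pzz,
                 Lz = lz, area = A, label = label, surften = surften)
}

#' Pressure-trace constructor
#'
#' Per-frame diagonal pressures (bar), box height (nm; constant or per
#' frame) and constant box area (nm^2) from a constant-area run.
#'
#' @param time frame times, ps, strictly increasing.
#' @param Pxx,Pyy,Pzz diagonal pressure-tensor components, bar.
#' @param Lz box height in nm (length 1 or one per frame), all > 0.
#' @param area box area in nm^2, a positive constant.
#' @param label free-text system label.
#' @param surften optional per-frame surface-tension column, bar nm.
#' @return a `pressure_trace` list.
#' @export
pressure_trace <- function(time, Pxx, Pyy, Pzz, Lz, area, label = "",
                           surften = NULL) {
  n <- length(time)
  if (n < 1L) stop("pressure trace needs at least one frame", call. = FALSE)
  if (length(Lz) == 1L) Lz <- rep(Lz, n)
  lens <- c(length(Pxx), length(Pyy), length(Pzz), length(Lz))
  if (any(lens != n))
    stop("Pxx, Pyy, Pzz, Lz must have one value per frame", call. = FALSE)
  if (!is.null(surften) && length(surften) != n)
    stop("surften must have one value per frame", call. = FALSE)
  if (any(Lz <= 0)) stop("box height Lz must be positive", call. = FALSE)
  if (length(area) != 1L || area <= 0)
    stop("area must be a single positive number (nm^2)", call. = FALSE)
  if (n > 1L && any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  structure(list(time = as.numeric(time), Pxx = as.numeric(Pxx),
                 Pyy = as.numeric(Pyy), Pzz = as.numeric(Pzz),
                 Lz = as.numeric(Lz), area = as.numeric(area),
                 label = label,
                 surften = if (is.null(surften)) NULL else as.numeric(surften)),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat("Pressure trace", if (nzchar(x$label)) paste0(" [", x$label, "]"),
      ": ", length(x$time), " frames, ",
      format(x$time[1]), "-", format(x$time[length(x$time)]), " ps, area ",
      format(x$area), " nm^2\n", sep = "")
  invisible(x)
}

.units_of <- function(fields) {
  u <- c(sigma = "mN/m", sem = "mN/m", area = "nm^2", t_discard = "ps",
         ddF = "kJ/mol", ddF_err = "kJ/mol", delta_sigma = "mN/m",
         chaos = "nm^2", chaos_err = "nm^2",
         dF_total = "kJ/mol", dF_err = "kJ/mol", dF_per_leg = "kJ/mol",
         end_states = "nm^2")
  ifelse(names(fields) %in% names(u), u[names(fields)], "")
}

#' Write an analysis result to disk
#'
#' Serializes a `sensing_result`, `tension_estimate` or `ti_result` to
#' JSON (lossless round trip via [read_report()]) or to a flat CSV with
#' one row per quantity and columns `name,value,error,units`.
#'
#' @param result object to serialize.
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  cls <- class(result)[1]
  if (!cls %in% c("sensing_result", "ti_result", "tension_estimate"))
    stop("write_report does not handle class ", cls, call. = FALSE)
  flat <- unclass(result)
  if (format == "json") {
    payload <- c(list(.class = cls), flat)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    rows <- list()
    for (nm in names(flat)) {
      v <- flat[[nm]]
      if (!is.numeric(v)) next
      err <- NA_real_
      u <- .units_of(stats::setNames(list(v), nm))
      if (length(v) == 1L) {
        rows[[nm]] <- data.frame(name = nm, value = v, error = err,
                                 units = u, stringsAsFactors = FALSE)
      } else {
        rows[[nm]] <- data.frame(
          name = paste0(nm, ".", if (!is.null(names(v))) names(v) else seq_along(v)),
          value = as.numeric(v), error = err, units = u,
          stringsAsFactors = FALSE)
      }
    }
    # pair value/error columns that belong together
    tab <- do.call(rbind, rows)
    pairs <- c(sigma = "sem", ddF = "ddF_err", chaos = "chaos_err",
               dF_total = "dF_err")
    for (v in names(pairs)) {
      if (v %in% tab$name && pairs[v] %in% tab$name) {
        tab$error[tab$name == v] <- tab$value[tab$name == pairs[v]]
        tab <- tab[tab$name != pairs[v], , drop = FALSE]
      }
    }
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON report path.
#' @return the original result object, class restored.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  # restore names dropped by scalar unboxing
  structure(payload, class = cls)
}

#' Read/write stretch curves as CSV
#'
#' Schema: columns `area_nm2`, `sigma_mNm`, `sem_mNm`; the first row is
#' the tensionless reference area A0 (zero strain).
#'
#' @param curve a [stretch_curve()].
#' @param path CSV path.
#' @param label label for the curve being read.
#' @return `read_stretch_curve()` returns a `stretch_curve`.
#' @export
write_stretch_curve <- function(curve, path) {
  stopifnot(inherits(curve, "stretch_curve"))
  utils::write.csv(data.frame(area_nm2 = curve$area,
                              sigma_mNm = curve$sigma,
                              sem_mNm = curve$sem),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stretch_curve
#' @export
read_stretch_curve <- function(path, label = "") {
  df <- utils::read.csv(path)
  need <- c("area_nm2", "sigma_mNm", "sem_mNm")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  stretch_curve(A0 = df$area_nm2[1], area = df$area_nm2,
                sigma = df$sigma_mNm, sem = df$sem_mNm, label = label)
}

#' FASTA input/output for peptide populations
#'
#' Thin wrappers around Biostrings for fixed-length amino-acid sequence
#' sets used by the evolution driver.
#'
#' @param path FASTA file path.
#' @param sequences named character vector of sequences.
#' @return `read_fasta_sequences()` returns a named character vector.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_fasta_sequences
#' @export
write_fasta_sequences <- function(sequences, path) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
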