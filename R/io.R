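# DVH file I/O.
#
# Two tabular text dialects are supported:
#  * "csv": the package's own exchange format. Per structure block:
#        # structure=<label>
#        # volume_cm3=<float>          (required when volumes are percent)
#        # dose_unit=<Gy|cGy>
#        # volume_unit=<cm3|percent>
#        dose,volume
#        ...
#    blocks separated by one blank line. Writers emit this dialect with fixed
#    6-significant-digit formatting so write -> read -> write is bit-identical.
#  * "planner_export": block-structured planning-system text with
#    "Structure:" / "Volume [cm3]:" header keys and a two-column table;
#    tolerant to thousands separators and trailing whitespace.

#' Read DVHs from a tabular text file
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (package exchange format) or `"planner_export"`
#'   (planning-system block text). See Details in the package vignette.
#' @return List of [cdvh] objects, one per structure block. Percent volumes
#'   are converted to cm^3 using the declared structure volume; cGy doses are
#'   converted to Gy.
#' @export
read_dvh_table <- function(path, dialect = c("csv", "planner_export")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "csv") parse_dvh_csv(lines) else parse_dvh_planner(lines)
}

split_blocks <- function(lines, is_start) {
  blank <- !nzchar(trimws(lines))
  keep <- !blank
  idx <- cumsum(is_start & keep)
  lapply(split(lines[keep], idx[keep]), identity)
}

parse_dvh_csv <- function(lines) {
  starts <- grepl("^\\s*#\\s*structure=", lines)
  if (!any(starts)) stop("no '# structure=' header found in csv dialect file")
  blocks <- split_blocks(lines, starts)
  lapply(unname(blocks), function(b) {
    hdr_lines <- b[grepl("^\\s*#", b)]
    data_lines <- b[!grepl("^\\s*#", b)]
    hdr <- list()
    for (h in hdr_lines) {
      kv <- sub("^\\s*#\\s*", "", h)
      key <- trimws(sub("=.*$", "", kv))
      hdr[[key]] <- trimws(sub("^[^=]*=", "", kv))
    }
    label <- if (is.null(hdr$structure)) "" else hdr$structure
    parts <- strsplit(data_lines, ",")
    dose <- vapply(parts, function(p) as.numeric(p[1L]), 0)
    vol <- vapply(parts, function(p) as.numeric(p[2L]), 0)
    if (anyNA(dose) || anyNA(vol))
      stop(sprintf("non-numeric DVH row in structure '%s'", label))
    if (identical(hdr$dose_unit, "cGy")) dose <- dose / 100
    if (identical(hdr$volume_unit, "percent")) {
      if (is.null(hdr$volume_cm3))
        stop(sprintf(
          "structure '%s': volumes are percent but no 'volume_cm3' header present",
          label))
      vol <- vol / 100 * as.numeric(hdr$volume_cm3)
    }
    cdvh(dose, vol, structure = label)
  })
}

parse_dvh_planner <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  starts <- grepl("^\\s*Structure\\s*:", lines)
  if (!any(starts)) stop("no 'Structure:' header found in planner_export file")
  blocks <- split_blocks(lines, starts)
  strip_num <- function(s) as.numeric(gsub("[, ]", "", s))
  lapply(unname(blocks), function(b) {
    label <- trimws(sub("^\\s*Structure\\s*:", "", b[grepl("^\\s*Structure\\s*:", b)][1L]))
    vol_line <- b[grepl("^\\s*Volume\\s*\\[", b)]
    declared <- if (length(vol_line))
      strip_num(sub("^[^:]*:", "", vol_line[1L])) else NA_real_
    col_hdr <- b[grepl("Dose", b) & grepl("\\[", b) & !grepl(":", b)]
    dose_cgy <- length(col_hdr) && grepl("cGy", col_hdr[1L])
    vol_pct <- length(col_hdr) && grepl("%", sub(".*Dose[^]]*\\]", "", col_hdr[1L]))
    is_data <- grepl("^\\s*[-0-9]", b)
    rows <- lapply(strsplit(trimws(b[is_data]), "\\s+"), strip_num)
    rows <- rows[vapply(rows, function(r) length(r) >= 2 && !anyNA(r[1:2]), TRUE)]
    if (!length(rows)) stop(sprintf("structure '%s': no data rows", label))
    dose <- vapply(rows, `[[`, 0, 1L)
    vol <- vapply(rows, `[[`, 0, 2L)
    if (dose_cgy) dose <- dose / 100
    if (vol_pct) {
      if (is.na(declared))
        stop(sprintf(
          "structure '%s': volumes are percent but no structure volume header present",
          label))
      vol <- vol / 100 * declared
    }
    cdvh(dose, vol, structure = label)
  })
}

fmt6 <- function(x) formatC(x, digits = 6, format = "g")

#' Write DVHs in the package csv dialect
#'
#' Emits the exchange format read by `read_dvh_table(dialect = "csv")` with
#' fixed 6-significant-digit float formatting, so the write/read cycle is
#' bit-reproducible.
#'
#' @param dvhs A [cdvh] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path) {
  if (inherits(dvhs, "cdvh")) dvhs <- list(dvhs)
  stopifnot(all(vapply(dvhs, inherits, TRUE, "cdvh")))
  out <- unlist(lapply(dvhs, function(c) {
    c(sprintf("# structure=%s", c$structure),
      sprintf("# volume_cm3=%s", fmt6(c$total_volume)),
      "# dose_unit=Gy",
      sprintf("# volume_unit=%s", c$volume_unit),
      paste(fmt6(c$dose), fmt6(c$volume), sep = ","),
      "")
  }))
  writeLines(out[-length(out)], path)  # no trailing blank line
  invisible(path)
}
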