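#' Read a structure from a PDB or XYZ file
#'
#' PDB files are parsed with \pkg{bio3d} (ATOM and HETATM records, fixed
#' columns). Alternate-location duplicates are resolved by keeping the
#' first-listed conformer; insertion codes are ignored; hydrogens are
#' retained (the conservative choice for clash testing). XYZ files follow
#' the standard count / comment / \code{element x y z} layout.
#'
#' @param path Path to the file.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"xyz"}.
#' @param as Return a \code{"chromophore"} (charges unset) or an
#'   \code{"environment_model"} (positions only, for clash testing).
#' @param name Name given to a returned chromophore.
#' @return A \code{\link{chromophore}} or \code{\link{environment_model}}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           as = c("chromophore", "environment"),
                           name = basename(path)) {
  format <- match.arg(format)
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else if (ext == "xyz")
      "xyz" else stop("cannot infer format from extension '", ext,
                      "'; pass format=", call. = FALSE)
  }
  parsed <- if (format == "pdb") .parse_pdb(path) else .parse_xyz_frame(path)
  if (nrow(parsed$xyz) == 0)
    stop("empty structure: no atoms in ", path, call. = FALSE)
  if (as == "environment")
    environment_model(parsed$xyz, source = path)
  else
    chromophore(parsed$elements, parsed$xyz, name = name)
}

.parse_pdb <- function(path, multi = FALSE) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = multi, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("empty structure: no ATOM/HETATM records in ", path, call. = FALSE)
  # first-listed altloc wins; insertion codes ignored
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "|")
  keep <- !duplicated(key)
  at <- at[keep, , drop = FALSE]
  el <- trimws(at$elesy)
  miss <- is.na(el) | el == ""
  if (any(miss)) el[miss] <- substr(trimws(at$elety[miss]), 1, 1)
  xyz <- cbind(at$x, at$y, at$z)
  frames <- NULL
  if (multi && !is.null(pdb$xyz) && nrow(pdb$xyz) > 1) {
    nm <- nrow(pdb$xyz)
    idx <- which(keep)
    frames <- lapply(seq_len(nm), function(i) {
      m <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
      m[idx, , drop = FALSE]
    })
  }
  list(elements = el, xyz = xyz, frames = frames)
}

# Parse one XYZ frame starting at line 'at' of 'lines'; returns the frame
# and the index of the next unread line.
.parse_xyz_block <- function(lines, at, path) {
  n <- suppressWarnings(as.integer(trimws(lines[at])))
  if (is.na(n) || n < 0)
    stop("XYZ parse error in ", path, " line ", at,
         ": expected an atom count", call. = FALSE)
  if (at + 1 + n > length(lines) + 1)
    stop("XYZ parse error in ", path, ": truncated frame at line ", at,
         call. = FALSE)
  el <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- at + 1 + i
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(tok) < 4)
      stop("XYZ parse error in ", path, " line ", ln,
           ": expected 'element x y z'", call. = FALSE)
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v))
      stop("XYZ parse error in ", path, " line ", ln,
           ": non-numeric coordinate", call. = FALSE)
    el[i] <- tok[1]
    xyz[i, ] <- v
  }
  list(elements = el, xyz = xyz, next_line = at + 2 + n)
}

.parse_xyz_frame <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || all(trimws(lines) == ""))
    stop("empty structure: no atoms in ", path, call. = FALSE)
  b <- .parse_xyz_block(lines, 1L, path)
  if (nrow(b$xyz) == 0)
    stop("empty structure: no atoms in ", path, call. = FALSE)
  b
}

#' Read coordinate frames from a multi-model PDB or concatenated XYZ file
#'
#' Frames stand in for molecular-dynamics snapshots: the atom list is
#' constant, only coordinates vary.
#'
#' @inheritParams read_structure
#' @param name Name stem for the returned chromophores.
#' @return List of \code{\link{chromophore}} objects (charges unset), one
#'   per frame, all with identical atom ordering.
#' @export
read_frames <- function(path, format = c("auto", "pdb", "xyz"),
                        name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  if (format == "pdb") {
    p <- .parse_pdb(path, multi = TRUE)
    coords <- if (is.null(p$frames)) list(p$xyz) else p$frames
    el <- p$elements
  } else {
    lines <- readLines(path)
    coords <- list()
    el <- NULL
    at <- 1L
    while (at <= length(lines) && trimws(lines[at]) != "") {
      b <- .parse_xyz_block(lines, at, path)
      if (is.null(el)) el <- b$elements
      else if (!identical(el, b$elements))
        stop("XYZ frames in ", path, " have inconsistent atom lists",
             call. = FALSE)
      coords[[length(coords) + 1L]] <- b$xyz
      at <- b$next_line
    }
    if (length(coords) == 0)
      stop("empty structure: no frames in ", path, call. = FALSE)
  }
  lapply(seq_along(coords), function(i)
    chromophore(el, coords[[i]], name = sprintf("%s#%d", name, i)))
}

#' Write a chromophore (or raw coordinates) as an XYZ file
#'
#' @param chrom A \code{\link{chromophore}}.
#' @param path Output path.
#' @param comment Comment line (line 2 of the file).
#' @param digits Decimal places for coordinates (default 6).
#' @return Invisibly, \code{path}.
#' @export
write_xyz <- function(chrom, path, comment = chrom$name, digits = 6) {
  stopifnot(inherits(chrom, "chromophore"))
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  rows <- sprintf(fmt, chrom$elements,
                  chrom$xyz[, 1], chrom$xyz[, 2], chrom$xyz[, 3])
  writeLines(c(nrow(chrom$xyz), comment, rows), path)
  invisible(path)
}

#' Attach transition charges to a chromophore
#'
#' @param chrom A \code{\link{chromophore}}.
#' @param charges Numeric vector, one transition charge (e) per atom.
#' @param renormalize If \code{TRUE}, subtract the mean charge from every
#'   atom so the charges sum exactly to zero. This leaves the transition
#'   dipole about the charge centroid unchanged.
#' @param charge_sum_tol Tolerance on \eqn{|\sum q_i|} after any
#'   renormalization (e).
#' @return The chromophore with charges set.
#' @export
set_charges <- function(chrom, charges, renormalize = FALSE,
                        charge_sum_tol = 1e-4) {
  stopifnot(inherits(chrom, "chromophore"))
  charges <- as.numeric(charges)
  if (length(charges) != nrow(chrom$xyz))
    stop("charge count mismatch: ", length(charges), " charges for ",
         nrow(chrom$xyz), " atoms", call. = FALSE)
  if (renormalize) charges <- charges - mean(charges)
  chromophore(chrom$elements, chrom$xyz, charges = charges,
              name = chrom$name, masses = chrom$masses,
              charge_sum_tol = charge_sum_tol)
}

#' Read a transition-charge table and attach it to a structure
#'
#' The table is a comma-, tab- or whitespace-delimited text file with a
#' header and columns \code{index}, \code{element}, \code{q} (charge in e).
#' Indices are 1-based and rows must appear in atom order; the element
#' column is cross-checked against the structure.
#'
#' @param path Path to the charge table.
#' @param chrom The \code{\link{chromophore}} the charges belong to.
#' @inheritParams set_charges
#' @return The chromophore with charges attached.
#' @export
read_charges <- function(path, chrom, renormalize = FALSE,
                         charge_sum_tol = 1e-4) {
  stopifnot(inherits(chrom, "chromophore"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  names(tab) <- tolower(names(tab))
  need <- c("index", "element", "q")
  if (!all(need %in% names(tab)))
    stop("charge table must have columns index, element, q; got: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  n <- nrow(chrom$xyz)
  if (nrow(tab) != n)
    stop("charge table row count (", nrow(tab),
         ") does not match atom count (", n, ")", call. = FALSE)
  mism <- which(toupper(trimws(tab$element)) != toupper(chrom$elements))
  if (length(mism) > 0)
    stop("element mismatch at charge-table row ", mism[1], ": table has '",
         tab$element[mism[1]], "', structure has '",
         chrom$elements[mism[1]], "'", call. = FALSE)
  out <- set_charges(chrom, tab$q, renormalize = renormalize,
                     charge_sum_tol = charge_sum_tol)
  message(sprintf("attached %d transition charges, sum %.3e e", n,
                  sum(out$charges)))
  out
}

# column-wise print formats for tabular reports: angles to 0.1 deg,
# distances to 0.01 A, orientation factors to 1e-4
.record_format <- function(col) {
  if (grepl("^(alpha|beta|gamma|theta)", col)) return("%.1f")
  if (grepl("^(R_|r_)", col)) return("%.2f")
  if (grepl("kappa", col)) return("%.4f")
  if (col == "time") return("%.4f")
  "%.6g"
}

#' Write a homogeneous table of records to a delimited text file
#'
#' Writes orientation records, rotated-candidate tables, or frame-metric
#' time series as tab-separated text with a header. Columns are formatted
#' by name: angle columns to 0.1 degrees, distance columns to 0.01 Å,
#' orientation factors to 1e-4. Reading the file back with
#' \code{\link{read_records}} reproduces the values at the written
#' precision.
#'
#' @param records A data frame, or a list of single-kind records
#'   (data frames with identical columns) that will be row-bound. Mixing
#'   record kinds is an error.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_records <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    if (length(records) > 0) {
      cols <- lapply(records, names)
      if (length(unique(vapply(cols, paste, "", collapse = "|"))) > 1)
        stop("mixed record kinds: all records must have the same columns",
             call. = FALSE)
      records <- do.call(rbind, lapply(records, as.data.frame))
    } else {
      records <- data.frame()
    }
  }
  if (!is.data.frame(records)) stop("'records' must be a data frame or a ",
                                    "list of records", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(records), collapse = "\t"), con)
  if (nrow(records) > 0) {
    cells <- vapply(names(records), function(cl) {
      v <- records[[cl]]
      if (is.numeric(v)) sprintf(.record_format(cl), v) else as.character(v)
    }, character(nrow(records)))
    if (nrow(records) == 1) cells <- matrix(cells, nrow = 1)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read back a table written by \code{\link{write_records}}
#'
#' @param path Path to the file.
#' @return A data frame.
#' @export
read_records <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a key-value run summary file
#'
#' Records the configuration of a run (inputs, seeds, constants version) as
#' plain \code{key = value} lines, so any result table can be traced back
#' to the exact parameters that produced it.
#'
#' @param path Output path.
#' @param ... Named scalar values to record.
#' @return Invisibly, \code{path}.
#' @export
write_run_summary <- function(path, ...) {
  vals <- list(...)
  if (length(vals) > 0 && (is.null(names(vals)) || any(names(vals) == "")))
    stop("all run-summary values must be named", call. = FALSE)
  vals <- c(list(fretkappa_version = as.character(
    utils::packageVersion("fretkappa"))), vals)
  lines <- vapply(names(vals), function(k)
    paste0(k, " = ", paste(format(vals[[k]], digits = 10), collapse = ",")),
    "")
  writeLines(lines, path)
  invisible(path)
}
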