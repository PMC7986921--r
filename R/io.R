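# Container layout (HDF5). Complex arrays are stored as paired
# `<name>_real` / `<name>_imag` float64 datasets:
#   /fields/{ex,ey,ez}_{real,imag}  [Nc, nx, ny, nz]  (V/m per sqrt(W))
#   /tissue/sigma /tissue/rho       [nx, ny, nz]
#   /tissue/mask                    [nx, ny, nz] integer 0/1
#   /q10g/entries_{real,imag}       [Nc, Nc, Nv]      (W/kg per W)
#   /q10g/voxel_index               [Nv, 3] 0-based (x, y, z)
#   root attributes: voxel_size (m), averaged (0/1), units, schema
# Axis order in every dataset is (x, y, z), x fastest.

SCHEMA_VERSION <- "trigsar-container-1"

h5_write_complex <- function(x, file, name) {
  rhdf5::h5write(Re(x), file, paste0(name, "_real"))
  rhdf5::h5write(Im(x), file, paste0(name, "_imag"))
}

h5_read_complex <- function(file, name) {
  re <- rhdf5::h5read(file, paste0(name, "_real"))
  im <- rhdf5::h5read(file, paste0(name, "_imag"))
  array(complex(real = re, imaginary = im), dim = dim(re) %||% length(re))
}

h5_root_attrs <- function(path, attrs) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  for (nm in names(attrs)) rhdf5::h5writeAttribute(attrs[[nm]], fid, nm)
}

#' Write a channel field set to the HDF5 container
#'
#' @param fields A [channel_field_set].
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_fields_h5 <- function(fields, path) {
  stopifnot(inherits(fields, "channel_field_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "fields")
  rhdf5::h5createGroup(path, "tissue")
  h5_write_complex(fields$ex, path, "fields/ex")
  h5_write_complex(fields$ey, path, "fields/ey")
  h5_write_complex(fields$ez, path, "fields/ez")
  g <- fields$grid
  rhdf5::h5write(g$sigma, path, "tissue/sigma")
  rhdf5::h5write(g$rho, path, "tissue/rho")
  rhdf5::h5write(array(as.integer(g$body_mask), dim = g$shape), path,
                 "tissue/mask")
  h5_root_attrs(path, list(voxel_size = g$voxel_size,
                           units = "V/m per sqrt(W); S/m; kg/m^3",
                           schema = SCHEMA_VERSION))
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a channel field set from the HDF5 container
#'
#' @param path Container written by [write_fields_h5()].
#' @return A [channel_field_set].
#' @export
read_fields_h5 <- function(path) {
  if (!file.exists(path))
    stop_trigsar(paste("no such file:", path), "trigsar_parse_error")
  at <- rhdf5::h5readAttributes(path, "/")
  sigma <- rhdf5::h5read(path, "tissue/sigma")
  rho <- rhdf5::h5read(path, "tissue/rho")
  mask <- rhdf5::h5read(path, "tissue/mask") != 0
  grid <- tissue_grid(dim(sigma), as.numeric(at$voxel_size), sigma, rho, mask)
  fs <- channel_field_set(grid,
                          h5_read_complex(path, "fields/ex"),
                          h5_read_complex(path, "fields/ey"),
                          h5_read_complex(path, "fields/ez"))
  rhdf5::h5closeAll()
  fs
}

#' Write a Q-matrix set to the HDF5 container
#'
#' @param qset A [q_matrix_set] (or [vop_set]; the compression allowance is
#'   stored under `/vops/delta_term`).
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_qset_h5 <- function(qset, path) {
  stopifnot(inherits(qset, "q_matrix_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "q10g")
  h5_write_complex(qset_array(qset), path, "q10g/entries")
  if (!is.null(qset$voxel_index))
    rhdf5::h5write(qset$voxel_index - 1L, path, "q10g/voxel_index")
  if (inherits(qset, "vop_set")) {
    rhdf5::h5createGroup(path, "vops")
    rhdf5::h5write(qset$delta_term, path, "vops/delta_term")
    rhdf5::h5write(qset$delta, path, "vops/delta")
  }
  h5_root_attrs(path, list(averaged = as.integer(qset$averaged),
                           units = "W/kg per W",
                           schema = SCHEMA_VERSION))
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a Q-matrix set (native or MATLAB v7.3 container)
#'
#' Native dialect reads the layout written by [write_qset_h5()]. The
#' `"matlab"` dialect reads MATLAB v7.3 (HDF5-based) files holding Q/VOP
#' matrix sets either as a 3-D complex array of size `Nc x Nc x Nv` or as a
#' cell array of `Nc x Nc` matrices; complex data stored as compound
#' real/imag is handled. Every read set is validated (Hermitian within
#' tolerance, PSD within `-1e-10 * lambda_max`); offending matrix indices are
#' reported.
#'
#' @param path Container path.
#' @param dialect `"native_h5"` or `"matlab"`.
#' @param matlab_var Variable name for the MATLAB dialect; defaults to the
#'   first top-level dataset that yields a square-matrix set.
#' @return A validated [q_matrix_set].
#' @export
read_qset <- function(path, dialect = c("native_h5", "matlab"),
                      matlab_var = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_trigsar(paste("no such file:", path), "trigsar_parse_error")
  qset <- if (dialect == "native_h5") read_qset_native(path)
          else read_qset_matlab(path, matlab_var)
  validate_qset(qset)
  qset
}

read_qset_native <- function(path) {
  ls <- tryCatch(rhdf5::h5ls(path), error = function(e)
    stop_trigsar(paste("malformed container:", conditionMessage(e)),
                 "trigsar_parse_error"))
  need <- c("/q10g/entries_real", "/q10g/entries_imag")
  have <- file.path(ls$group, ls$name)
  miss <- setdiff(need, gsub("//", "/", have))
  if (length(miss))
    stop_trigsar(paste("malformed container: missing dataset", miss[1]),
                 "trigsar_parse_error")
  arr <- h5_read_complex(path, "q10g/entries")
  at <- rhdf5::h5readAttributes(path, "/")
  vi <- NULL
  if ("voxel_index" %in% ls$name[ls$group == "/q10g"])
    vi <- rhdf5::h5read(path, "q10g/voxel_index") + 1L
  has_vops <- any(ls$group == "/vops")
  if (has_vops) {
    delta <- as.numeric(rhdf5::h5read(path, "vops/delta"))
    delta_term <- as.numeric(rhdf5::h5read(path, "vops/delta_term"))
  }
  rhdf5::h5closeAll()
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  mats <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  qset <- q_matrix_set(mats, voxel_index = vi,
                       averaged = isTRUE(as.integer(at$averaged %||% 0L) == 1L),
                       validate = TRUE)
  if (has_vops) {
    class(qset) <- c("vop_set", class(qset))
    qset$delta <- delta
    qset$delta_term <- delta_term
    qset$provenance <- NULL # not serialized
  }
  qset
}

ml_to_complex <- function(x) {
  # rhdf5 returns compound real/imag as a list; native floats come through as-is
  if (is.list(x)) {
    re <- x[[grep("^r", names(x), ignore.case = TRUE)[1]]]
    im <- x[[grep("^i", names(x), ignore.case = TRUE)[1]]]
    array(complex(real = re, imaginary = im), dim = dim(re) %||% length(re))
  } else {
    array(as.complex(x), dim = dim(x) %||% length(x))
  }
}

read_qset_matlab <- function(path, matlab_var = NULL) {
  ls <- tryCatch(rhdf5::h5ls(path), error = function(e)
    stop_trigsar(paste("malformed container:", conditionMessage(e)),
                 "trigsar_parse_error"))
  top <- ls[ls$group == "/" & ls$otype == "H5I_DATASET" &
              !startsWith(ls$name, "#"), , drop = FALSE]
  cand <- if (is.null(matlab_var)) top$name else matlab_var
  if (length(cand) == 0L)
    stop_trigsar("malformed container: no top-level variable found",
                 "trigsar_parse_error")
  for (var in cand) {
    mats <- tryCatch(read_matlab_variable(path, var), error = function(e) NULL)
    if (!is.null(mats)) {
      rhdf5::h5closeAll()
      return(q_matrix_set(mats, averaged = TRUE, validate = TRUE))
    }
  }
  rhdf5::h5closeAll()
  stop_trigsar(sprintf("no usable Q-matrix variable in '%s' (tried: %s)",
                       path, paste(cand, collapse = ", ")),
               "trigsar_parse_error")
}

read_matlab_variable <- function(path, var) {
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, var)
  raw <- rhdf5::H5Dread(did, compoundAsDataFrame = FALSE)
  rhdf5::H5Dclose(did)
  if (inherits(raw, "H5Ref")) {
    # cell array: one object reference per cell; resolve to paths first
    nref <- length(raw@val) %/% 8L
    paths <- vapply(seq_len(nref), function(i) {
      ri <- methods::new("H5Ref", val = raw@val[((i - 1L) * 8L + 1L):(i * 8L)],
                         type = raw@type)
      rhdf5::H5Rget_name(ri, fid)
    }, character(1))
    rhdf5::H5Fclose(fid)
    mats <- lapply(paths, function(nm) {
      m <- ml_to_complex(rhdf5::h5read(path, nm, compoundAsDataFrame = FALSE))
      if (length(dim(m)) != 2L || nrow(m) != ncol(m))
        stop("cell entry is not a square matrix")
      m
    })
    return(mats)
  }
  rhdf5::H5Fclose(fid)
  arr <- ml_to_complex(raw)
  d <- dim(arr)
  if (length(d) == 2L && d[1] == d[2]) return(list(arr))
  if (length(d) == 3L && d[1] == d[2])
    return(lapply(seq_len(d[3]), function(i) arr[, , i]))
  stop("variable is not an Nc x Nc x Nv array")
}

validate_qset <- function(qset) {
  bad <- integer(0)
  for (i in seq_along(qset$matrices)) {
    e <- eigen(qset$matrices[[i]], symmetric = TRUE, only.values = TRUE)$values
    if (min(e) < -.tol_rank * max(e[1], 0)) bad <- c(bad, i)
  }
  if (length(bad))
    stop_trigsar(paste("validation failed: matrices not PSD at indices",
                       paste(bad, collapse = ", ")),
                 "trigsar_validation_error")
  invisible(qset)
}

#' Read / write a drive vector as CSV
#'
#' One row per channel with column `amplitude` (sqrt(W)) and optional column
#' `phase` (rad).
#'
#' @param path CSV path.
#' @return [read_drive_csv()]: a [drive_vector].
#' @export
read_drive_csv <- function(path) {
  d <- utils::read.csv(path)
  if (is.null(d$amplitude))
    stop_trigsar("drive CSV needs an `amplitude` column", "trigsar_parse_error")
  drive_vector(d$amplitude, d$phase)
}

#' @rdname read_drive_csv
#' @param drive A [drive_vector].
#' @export
write_drive_csv <- function(drive, path) {
  stopifnot(inherits(drive, "drive_vector"))
  d <- data.frame(channel = seq_along(drive$amplitudes),
                  amplitude = drive$amplitudes)
  if (!is.null(drive$phases)) d$phase <- drive$phases
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an amplitude trajectory from CSV
#'
#' Long format: columns `step`, `duration` (s), `channel`, `amplitude`
#' (sqrt(W)). Returns the wide per-step tibble accepted by
#' [time_integrated_worst_case()].
#'
#' @param path CSV path.
#' @return Tibble with `duration` and an `amplitudes` list-column.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("step", "duration", "channel", "amplitude")
  if (!all(need %in% names(d)))
    stop_trigsar(paste("trajectory CSV needs columns:",
                       paste(need, collapse = ", ")), "trigsar_parse_error")
  d <- d[order(d$step, d$channel), ]
  steps <- unname(split(d, d$step))
  tibble::tibble(
    duration = vapply(steps, function(s) s$duration[1], numeric(1)),
    amplitudes = lapply(steps, function(s) s$amplitude))
}

report_table <- function(report) {
  if (inherits(report, "bounds_report")) return(as.data.frame(report$drives))
  if (inherits(report, "worst_case_result")) {
    out <- as.data.frame(report$results[setdiff(names(report$results), "phases")])
    if (!is.null(report$results$phases)) {
      ph <- do.call(rbind, report$results$phases)
      colnames(ph) <- paste0("phase_", seq_len(ncol(ph)))
      out <- cbind(out, ph)
    }
    return(out)
  }
  stop_trigsar("unsupported report type", "trigsar_domain_error")
}

#' Serialize a result report
#'
#' Writes a [compare_methods()] report or [worst_case_psar()] result with a
#' deterministic column order, 12 significant digits for floats, and a schema
#' version stamp (JSON) / header (CSV).
#'
#' @param report A `bounds_report` or `worst_case_result`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  tab <- report_table(report)
  num <- vapply(tab, is.double, logical(1))
  if (format == "csv") {
    tab[num] <- lapply(tab[num], signif, digits = 12)
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    payload <- list(schema = paste0(SCHEMA_VERSION, "-report"),
                    type = class(report)[1],
                    rows = tab)
    if (inherits(report, "bounds_report"))
      payload$summary <- as.data.frame(report$summary)
    if (inherits(report, "worst_case_result"))
      payload$peak <- list(peak_sar = report$peak_sar,
                           peak_index = report$peak_index)
    jsonlite::write_json(payload, path, digits = 12, auto_unbox = TRUE,
                         dataframe = "columns")
  }
  invisible(path)
}
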