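#' Write mesh fields to an ASCII VTU file
#'
#' Minimal XML VTU (unstructured grid, quad cells) writer for nodal and
#' element data arrays; readable by ParaView/VTK and by [read_vtu()].
#'
#' @param mesh A [gen_sheet_mesh()] mesh.
#' @param path Output path (`.vtu`).
#' @param point_data Named list of numeric nodal vectors.
#' @param cell_data Named list of numeric per-element vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  num <- function(x) paste(formatC(x, format = "g", digits = 17),
                           collapse = " ")
  da <- function(name, x) {
    sprintf(
      '<DataArray type="Float64" Name="%s" format="ascii">%s</DataArray>',
      name, num(x))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ne),
    '<Points>',
    sprintf('<DataArray type="Float64" NumberOfComponents="3" format="ascii">%s</DataArray>',
            num(as.numeric(t(cbind(mesh$nodes$x_mm, mesh$nodes$y_mm, 0))))),
    '</Points>',
    '<Cells>',
    sprintf('<DataArray type="Int64" Name="connectivity" format="ascii">%s</DataArray>',
            paste(as.integer(t(mesh$elems)) - 1L, collapse = " ")),
    sprintf('<DataArray type="Int64" Name="offsets" format="ascii">%s</DataArray>',
            paste(seq_len(ne) * 4L, collapse = " ")),
    sprintf('<DataArray type="UInt8" Name="types" format="ascii">%s</DataArray>',
            paste(rep(9L, ne), collapse = " ")),
    '</Cells>',
    '<PointData>',
    vapply(names(point_data), function(nm) da(nm, point_data[[nm]]),
           character(1)),
    '</PointData>',
    '<CellData>',
    vapply(names(cell_data), function(nm) da(nm, cell_data[[nm]]),
           character(1)),
    '</CellData>',
    '</Piece>', '</UnstructuredGrid>', '</VTKFile>'), con)
  invisible(path)
}

#' Read back an ASCII VTU file written by [write_vtu()]
#'
#' @param path VTU path.
#' @return List with `points` (n x 3), `connectivity` (ne x 4, 1-based),
#'   `point_data`, `cell_data` (named lists).
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  getnum <- function(node) {
    as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  }
  pts <- getnum(xml2::xml_find_first(piece, ".//Points/DataArray"))
  pts <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- getnum(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='connectivity']"))
  conn <- matrix(as.integer(conn) + 1L, ncol = 4, byrow = TRUE)
  read_arrays <- function(xpath) {
    nodes <- xml2::xml_find_all(piece, xpath)
    out <- lapply(nodes, getnum)
    names(out) <- xml2::xml_attr(nodes, "Name")
    out
  }
  list(points = pts, connectivity = conn,
       point_data = read_arrays(".//PointData/DataArray"),
       cell_data = read_arrays(".//CellData/DataArray"))
}

#' Export a simulation's recorded frames as a VTU time series
#'
#' One VTU per recorded frame (array `u_mV`) plus a JSON collection index
#' with times and the producing configuration hash; a partial (diverged)
#' result is marked in the index with the last valid frame.
#'
#' @param result A [run_monodomain()] result with frames.
#' @param dir Output directory (created if needed).
#' @param basename File basename.
#' @return Paths of written files, invisibly.
#' @export
write_vtu_series <- function(result, dir, basename = "frame") {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(result$frames)) stop("no frames recorded")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- ncol(result$frames)
  paths <- character(nf)
  for (i in seq_len(nf)) {
    paths[i] <- file.path(dir, sprintf("%s_%04d.vtu", basename, i - 1))
    write_vtu(result$mesh, paths[i],
              point_data = list(u_mV = result$frames[, i]))
  }
  index <- list(
    files = basename(paths), t_ms = result$frame_t_ms,
    config_hash = result$config_hash, diverged = result$diverged,
    last_valid_frame = if (result$diverged) nf - 1L else nf
  )
  idx_path <- file.path(dir, paste0(basename, "_series.json"))
  jsonlite::write_json(index, idx_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, idx_path))
}

#' Write / read a substrate to VTU
#'
#' Nodal arrays `CV`, `ICV`, `g_to`, `g_CaL`, `g_Kur` and element arrays
#' `sigma_l`, `sigma_t` plus the flattened tensor entries.
#'
#' @param substrate A [build_substrate()] object.
#' @param path Output `.vtu` path.
#' @return `path`, invisibly.
#' @export
write_substrate_vtu <- function(substrate, path) {
  write_vtu(substrate$mesh, path,
            point_data = list(
              CV = substrate$nodal$cv, ICV = substrate$nodal$icv,
              g_to = substrate$nodal$g_to, g_CaL = substrate$nodal$g_CaL,
              g_Kur = substrate$nodal$g_Kur),
            cell_data = list(
              sigma_l = substrate$elem$sigma_l,
              sigma_t = substrate$elem$sigma_t,
              Dxx = substrate$elem$Dxx, Dxy = substrate$elem$Dxy,
              Dyy = substrate$elem$Dyy))
}

#' Run configuration as validated JSON
#'
#' @param config Named list: `mesh` (lx_mm, ly_mm, h_mm), `cv_preset`,
#'   `coefficients`, `remodeling`, `solver` (dt_ms, t_end_ms, bdf_order),
#'   `seed`. Unknown top-level keys are rejected.
#' @param path JSON path.
#' @return For `write_run_config`: `path` invisibly; for
#'   `read_run_config`: the validated list with a `config_hash`.
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(config)
  config$config_hash <- rlang::hash(config)
  config
}

validate_run_config <- function(config) {
  allowed <- c("mesh", "cv_preset", "coefficients", "remodeling", "solver",
               "protocol", "seed", "out_dir", "config_hash")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  required <- c("mesh", "solver", "seed")
  miss <- setdiff(required, names(config))
  if (length(miss) > 0) {
    stop("missing config key(s): ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' Export dense state checkpoints
#'
#' Writes the final state (potential, gates, concentrations) of a run to a
#' columnar file: Feather via the arrow package when available, CSV
#' otherwise.
#'
#' @param result A [run_monodomain()] result.
#' @param path Output path (extension decides: `.feather` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_state_checkpoint <- function(result, path) {
  df <- dplyr::bind_cols(
    tibble::tibble(node = result$activation$node, u_mv = result$u_final),
    tibble::as_tibble(result$gates_final, .name_repair = ~ crn_gate_names()),
    tibble::as_tibble(result$conc_final, .name_repair = ~ crn_conc_names())
  )
  if (grepl("\\.feather$", path) && requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_feather(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
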