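# Configuration validation, file formats and run manifests.
#
# Formats: ASCII PLY for surface meshes, TSV for sensor layouts and result
# tables ('.' decimal separator, UTF-8, deterministic row order), YAML for
# sweep configurations, JSON for run manifests.

# ---- config ----------------------------------------------------------------

config_field_names <- function() names(formals(sweep_config))

#' Load and validate a sweep configuration from YAML
#'
#' Unknown keys are rejected by name; missing keys receive the documented
#' defaults of [sweep_config()] (200 trials, 200 Hz, 5 mm patches, ...).
#'
#' @param path path to a YAML file whose keys match [sweep_config()]
#'   arguments.
#' @return a validated `sweep_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_field_names())
  if (length(unknown))
    stop("unknown config key(s): ", paste(sQuote(unknown), collapse = ", "))
  if (!is.null(raw$patch_fwhm_pairs))
    raw$patch_fwhm_pairs <- lapply(raw$patch_fwhm_pairs, as.numeric)
  do.call(sweep_config, raw)
}

#' Write a sweep configuration to YAML
#' @param config a `sweep_config`.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Stable content hash of a configuration
#'
#' Multiplicative string hash over the canonical (recursively key-sorted)
#' deparse of the configuration; invariant under key reordering.
#'
#' @param config a `sweep_config` (or any list).
#' @return an 8-hex-digit character hash.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      if (!is.null(nm) && any(nzchar(nm))) x <- x[order(nm)]
      lapply(x, canon)
    } else x
  }
  key <- paste(deparse(canon(unclass(config))), collapse = "")
  bytes <- utf8ToInt(key)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

# ---- atomic table / manifest writing ---------------------------------------

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

#' Write sweep outputs (tables, summaries, manifest) to a directory
#'
#' Tables are written as TSV (temp-file-then-rename for atomicity) and the
#' run manifest as JSON recording the config hash, master seed, package
#' version and the forward-model substitution note.
#'
#' @param table an `experiment_table`.
#' @param summaries output of [summarize_decisions()] (optional).
#' @param config the `sweep_config` that produced the table.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_outputs <- function(table, summaries = NULL, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_atomic(table, file.path(out_dir, "decisions.tsv"))
  if (!is.null(summaries))
    write_tsv_atomic(summaries, file.path(out_dir, "summary.tsv"))
  manifest <- list(
    config_hash = config_hash(config),
    master_seed = config$seed,
    package_version = as.character(utils::packageVersion("opmlaminar")),
    forward_model = "analytic spherical conductor (Sarvas); synthetic icosphere geometry",
    n_rows = nrow(table),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  tmp <- file.path(out_dir, "manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Read a decisions table written by [write_outputs()]
#' @param path path to a decisions/summary TSV.
#' @export
read_decisions <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# ---- PLY surface meshes ----------------------------------------------------

#' Write a surface mesh as ASCII PLY
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$vertices, digits = 9, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#' @param path path to an ASCII PLY file with triangle faces.
#' @return a `surface_mesh` (normals recomputed).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(p) as.numeric(p[1:3])))
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"),
                             function(p) as.integer(p[2:4]) + 1L))
  surface_mesh(v, f)
}

# ---- sensor layout TSV -----------------------------------------------------

#' Write a sensor array layout as TSV
#'
#' Columns: sensor_id, x, y, z, ax1x..ax3z (unused axes NA), n_axes,
#' offset_mm; one row per sensor.
#'
#' @param array a `sensor_array`.
#' @param path output path.
#' @export
write_sensor_layout <- function(array, path) {
  ns <- nrow(array$positions)
  ax <- matrix(NA_real_, ns, 9)
  for (k in seq_len(array$n_axes))
    ax[, (3 * k - 2):(3 * k)] <- array$axes[, , k]
  df <- data.frame(sensor_id = seq_len(ns), x = array$positions[, 1],
                   y = array$positions[, 2], z = array$positions[, 3])
  axn <- as.vector(t(outer(paste0("ax", 1:3), c("x", "y", "z"), paste0)))
  df[axn] <- ax
  df$n_axes <- array$n_axes
  df$offset_mm <- array$offset_mm
  write_tsv_atomic(df, path)
}

#' Read a sensor array layout TSV written by [write_sensor_layout()]
#' @param path path to the TSV.
#' @return a `sensor_array` (anchors reconstructed from offset and radial
#'   axis; canonical fiducials placed at the mean sensor radius).
#' @export
read_sensor_layout <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  n_axes <- df$n_axes[1]
  axes <- base::array(NA_real_, dim = c(nrow(df), 3, n_axes))
  for (k in seq_len(n_axes))
    axes[, , k] <- as.matrix(df[, paste0("ax", k, c("x", "y", "z"))])
  radial <- axes[, , 1]
  offset <- df$offset_mm[1]
  r <- mean(row_norms(pos))
  fid <- rbind(nasion = unit(c(0, 0.95, 0.31)), lpa = c(-1, 0, 0),
               rpa = c(1, 0, 0)) * r
  new_sensor_array(positions = pos, radial = radial,
                   anchors = pos - offset * radial, fiducials = fid,
                   n_axes = n_axes, offset_mm = offset, axes = axes)
}
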