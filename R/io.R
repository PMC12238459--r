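## Grid and table I/O: MetaImage (.mhd/.raw) for 3D grids, gzip-compressed
## binary with a JSON sidecar as an alternative container, and CSV for
## label tables and S-value tables.

#' Write a 3D grid as MetaImage (.mhd + .raw)
#'
#' @param grid 3D numeric or integer array.
#' @param path output path; ".mhd" is appended if missing.
#' @param voxel_mm isotropic voxel size, mm.
#' @param origin world mm of the first voxel centre.
#' @return the .mhd path, invisibly.
#' @export
write_metaimage <- function(grid, path, voxel_mm = 1, origin = c(0, 0, 0)) {
  if (!grepl("\\.mhd$", path)) path <- paste0(path, ".mhd")
  raw_path <- sub("\\.mhd$", ".raw", path)
  is_int <- is.integer(grid)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("TransformMatrix =", "1 0 0 0 1 0 0 0 1"),
           paste("Offset =", paste(origin, collapse = " ")),
           paste("ElementSpacing =", paste(rep(voxel_mm, 3), collapse = " ")),
           paste("DimSize =", paste(dim(grid), collapse = " ")),
           paste("ElementType =", if (is_int) "MET_INT" else "MET_DOUBLE"),
           paste("ElementDataFile =", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.vector(grid), con, size = if (is_int) 4L else 8L,
           endian = "little")
  invisible(path)
}

#' Read a MetaImage (.mhd/.raw) grid
#'
#' Supports the subset written by [write_metaimage()] (3D, uncompressed,
#' little-endian MET_INT / MET_DOUBLE / MET_FLOAT).
#'
#' @param path path to the .mhd header.
#' @return list with `grid` (3D array), `voxel_mm`, `origin`.
#' @export
read_metaimage <- function(path) {
  hdr <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  dims <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  offset <- get("Offset")
  origin <- if (is.null(offset)) c(0, 0, 0) else as.numeric(strsplit(offset, " +")[[1]])
  etype <- get("ElementType")
  datafile <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(dims)
  con <- file(datafile, "rb")
  on.exit(close(con))
  vec <- switch(etype,
    MET_INT = readBin(con, "integer", n, size = 4L, endian = "little"),
    MET_FLOAT = readBin(con, "double", n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8L, endian = "little"),
    stop("unsupported ElementType: ", etype))
  list(grid = array(vec, dims), voxel_mm = spacing[1], origin = origin)
}

#' Write a grid as gzip-compressed binary with a JSON sidecar
#'
#' @inheritParams write_metaimage
#' @return the data path, invisibly.
#' @export
write_grid_gz <- function(grid, path, voxel_mm = 1, origin = c(0, 0, 0)) {
  if (!grepl("\\.bin\\.gz$", path)) path <- paste0(path, ".bin.gz")
  con <- gzfile(path, "wb")
  writeBin(as.vector(as.numeric(grid)), con, size = 8L, endian = "little")
  close(con)
  meta <- list(dims = dim(grid), voxel_mm = voxel_mm, origin = origin,
               dtype = "float64_le")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid_gz
#' @export
read_grid_gz <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- gzfile(path, "rb")
  vec <- readBin(con, "double", prod(meta$dims), size = 8L, endian = "little")
  close(con)
  list(grid = array(vec, meta$dims), voxel_mm = meta$voxel_mm,
       origin = meta$origin)
}

#' Write / read a phantom label table as CSV
#'
#' Columns: label, name, material, density.
#'
#' @param phantom a `voxel_phantom`.
#' @param path CSV path.
#' @export
write_label_table <- function(phantom, path) {
  tab <- phantom$label_table
  write.csv(data.frame(label = tab$label, name = tab$organ,
                       material = tab$material, density = tab$density),
            path, row.names = FALSE)
  invisible(path)
}

#' Write an S-value table in long and wide formats
#'
#' Long format: source, target, s_gy_per_bq_s, delta_s, rel_unc_pct.  Wide
#' format mirrors the published layout: one row per source, one column per
#' target, cells "S (rel%)".
#'
#' @param table an `svalue_table`.
#' @param path_long,path_wide output CSV paths (NULL to skip one).
#' @param units "per-decay" (Gy/(Bq s)) or "per-mbq-s" (Gy/(MBq s)).
#' @export
write_svalue_table <- function(table, path_long = NULL, path_wide = NULL,
                               units = c("per-decay", "per-mbq-s")) {
  units <- match.arg(units)
  f <- if (units == "per-mbq-s") 1e6 else 1
  tab <- data.frame(source = table$source, target = table$target,
                    s = table$s * f, delta_s = table$delta_s * f,
                    rel_unc_pct = table$rel_unc_pct)
  unit_lab <- if (units == "per-mbq-s") "gy_per_mbq_s" else "gy_per_bq_s"
  names(tab)[3:4] <- paste(c("s", "delta_s"), unit_lab, sep = "_")
  if (!is.null(path_long)) write.csv(tab, path_long, row.names = FALSE)
  if (!is.null(path_wide)) {
    targets <- unique(table$target)
    wide <- data.frame(source = unique(table$source))
    for (tg in targets) {
      sel <- table[table$target == tg, ]
      cell <- paste0(format_svalue(sel$s * f),
                     ifelse(is.na(sel$rel_unc_pct), "",
                            sprintf(" (%.2g%%)", sel$rel_unc_pct)))
      wide[[tg]] <- cell[match(wide$source, sel$source)]
    }
    write.csv(wide, path_wide, row.names = FALSE)
  }
  invisible(table)
}
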