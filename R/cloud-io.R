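#' Read a point cloud from PLY, OBJ or XYZ
#'
#' Reads the vertex records of a mesh/point-cloud file into a point-cloud
#' tibble (columns `x`, `y`, `z`, in mm). PLY files may be `ascii` or
#' `binary_little_endian`; unknown vertex properties (colour, normals) are
#' ignored, except an integer `label` property which is kept as a `label`
#' column. For OBJ only `v` records are read; XYZ is whitespace-separated
#' text with 3 (or 4: label) numeric columns.
#'
#' @param path File path.
#' @param format One of `"ply"`, `"obj"`, `"xyz"`; default guesses from the
#'   file extension.
#' @return A point-cloud tibble (possibly with zero rows).
#' @seealso [write_point_cloud()]
#' @export
read_point_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- format %||% guess_cloud_format(path)
  format <- match.arg(format, c("ply", "obj", "xyz"))
  switch(format,
    ply = read_ply(path),
    obj = read_obj(path),
    xyz = read_xyz(path)
  )
}

#' Write a point cloud to PLY, OBJ or XYZ
#'
#' PLY output is ASCII by default (diffable); pass `binary = TRUE` for
#' `binary_little_endian`. A `label` column, when present, is written as an
#' `int label` vertex property (PLY) or a fourth column (XYZ); OBJ has no
#' place for labels and drops them.
#'
#' @param cloud A point-cloud tibble.
#' @param path Output file path.
#' @param format One of `"ply"`, `"obj"`, `"xyz"`; default guesses from the
#'   file extension.
#' @param binary Write binary-little-endian PLY instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = NULL, binary = FALSE) {
  validate_cloud(cloud)
  format <- format %||% guess_cloud_format(path)
  format <- match.arg(format, c("ply", "obj", "xyz"))
  switch(format,
    ply = write_ply(cloud, path, binary = binary),
    obj = write_obj(cloud, path),
    xyz = write_xyz(cloud, path)
  )
  invisible(path)
}

guess_cloud_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "obj", "xyz")) ext
  else abort(sprintf("cannot guess point-cloud format from extension '.%s'", ext))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- PLY ------------------------------------------------------------------

ply_type_size <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

ply_read_one <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = 1L, size = sz, endian = "little")
  } else if (type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32")) {
    readBin(con, "integer", n = 1L, size = sz, signed = sz < 4, endian = "little")
  } else {
    readBin(con, "integer", n = 1L, size = sz, endian = "little")
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) abort("not a PLY file (missing 'ply' magic)")
  fmt <- NULL
  elements <- list()   # each: list(name, count, props = tibble(name, type, list_count_type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) abort("malformed PLY header (no end_header)")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) abort("malformed PLY header (property before element)")
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list_count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list_count_type = NA_character_)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    abort(sprintf("unsupported PLY format '%s'", fmt %||% "<none>"))
  }
  vert <- elements[["vertex"]]
  if (is.null(vert)) abort("PLY file has no vertex element")
  pnames <- vapply(vert$props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames)) abort("PLY vertex element lacks x/y/z")

  if (fmt == "ascii") {
    vals <- read_ply_ascii(con, elements)
  } else {
    vals <- read_ply_binary(con, elements)
  }
  v <- vals[["vertex"]]
  out <- tibble(x = v[["x"]], y = v[["y"]], z = v[["z"]])
  if ("label" %in% names(v)) out$label <- as.integer(v[["label"]])
  validate_cloud(out)
  out
}

read_ply_ascii <- function(con, elements) {
  txt <- readLines(con)
  txt <- txt[nzchar(trimws(txt))]
  pos <- 0L
  out <- list()
  for (el in elements) {
    has_list <- any(!is.na(vapply(el$props, `[[`, "", "list_count_type")))
    lines <- txt[seq_len(el$count) + pos]
    pos <- pos + el$count
    if (el$name != "vertex") next
    if (has_list) abort("list properties on the vertex element are unsupported")
    if (el$count == 0) {
      out[[el$name]] <- stats::setNames(
        rep(list(numeric(0)), length(el$props)),
        vapply(el$props, `[[`, "", "name")
      )
      next
    }
    mat <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
    if (ncol(mat) < length(el$props)) abort("malformed PLY vertex records")
    vals <- stats::setNames(
      lapply(seq_along(el$props), function(i) mat[, i]),
      vapply(el$props, `[[`, "", "name")
    )
    out[[el$name]] <- vals
  }
  out
}

read_ply_binary <- function(con, elements) {
  out <- list()
  for (el in elements) {
    want <- el$name == "vertex"
    cols <- stats::setNames(
      rep(list(numeric(el$count)), length(el$props)),
      vapply(el$props, `[[`, "", "name")
    )
    simple <- all(is.na(vapply(el$props, `[[`, "", "list_count_type")))
    if (simple && el$count > 0) {
      # fixed record size: read property-wise row by row
      for (i in seq_len(el$count)) {
        for (j in seq_along(el$props)) {
          v <- ply_read_one(con, el$props[[j]]$type)
          if (want) cols[[j]][i] <- v
        }
      }
    } else if (el$count > 0) {
      for (i in seq_len(el$count)) {
        for (j in seq_along(el$props)) {
          p <- el$props[[j]]
          if (is.na(p$list_count_type)) {
            v <- ply_read_one(con, p$type)
            if (want) cols[[j]][i] <- v
          } else {
            n <- ply_read_one(con, p$list_count_type)
            for (k in seq_len(n)) ply_read_one(con, p$type)
          }
        }
      }
    }
    if (want) out[[el$name]] <- cols
  }
  out
}

write_ply <- function(cloud, path, binary = FALSE) {
  has_label <- "label" %in% names(cloud)
  hdr <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    "comment grain3d point cloud",
    sprintf("element vertex %d", nrow(cloud)),
    "property double x",
    "property double y",
    "property double z",
    if (has_label) "property int label",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(cloud) == 0) return(invisible(path))
  if (binary) {
    for (i in seq_len(nrow(cloud))) {
      writeBin(c(cloud$x[i], cloud$y[i], cloud$z[i]), con, size = 8, endian = "little")
      if (has_label) writeBin(as.integer(cloud$label[i]), con, size = 4, endian = "little")
    }
  } else {
    recs <- paste(
      format_coord(cloud$x), format_coord(cloud$y), format_coord(cloud$z)
    )
    if (has_label) recs <- paste(recs, as.integer(cloud$label))
    writeLines(recs, con)
  }
  invisible(path)
}

format_coord <- function(v) formatC(v, format = "g", digits = 17)

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", txt, value = TRUE)
  if (length(vlines) == 0) return(tibble(x = double(), y = double(), z = double()))
  mat <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }))
  if (anyNA(mat)) abort("malformed OBJ vertex records")
  out <- tibble(x = mat[, 1], y = mat[, 2], z = mat[, 3])
  validate_cloud(out)
  out
}

write_obj <- function(cloud, path) {
  lines <- paste(
    "v", format_coord(cloud$x), format_coord(cloud$y), format_coord(cloud$z)
  )
  writeLines(c("# grain3d point cloud", lines), path)
  invisible(path)
}

# ---- XYZ ------------------------------------------------------------------

read_xyz <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(tibble(x = double(), y = double(), z = double()))
  }
  df <- utils::read.table(path, header = FALSE, colClasses = "numeric")
  if (ncol(df) < 3) abort("XYZ file needs at least 3 columns")
  out <- tibble(x = df[[1]], y = df[[2]], z = df[[3]])
  if (ncol(df) >= 4) out$label <- as.integer(df[[4]])
  validate_cloud(out)
  out
}

write_xyz <- function(cloud, path) {
  recs <- paste(format_coord(cloud$x), format_coord(cloud$y), format_coord(cloud$z))
  if ("label" %in% names(cloud)) recs <- paste(recs, as.integer(cloud$label))
  writeLines(recs, path)
  invisible(path)
}

# ---- design + trait tables ------------------------------------------------

#' Read an L9 orthogonal design table
#'
#' Expects a CSV with 9 test rows, at least three factor columns and one
#' numeric response column. Factor columns may hold level codes (1-3) or
#' level labels; labels are coded 1-3 in order of first appearance (test 1 of
#' a standard L9 is all level 1). A column named `test`, `run` or `id` is
#' treated as the run index and dropped.
#'
#' @param path CSV file path.
#' @param response Name of the response column; default: the last column.
#' @return A tibble with integer-coded factor columns and a numeric
#'   `response` column; level labels are kept in the `"levels"` attribute.
#' @export
read_design_table <- function(path, response = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_design_table(df, response = response)
}

#' @rdname read_design_table
#' @param df A data frame already holding the design.
#' @export
as_design_table <- function(df, response = NULL) {
  df <- as_tibble(df)
  idcol <- intersect(c("test", "run", "id"), tolower(names(df)))
  if (length(idcol)) df <- df[, tolower(names(df)) != idcol[1]]
  if (nrow(df) != 9) abort(sprintf("wrong row count: expected 9 test rows, got %d", nrow(df)))
  response <- response %||% names(df)[ncol(df)]
  if (!response %in% names(df)) abort(sprintf("no response column '%s'", response))
  resp <- df[[response]]
  if (!is.numeric(resp)) abort("non-numeric response column")
  if (anyNA(resp) || any(!is.finite(resp))) abort("response column contains non-finite values")
  factors <- setdiff(names(df), response)
  if (length(factors) < 3) abort("need at least 3 factor columns")
  lev <- list()
  out <- tibble(.rows = 9)
  for (f in factors) {
    v <- df[[f]]
    labs <- as.character(unique(v))
    code <- match(as.character(v), labs)
    if (is.numeric(v) && all(v %in% 1:3)) {
      code <- as.integer(v)
      labs <- as.character(sort(unique(v)))
    }
    if (any(is.na(code)) || !all(code %in% 1:3)) {
      abort(sprintf("factor '%s' does not code into levels 1-3", f))
    }
    out[[f]] <- as.integer(code)
    lev[[f]] <- labs
  }
  out$response <- resp
  attr(out, "levels") <- lev
  out
}

#' The 32 grain trait names, in standard order
#'
#' Column order of a grain3d trait table: 16 basic measures (length `l`,
#' width `w`, thickness `h`, volume `V`, surface area `S`, sulcus depth `D`,
#' section perimeters/areas `C_yz`...`S_xy`, slice measures `C_c`, `S_c`,
#' `S_s`, and `l/w`) followed by 16 derived ratios and shape indices.
#'
#' @return Character vector of length 32.
#' @export
trait_names <- function() {
  c(
    "l", "w", "h", "V", "S", "D",
    "C_yz", "S_yz", "C_xz", "S_xz", "C_xy", "S_xy",
    "C_c", "S_c", "S_s", "l/w",
    "l/h", "w/h", "D/h", "V_obb",
    "S/V", "S/l", "S/w", "S/h",
    "V/l", "V/w", "V/h", "S_s/S_c",
    "c_yz", "c_xz", "c_xy", "E"
  )
}

#' Read / write a grain trait table
#'
#' The CSV carries one row per grain: an `id` column, the 32 traits of
#' [trait_names()] in order (symbols as headers), and optionally a `weight`
#' column (mg).
#'
#' @param path CSV file path.
#' @return A trait tibble.
#' @export
read_trait_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trait_table(df)
  df
}

#' @rdname read_trait_table
#' @param traits A trait tibble as produced by [grain_traits()].
#' @export
write_trait_table <- function(traits, path) {
  validate_trait_table(traits)
  cols <- intersect(c("id", trait_names(), "weight"), names(traits))
  readr::write_csv(traits[, cols], path, progress = FALSE)
  invisible(path)
}

validate_trait_table <- function(df, require_weight = FALSE) {
  missing <- setdiff(trait_names(), names(df))
  if (length(missing)) {
    abort(sprintf("trait table lacks columns: %s", paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(df[, trait_names()])
  if (anyNA(vals) || any(!is.finite(vals))) abort("trait table contains non-finite values")
  if (require_weight && is.null(df$weight)) abort("trait table lacks a `weight` column")
  invisible(df)
}
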