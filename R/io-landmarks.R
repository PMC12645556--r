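#' Construct a vertebral landmark point cloud
#'
#' A `spine_point_cloud` holds the annotated skeleton of one mouse: an ordered
#' set of vertebrae (rostral to caudal), each carrying a small set of 3-D
#' landmark coordinates in millimetres (typically a ring of 8 points per
#' vertebra). Coordinates follow a right-handed convention with x =
#' medio-lateral, y = dorso-ventral, z = rostro-caudal, so the coronal plane is
#' x-z and the sagittal plane is y-z.
#'
#' @param spine_id Character scalar identifying the animal/spine.
#' @param group Character scalar group label (e.g. `"WT"`, `"dHT"`, `"Ex36"`).
#' @param vertebrae List of vertebrae, each a list with `index` (integer,
#'   strictly increasing rostral to caudal) and `landmarks` (numeric matrix
#'   with 3 columns, one row per landmark, in mm).
#' @param units Character scalar, coordinate units; only `"mm"` is used.
#'
#' @return An object of class `spine_point_cloud`.
#' @seealso [read_landmarks()], [collapse_vertebrae()], [generate_spine()]
#' @export
spine_point_cloud <- function(spine_id, group, vertebrae, units = "mm") {
  obj <- structure(
    list(spine_id = as.character(spine_id)[1],
         group = as.character(group)[1],
         vertebrae = vertebrae,
         units = units),
    class = "spine_point_cloud")
  validate_spine_point_cloud(obj)
}

#' Validate a spine point cloud
#'
#' Checks the structural invariants: at least 4 vertebrae, strictly increasing
#' unique vertebra indices, at least one landmark per vertebra, and finite
#' coordinates throughout.
#'
#' @param x A `spine_point_cloud`.
#' @return `x`, invisibly unchanged, if valid; otherwise a validation error.
#' @export
validate_spine_point_cloud <- function(x) {
  if (!inherits(x, "spine_point_cloud"))
    stop_usage("not a spine_point_cloud")
  if (length(x$vertebrae) < 4L)
    stop_validation("spine '%s': needs >= 4 vertebrae, got %d",
                    x$spine_id, length(x$vertebrae))
  idx <- vapply(x$vertebrae, function(v) as.numeric(v$index), numeric(1))
  if (anyNA(idx) || any(diff(idx) <= 0))
    stop_validation("spine '%s': vertebra indices must be strictly increasing and unique",
                    x$spine_id)
  for (v in x$vertebrae) {
    lm <- v$landmarks
    if (!is.matrix(lm) || ncol(lm) != 3L || nrow(lm) < 1L)
      stop_validation("spine '%s', vertebra %s: landmarks must be an n x 3 matrix with n >= 1",
                      x$spine_id, v$index)
    if (!all(is.finite(lm)))
      stop_validation("spine '%s', vertebra %s: non-finite landmark coordinate",
                      x$spine_id, v$index)
  }
  invisible(x)
}

#' @export
print.spine_point_cloud <- function(x, ...) {
  nlm <- sum(vapply(x$vertebrae, function(v) nrow(v$landmarks), integer(1)))
  cat(sprintf("spine_point_cloud '%s' (group %s): %d vertebrae, %d landmarks [%s]\n",
              x$spine_id, x$group, length(x$vertebrae), nlm, x$units))
  invisible(x)
}

landmark_csv_columns <- c("spine_id", "group", "vertebra_index",
                          "landmark_index", "x_mm", "y_mm", "z_mm")

#' Read vertebral landmark point clouds
#'
#' Reads per-mouse landmark sets from CSV (long format, one row per landmark,
#' header `spine_id,group,vertebra_index,landmark_index,x_mm,y_mm,z_mm`) or an
#' equivalent JSON document. One `spine_point_cloud` is returned per distinct
#' `spine_id`; vertebrae are sorted by `vertebra_index` and landmark order
#' within a vertebra is the file order (CSV rows are ordered by
#' `landmark_index`).
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"json"`; by default guessed from the extension.
#' @return A list of [spine_point_cloud()] objects.
#' @export
read_landmarks <- function(path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("landmark file not found: %s", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (dialect == "json") return(read_landmarks_json(path))

  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(landmark_csv_columns, names(df))
  if (length(missing))
    stop_format("landmark CSV %s: missing column(s) %s",
                path, paste(missing, collapse = ", "))
  coords <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  bad <- which(!is.finite(coords), arr.ind = TRUE)
  if (nrow(bad))
    stop_validation("landmark CSV %s: non-finite coordinate at data row %d",
                    path, bad[1, 1])
  clouds <- lapply(split(df, df$spine_id), function(d) {
    d <- d[order(d$vertebra_index, d$landmark_index), , drop = FALSE]
    verts <- lapply(split(d, d$vertebra_index), function(v) {
      list(index = v$vertebra_index[1],
           landmarks = unname(as.matrix(v[, c("x_mm", "y_mm", "z_mm")])))
    })
    verts <- verts[order(vapply(verts, `[[`, numeric(1), "index"))]
    spine_point_cloud(d$spine_id[1], d$group[1], unname(verts))
  })
  unname(clouds[unique(df$spine_id)])
}

read_landmarks_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  # accept either a single object or an array of objects
  if (!is.null(doc$spine_id)) doc <- list(doc)
  lapply(doc, function(sp) {
    verts <- lapply(sp$vertebrae, function(v) {
      lm <- do.call(rbind, lapply(v$landmarks, function(p) as.numeric(unlist(p))))
      list(index = as.numeric(v$index), landmarks = lm)
    })
    spine_point_cloud(sp$spine_id, sp$group, verts)
  })
}

#' Write landmark point clouds
#'
#' Serializes a list of point clouds to the long CSV schema read by
#' [read_landmarks()], or to the equivalent JSON document. Round-tripping
#' preserves coordinates to better than 1e-9 mm.
#'
#' @param clouds A `spine_point_cloud` or list of them.
#' @param path Output path.
#' @param dialect `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(clouds, path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (inherits(clouds, "spine_point_cloud")) clouds <- list(clouds)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (dialect == "json") {
    doc <- lapply(clouds, function(cl) list(
      spine_id = cl$spine_id, group = cl$group,
      vertebrae = lapply(cl$vertebrae, function(v) list(
        index = v$index,
        landmarks = lapply(seq_len(nrow(v$landmarks)),
                           function(i) as.numeric(v$landmarks[i, ]))))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(clouds, function(cl) {
    do.call(rbind, lapply(cl$vertebrae, function(v) {
      data.frame(spine_id = cl$spine_id, group = cl$group,
                 vertebra_index = v$index,
                 landmark_index = seq_len(nrow(v$landmarks)),
                 x_mm = v$landmarks[, 1], y_mm = v$landmarks[, 2],
                 z_mm = v$landmarks[, 3])
    }))
  }))
  utils::write.csv(format_df_full_precision(rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# write.csv would round doubles at 15 significant digits via as.character;
# format with 17 digits so read/write is an identity well below 1e-9 mm.
format_df_full_precision <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  df
}
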