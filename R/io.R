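#' Write a numeric matrix in the plain-text dialect
#'
#' Format: one header line `n_rows n_cols`, then the matrix row-major,
#' whitespace-separated, full double precision. This is the package's
#' portable on-disk representation for BOLD blocks, spatial maps and
#' template components.
#'
#' @param x Numeric matrix.
#' @param path Output file path.
#' @export
write_matrix_text <- function(x, path) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(x), ncol(x)), con)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_text()]
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix_text <- function(path) {
  hdr <- scan(path, integer(), n = 2, quiet = TRUE)
  vals <- scan(path, double(), skip = 1, quiet = TRUE)
  stopifnot(length(vals) == hdr[1] * hdr[2])
  matrix(vals, hdr[1], hdr[2], byrow = TRUE)
}

#' Write a surface mesh as columnar text
#'
#' Writes `<stem>_vertices.txt` (x y z area excluded; one vertex per
#' line) and `<stem>_triangles.txt` (three 0-based vertex indices per
#' line).
#'
#' @param mesh A `surf_mesh`.
#' @param stem Output path stem.
#' @export
write_mesh_text <- function(mesh, stem) {
  vt <- data.frame(mesh$coordinates, area = mesh$vertex_areas,
                   excluded = as.integer(mesh$exclusion_mask))
  utils::write.table(vt, paste0(stem, "_vertices.txt"),
                     row.names = FALSE, col.names = c("x", "y", "z", "area", "excluded"),
                     quote = FALSE)
  utils::write.table(mesh$triangles - 1L, paste0(stem, "_triangles.txt"),
                     row.names = FALSE, col.names = c("v1", "v2", "v3"),
                     quote = FALSE)
  invisible(stem)
}

#' Read a mesh written by [write_mesh_text()]
#'
#' @param stem Path stem used when writing.
#' @return A `surf_mesh`.
#' @export
read_mesh_text <- function(stem) {
  vt <- utils::read.table(paste0(stem, "_vertices.txt"), header = TRUE)
  tr <- as.matrix(utils::read.table(paste0(stem, "_triangles.txt"),
                                    header = TRUE)) + 1L
  structure(list(coordinates = unname(as.matrix(vt[, c("x", "y", "z")])),
                 triangles = unname(tr),
                 vertex_areas = vt$area,
                 exclusion_mask = vt$excluded == 1,
                 radius = NA_real_),
            class = "surf_mesh")
}

#' Write a template prior (matrices + JSON sidecar)
#'
#' @param prior A `template_prior`.
#' @param stem Output path stem; writes `<stem>_mean.txt`,
#'   `<stem>_between_var.txt` and `<stem>.json`.
#' @export
write_template <- function(prior, stem) {
  write_matrix_text(prior$mean, paste0(stem, "_mean.txt"))
  write_matrix_text(prior$between_var, paste0(stem, "_between_var.txt"))
  jsonlite::write_json(
    list(n_template_subjects = prior$n_template_subjects,
         variance_floor = prior$variance_floor,
         n_vertices = nrow(prior$mean), n_ics = ncol(prior$mean)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Write a per-subject censoring report
#'
#' @param censors Named list of `censor_result`s (names = subject ids).
#' @param path Output TSV path.
#' @return The report as a data frame (invisibly written to `path` when
#'   given).
#' @export
write_censor_report <- function(censors, path = NULL) {
  df <- data.frame(
    subject_id = names(censors),
    block_start = vapply(censors, function(z) z$block_start, integer(1)),
    block_length = vapply(censors, function(z) z$block_length, numeric(1)),
    n_outliers = vapply(censors, function(z) z$n_outliers, numeric(1)),
    excluded = vapply(censors, function(z) z$excluded, logical(1)),
    row.names = NULL)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
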