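#' Write / read a surface mesh as plain-text tables
#'
#' Neutral on-disk format: `<prefix>_vertices.tsv` (x, y, z in mm),
#' `<prefix>_triangles.tsv` (1-based indices) and a JSON sidecar with the
#' vertex count and hemisphere tag.
#'
#' @param mesh a `surface_mesh`.
#' @param prefix file path prefix.
#' @return The prefix, invisibly.
#' @export
write_mesh <- function(mesh, prefix) {
  stopifnot(inherits(mesh, "surface_mesh"))
  data.table::fwrite(as.data.frame(mesh$vertices),
                     paste0(prefix, "_vertices.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(mesh$triangles),
                     paste0(prefix, "_triangles.tsv"), sep = "\t")
  jsonlite::write_json(list(n_vertices = nrow(mesh$vertices),
                            hemisphere = mesh$hemisphere),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  v <- as.matrix(data.table::fread(paste0(prefix, "_vertices.tsv")))
  tr <- as.matrix(data.table::fread(paste0(prefix, "_triangles.tsv")))
  surface_mesh(v, tr, hemisphere = side$hemisphere)
}

#' Write / read a BOLD series as plain text plus a JSON sidecar
#'
#' The signal matrix (vertices x timepoints) goes to `<prefix>.tsv`; the
#' sidecar records TR, subject id, hemisphere and dimensions.
#'
#' @param bold a `bold_series`.
#' @param prefix file path prefix.
#' @return The prefix, invisibly.
#' @export
write_series <- function(bold, prefix) {
  stopifnot(inherits(bold, "bold_series"))
  data.table::fwrite(as.data.frame(bold$signal), paste0(prefix, ".tsv"),
                     sep = "\t")
  jsonlite::write_json(list(tr_s = bold$tr_s, subject = bold$subject,
                            hemisphere = bold$hemisphere,
                            n_vertices = nrow(bold$signal),
                            n_timepoints = ncol(bold$signal)),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_series
#' @export
read_series <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  sig <- as.matrix(data.table::fread(paste0(prefix, ".tsv")))
  dimnames(sig) <- NULL
  bold_series(sig, tr_s = side$tr_s, subject = side$subject,
              hemisphere = side$hemisphere)
}

#' Write a motion trace as TSV
#'
#' Six parameter columns plus the derived framewise displacement.
#'
#' @param trace a `motion_trace`.
#' @param path output TSV path.
#' @export
write_motion <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  df <- as.data.frame(trace$params)
  df$fd <- trace$fd
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  motion_trace(as.matrix(df[, 1:6]))
}

#' Export a synthetic cohort to disk
#'
#' Writes per-subject series and motion traces, the subject table
#' (subject, group, age, sex, mean_fd, md_vf) as TSV, the mesh, the
#' parcellation labels, and the ground truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(cohort$mesh, file.path(dir, "mesh"))
  data.table::fwrite(data.frame(label = cohort$atlas$labels),
                     file.path(dir, "atlas_labels.tsv"), sep = "\t")
  data.table::fwrite(cohort$design, file.path(dir, "participants.tsv"),
                     sep = "\t")
  for (i in seq_along(cohort$subjects)) {
    id <- cohort$design$subject[i]
    write_series(cohort$subjects[[i]]$bold, file.path(dir, id))
    write_motion(cohort$subjects[[i]]$motion,
                 file.path(dir, paste0(id, "_motion.tsv")))
  }
  jsonlite::write_json(unclass(cohort$truth),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
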