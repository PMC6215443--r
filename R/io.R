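# Plain-text interchange formats: model spec (key-value), fabric /
# stress vector-field tables, ROI tables, posture files and a JSON run
# manifest.  Numeric values are written with full (round-trip) precision.

MODEL_SPEC_HEADER <- "# trabpose model spec v1"
FABRIC_HEADER <- c("bone", "x", "y", "z", "ux", "uy", "uz", "roi")

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a model spec file
#'
#' Key-value text with a versioned header.  The template itself is
#' referenced by name and rebuilt deterministically on read.
#'
#' @param model a `model_spec`
#' @param path output file
#' @export
write_model_spec <- function(model, path) {
  lines <- c(MODEL_SPEC_HEADER,
             paste0("template: ", model$template$name),
             paste0("g: ", fmt_num(model$g)),
             paste0("knee_axis_skew: ", fmt_num(model$knee_axis_skew)),
             paste0("hip_medial_offset: ", fmt_num(model$hip_medial_offset)),
             paste0("extra_abduction: ", fmt_num(model$extra_abduction)),
             paste0("extra_lar: ", fmt_num(model$extra_lar)),
             paste0("com_fraction: ", fmt_num(model$com_fraction)))
  writeLines(lines, path)
  invisible(path)
}

read_kv <- function(path, header = NULL) {
  lines <- readLines(path)
  if (!is.null(header) && !identical(lines[1], header))
    stop("unrecognized file header in ", path)
  lines <- grep("^\\s*(#|$)", lines, value = TRUE, invert = TRUE)
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  vals <- stats::setNames(vapply(kv, `[`, "", 3),
                          trimws(vapply(kv, `[`, "", 2)))
  vals
}

#' Read a model spec file
#' @param path file written by [write_model_spec()]
#' @return a `model_spec`
#' @export
read_model_spec <- function(path) {
  v <- read_kv(path, MODEL_SPEC_HEADER)
  m <- model_spec(build_species_template(v[["template"]]),
                  g = as.numeric(v[["g"]]),
                  knee_axis_skew = as.numeric(v[["knee_axis_skew"]]),
                  hip_medial_offset = as.numeric(v[["hip_medial_offset"]]),
                  com_fraction = as.numeric(v[["com_fraction"]]))
  m$extra_abduction <- as.numeric(v[["extra_abduction"]])
  m$extra_lar <- as.numeric(v[["extra_lar"]])
  m
}

#' Write a fabric (or axis) field table
#'
#' Whitespace-delimited `bone x y z ux uy uz roi` with a header row;
#' one row per lattice point, full numeric precision.
#'
#' @param field a `fabric_field`
#' @param path output file
#' @export
write_fabric_field <- function(field, path) {
  df <- as.data.frame(field)[, FABRIC_HEADER]
  for (cn in c("x", "y", "z", "ux", "uy", "uz")) df[[cn]] <- fmt_num(df[[cn]])
  df$roi[df$roi == ""] <- "."
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a fabric field table
#' @param path file written by [write_fabric_field()]
#' @return a `fabric_field`
#' @export
read_fabric_field <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(FABRIC_HEADER %in% names(df)))
    stop("fabric table must have columns ",
         paste(FABRIC_HEADER, collapse = " "))
  df$roi[df$roi == "."] <- ""
  class(df) <- c("fabric_field", "data.frame")
  df
}

#' Write a stress trajectory field in long format
#'
#' Same table format as the fabric field with an extra `component`
#' column in `{s1, s3}` (two rows per lattice point).
#'
#' @param stress result of [stress_trajectory_field()]
#' @param path output file
#' @export
write_stress_field <- function(stress, path) {
  lf <- rbind(
    data.frame(bone = stress$bone, x = stress$x, y = stress$y, z = stress$z,
               ux = stress$s1x, uy = stress$s1y, uz = stress$s1z,
               component = "s1"),
    data.frame(bone = stress$bone, x = stress$x, y = stress$y, z = stress$z,
               ux = stress$s3x, uy = stress$s3y, uz = stress$s3z,
               component = "s3"))
  for (cn in c("x", "y", "z", "ux", "uy", "uz")) lf[[cn]] <- fmt_num(lf[[cn]])
  utils::write.table(lf, path, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write an ROI table
#'
#' Columns: `label bone cx cy cz radius mode`.
#'
#' @param rois list of [spherical_roi()]
#' @param path output file
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(label = r$label, bone = r$bone, cx = fmt_num(r$centre[1]),
               cy = fmt_num(r$centre[2]), cz = fmt_num(r$centre[3]),
               radius = fmt_num(r$radius), mode = r$mode)))
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an ROI table
#' @param path file written by [write_rois()]
#' @return list of [spherical_roi()]
#' @export
read_rois <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    spherical_roi(df$label[i], df$bone[i],
                  c(df$cx[i], df$cy[i], df$cz[i]), df$radius[i],
                  df$mode[i]))
}

#' Write a posture file
#' @param pose a [posture()]
#' @param path output file
#' @export
write_posture <- function(pose, path) {
  pose <- as_posture(pose)
  writeLines(c("# trabpose posture v1",
               paste0(DOF_NAMES, "_deg: ",
                      fmt_num(unclass(pose)[DOF_NAMES]))), path)
  invisible(path)
}

#' Read a posture file
#' @param path file written by [write_posture()]
#' @return a [posture()]
#' @export
read_posture <- function(path) {
  v <- read_kv(path, "# trabpose posture v1")
  vals <- as.numeric(v[paste0(DOF_NAMES, "_deg")])
  do.call(posture, as.list(stats::setNames(vals, DOF_NAMES)))
}

#' Write a complete synthetic fixture set
#'
#' Emits the model spec, fabric-field table, ROI table, the hidden true
#' posture, and a JSON manifest recording the seed and parameters.
#' Everything round-trips losslessly through the package readers.
#'
#' @param template a `species_template`
#' @param scenario a [fabric_scenario()]
#' @param directory output directory (created if needed)
#' @param model optional prebuilt `model_spec`
#' @return named character vector of the files written
#' @export
write_fixtures <- function(template, scenario, directory, model = NULL) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  if (is.null(model)) model <- model_spec(template)
  rois <- scenario$rois %||% default_rois(template)
  scenario$rois <- rois
  fabric <- generate_fabric_field(template, scenario, model)
  paths <- c(model = file.path(directory, "model.spec"),
             fabric = file.path(directory, "fabric.tsv"),
             rois = file.path(directory, "rois.tsv"),
             posture = file.path(directory, "true_posture.txt"),
             manifest = file.path(directory, "manifest.json"))
  write_model_spec(model, paths[["model"]])
  write_fabric_field(fabric, paths[["fabric"]])
  write_rois(rois, paths[["rois"]])
  write_posture(scenario$true_posture, paths[["posture"]])
  jsonlite::write_json(list(
    format = "trabpose fixture manifest v1",
    template = template$name,
    rng_seed = scenario$rng_seed,
    axial_concentration = scenario$axial_concentration,
    lattice_spacing = scenario$lattice_spacing %||%
      (template$femur_length / 40),
    n_lattice_points = nrow(fabric),
    package_version = as.character(utils::packageVersion("trabpose"))
  ), paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
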