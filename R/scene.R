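# Scene configuration (YAML), validation, fixture generation and run
# manifests. Units are fixed: micrometres and radians throughout.

scene_schema <- list(
  top = c("schema_version", "units", "seed", "media", "fluorophores",
          "objects", "sources", "detectors"),
  medium = c("mu_a", "mu_s", "particle_diameter", "medium_index",
             "particle_index", "wavelength"),
  fluorophore = c("l_f", "p_f", "emission_wavelengths", "emission_weights",
                  "excitation_band", "quantum_yield"),
  object = c("id", "type", "thickness", "medium", "fluorophore", "file",
             "absorbers"),
  absorber = c("point", "axis", "radius", "mu_a"),
  source = c("type", "n_rays", "wavelength", "polarization", "radius",
             "origin", "direction"),
  detector = c("id", "nx", "ny", "pitch", "center", "mode", "magnification",
               "pinhole_radius")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(TRUE)
}

#' Load and validate a scene configuration
#'
#' Reads a YAML scene description (geometry objects with media assignments,
#' sources, detectors, a mandatory global seed) and validates it strictly:
#' unknown keys, references to undefined media or fluorophores, a missing
#' seed, and non-watertight fluorescent meshes are all errors.
#'
#' @param file Path to a YAML scene file.
#' @param base_dir Directory for resolving relative mesh paths (defaults to
#'   the config's directory).
#' @return An object of class `scene` (validated named list).
#' @export
load_scene <- function(file, base_dir = dirname(file)) {
  cfg <- yaml::read_yaml(file)
  validate_scene(cfg, base_dir = base_dir)
}

#' Validate a scene list
#'
#' @param cfg Scene as a named list (parsed YAML).
#' @param base_dir Directory for resolving mesh paths.
#' @return The validated `scene` object.
#' @export
validate_scene <- function(cfg, base_dir = ".") {
  check_keys(cfg, scene_schema$top, "scene")
  if (is.null(cfg$schema_version)) stop("scene must declare schema_version")
  if (is.null(cfg$seed))
    stop("scene must declare a seed (reproducibility is mandatory)")
  if (!is.null(cfg$units) && cfg$units != "micron")
    stop("units must be 'micron'")
  for (nm in names(cfg$media))
    check_keys(cfg$media[[nm]], scene_schema$medium, paste0("media/", nm))
  for (nm in names(cfg$fluorophores))
    check_keys(cfg$fluorophores[[nm]], scene_schema$fluorophore,
               paste0("fluorophores/", nm))
  ids <- character(0)
  for (obj in cfg$objects) {
    check_keys(obj, scene_schema$object, paste0("object '", obj$id %||% "?", "'"))
    if (is.null(obj$id)) stop("every object needs an id")
    if (obj$id %in% ids) stop("duplicate object id: ", obj$id)
    ids <- c(ids, obj$id)
    if (is.null(obj$medium) || !obj$medium %in% names(cfg$media))
      stop("object '", obj$id, "' references undefined medium '",
           obj$medium %||% "<missing>", "'")
    if (!is.null(obj$fluorophore) &&
        !obj$fluorophore %in% names(cfg$fluorophores))
      stop("object '", obj$id, "' references undefined fluorophore '",
           obj$fluorophore, "'")
    if (identical(obj$type, "mesh")) {
      path <- file.path(base_dir, obj$file)
      if (!file.exists(path)) stop("mesh file not found: ", path)
      if (!is.null(obj$fluorophore)) {
        mesh <- read_stl(path)
        if (!mesh_is_watertight(mesh))
          stop("fluorescent mesh '", obj$id, "' is not watertight")
      }
    }
    for (ab in obj$absorbers)
      check_keys(ab, scene_schema$absorber,
                 paste0("object '", obj$id, "' absorber"))
  }
  for (src in cfg$sources)
    check_keys(src, scene_schema$source, "source")
  for (det in cfg$detectors)
    check_keys(det, scene_schema$detector,
               paste0("detector '", det$id %||% "?", "'"))
  structure(cfg, class = "scene", base_dir = base_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a scene back to YAML
#'
#' @param scene A `scene` object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
save_scene <- function(scene, file) {
  yaml::write_yaml(unclass(scene), file)
  invisible(file)
}

#' Materialize a scene medium
#'
#' @param scene A `scene`.
#' @param name Medium name.
#' @param build_tables Build phase tables immediately?
#' @return A [medium_optics()].
#' @export
scene_medium <- function(scene, name, build_tables = FALSE) {
  m <- scene$media[[name]]
  if (is.null(m)) stop("undefined medium: ", name)
  spec <- NULL
  if ((m$mu_s %||% 0) > 0)
    spec <- scatterer_spec(m$particle_diameter, m$medium_index,
                           m$particle_index, m$wavelength)
  med <- medium_optics(m$mu_a %||% 0, m$mu_s %||% 0, spec)
  if (build_tables) med <- ensure_tables(med)
  med
}

#' Materialize a scene fluorophore
#'
#' @param scene A `scene`.
#' @param name Fluorophore name.
#' @return A [fluorophore_spec()].
#' @export
scene_fluorophore <- function(scene, name) {
  f <- scene$fluorophores[[name]]
  if (is.null(f)) stop("undefined fluorophore: ", name)
  fluorophore_spec(f$l_f, f$p_f, unlist(f$emission_wavelengths),
                   unlist(f$emission_weights),
                   unlist(f$excitation_band %||% c(0, Inf)),
                   f$quantum_yield %||% 1)
}

scene_geometry_for <- function(scene, obj) {
  if (identical(obj$type, "slab")) {
    abs_list <- lapply(obj$absorbers, function(ab)
      cylinder_absorber(unlist(ab$point), unlist(ab$axis), ab$radius, ab$mu_a))
    slab_geometry(obj$thickness, abs_list)
  } else if (identical(obj$type, "mesh")) {
    mesh_geometry(read_stl(file.path(attr(scene, "base_dir") %||% ".",
                                     obj$file)))
  } else stop("unknown object type: ", obj$type)
}

scene_source_rays <- function(scene, src = scene$sources[[1]]) {
  pol <- unlist(src$polarization)
  jones <- if (length(pol) == 4)
    complex(real = pol[c(1, 3)], imaginary = pol[c(2, 4)]) else as.complex(pol)
  launch_collimated(src$n_rays, jones = jones, wavelength = src$wavelength,
                    origin = unlist(src$origin %||% c(0, 0, 0)),
                    radius = src$radius %||% 0,
                    direction = unlist(src$direction %||% c(0, 0, 1)))
}

scene_detector <- function(det) {
  detector_spec(det$nx, det$ny, det$pitch,
                center = unlist(det$center %||% c(0, 0)),
                mode = det$mode %||% "direct",
                magnification = det$magnification %||% 1)
}

#' Run the transport experiment described by a scene
#'
#' Launches the first source into the first object and accumulates every
#' configured detector. Slab objects with a fluorophore assignment run the
#' fluorescent transport kernel.
#'
#' @param scene A validated `scene`.
#' @param max_events Event cap per ray.
#' @return A list: `result` (transport or fluorescence result), `images`
#'   (named list of [accumulate_detector()] images over transmitted rays),
#'   `seed`.
#' @export
run_scene_transport <- function(scene, max_events = 10000L) {
  stopifnot(inherits(scene, "scene"))
  set.seed(scene$seed, kind = "Mersenne-Twister")
  obj <- scene$objects[[1]]
  medium <- scene_medium(scene, obj$medium)
  geometry <- scene_geometry_for(scene, obj)
  rays <- scene_source_rays(scene)
  result <- if (!is.null(obj$fluorophore)) {
    propagate_fluorescent_medium(rays, medium,
                                 scene_fluorophore(scene, obj$fluorophore),
                                 geometry, max_events = max_events)
  } else {
    propagate_through_medium(rays, medium, geometry, max_events = max_events)
  }
  trans <- result$exits[result$exits$status %in% c("transmitted", "exited",
                                                   "emitted"), ]
  images <- list()
  for (det in scene$detectors)
    images[[det$id]] <- accumulate_detector(trans, scene_detector(det))
  list(result = result, images = images, seed = scene$seed)
}

# ---------------------------------------------------------------------------
# Fixture generation

#' Generate synthetic scenes and meshes
#'
#' Deterministic fixture generators standing in for CAD sample models:
#' \describe{
#'   \item{`slab_phantom`}{Homogeneous scattering/absorbing slab with a
#'     collimated polarized source and a transmission detector.}
#'   \item{`rod_in_slab`}{The slab phantom with an embedded absorbing
#'     cylinder (vessel rod).}
#'   \item{`mueller_slab`}{A backscattering slab configured for the
#'     Mueller-matrix protocol.}
#'   \item{`neuron_like_mesh`}{A watertight neuron-like mesh: icosphere soma
#'     with cylindrical dendrites (separate closed components; interior =
#'     union). Parameters yielding overlapping dendrites are rejected.}
#' }
#'
#' @param kind One of `"slab_phantom"`, `"rod_in_slab"`,
#'   `"neuron_like_mesh"`, `"mueller_slab"`.
#' @param params Named list of overrides (see Details in the code; all have
#'   defaults).
#' @param seed Integer seed; fixes every random choice.
#' @param dir Optional directory: scene YAML (and STL mesh) files are written
#'   there.
#' @return A list with `scene` (a validated `scene`, where applicable),
#'   `mesh` (a `tri_mesh`, for mesh fixtures) and `files` (paths written).
#' @export
generate_fixture <- function(kind = c("slab_phantom", "rod_in_slab",
                                      "neuron_like_mesh", "mueller_slab"),
                             params = list(), seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  set.seed(seed, kind = "Mersenne-Twister")
  p <- function(name, default) params[[name]] %||% default
  files <- character(0)
  base_media <- list(
    tissue = list(mu_a = p("mu_a", 0.001), mu_s = p("mu_s", 0.05),
                  particle_diameter = p("particle_diameter", 0.1),
                  medium_index = p("medium_index", 1.33),
                  particle_index = p("particle_index", 1.59),
                  wavelength = p("wavelength", 0.488)))
  scene <- NULL; mesh <- NULL
  if (kind %in% c("slab_phantom", "rod_in_slab", "mueller_slab")) {
    obj <- list(id = "slab", type = "slab",
                thickness = p("thickness", 40), medium = "tissue")
    if (kind == "rod_in_slab")
      obj$absorbers <- list(list(point = c(0, 0, p("rod_depth", 20)),
                                 axis = c(0, 1, 0),
                                 radius = p("rod_radius", 5),
                                 mu_a = p("rod_mu_a", 0.2)))
    scene <- validate_scene(list(
      schema_version = 1, units = "micron", seed = seed,
      media = base_media,
      objects = list(obj),
      sources = list(list(type = "collimated", n_rays = p("n_rays", 10000L),
                          wavelength = p("wavelength", 0.488),
                          polarization = c(1, 0),
                          radius = p("beam_radius", 0))),
      detectors = list(list(id = "det", nx = p("det_nx", 64L),
                            ny = p("det_ny", 64L),
                            pitch = p("det_pitch", 2)))))
  }
  if (kind == "neuron_like_mesh") {
    soma_r <- p("soma_radius", 5)
    n_d <- p("n_dendrites", 4L)
    len <- p("dendrite_length", 15)
    rad <- p("dendrite_radius", 1)
    min_sep <- 2 * asin(min(1, 1.2 * rad / soma_r)) + 0.2
    dirs <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(dirs) < n_d) {
      tries <- tries + 1L
      if (tries > 500L)
        stop("cannot place ", n_d, " non-intersecting dendrites with these ",
             "parameters (self-intersecting mesh)")
      d <- isotropic_directions(1)
      ok <- !nrow(dirs) ||
        all(acos(pmin(1, as.numeric(dirs %*% t(d)))) > min_sep)
      if (ok) dirs <- rbind(dirs, d)
    }
    parts <- list(make_icosphere(soma_r, subdiv = p("subdiv", 2L)))
    for (i in seq_len(n_d))
      parts[[i + 1L]] <- make_cylinder_mesh(
        0.5 * soma_r * dirs[i, ], (soma_r + len) * dirs[i, ], rad,
        nseg = p("cyl_segments", 12L))
    mesh <- merge_meshes(parts)
    if (!is.null(params$dimensions)) {
      dims <- rep_len(unlist(params$dimensions), 3)
      bb <- mesh_bbox(mesh)
      ctr <- (bb[1, ] + bb[2, ]) / 2
      mesh <- mesh_fit_bbox(mesh, ctr - dims / 2, ctr + dims / 2)
    }
    if (!mesh_is_watertight(mesh)) stop("generated mesh is not watertight")
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(mesh)) {
      f <- file.path(dir, paste0(kind, "_seed", seed, ".stl"))
      write_stl(mesh, f, name = kind)
      files <- c(files, f)
    }
    if (!is.null(scene)) {
      f <- file.path(dir, paste0(kind, "_seed", seed, ".yaml"))
      save_scene(scene, f)
      files <- c(files, f)
    }
  }
  list(scene = scene, mesh = mesh, files = files)
}

#' Write a reproducibility manifest
#'
#' Records the configuration hash, seed and software versions needed to
#' reproduce a run byte-for-byte (deterministic stages) or statistically
#' (stochastic stages).
#'
#' @param file Output JSON path.
#' @param seed Integer seed of the run.
#' @param config_path Optional scene file; its MD5 is recorded.
#' @param extra Named list of additional entries (ray budgets, ledgers, ...).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(file, seed, config_path = NULL, extra = list()) {
  man <- c(list(
    seed = seed,
    config_hash = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    package = "polmc",
    package_version = as.character(utils::packageVersion("polmc")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(man, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}
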