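#' Lighting configuration and presets
#'
#' Phong shading terms for the interior renderer.  Three presets mirror the
#' rendering models compared in the pipeline: `baseline` (pure global diffuse
#' with wireframe edges in contrasting colors), `customsurface` (full ambient
#' plus 30% diffuse, edges kept), and `customlight` (0% ambient, 50% diffuse,
#' 10% specular, a headlight placed just behind the camera, no edges) which
#' imitates the co-located illumination of a real ureteroscope.
#'
#' @param ambient,diffuse,specular Phong term weights in `[0, 1]`.
#' @param specular_exponent Shininess exponent (> 0).
#' @param headlight Place the light at the camera (offset slightly behind it)
#'   instead of using a global directional light.
#' @param render_edges Overlay wireframe edges cycling through `edge_palette`.
#' @param edge_palette `k x 3` matrix of RGB colors in `[0, 1]`.
#' @param edge_fraction Barycentric width of the edge overlay.
#' @param base_color Surface RGB (solid, textureless).
#' @param background Background RGB for rays that miss the mesh.
#' @param light_dir Unit vector pointing toward the global light (used when
#'   `headlight = FALSE`).
#' @param headlight_offset_mm Headlight offset behind the camera (default 1).
#' @param falloff Enable inverse-square light falloff for the headlight.
#' @param falloff_ref_mm Distance at which falloff attenuation reaches 1.
#' @export
lighting_config <- function(ambient = 0, diffuse = 1, specular = 0,
                            specular_exponent = 20, headlight = FALSE,
                            render_edges = FALSE,
                            edge_palette = default_edge_palette(),
                            edge_fraction = 0.05,
                            base_color = c(0.8, 0.8, 0.8),
                            background = c(0, 0, 0),
                            light_dir = c(1, 1, 1) / sqrt(3),
                            headlight_offset_mm = 1,
                            falloff = FALSE, falloff_ref_mm = 10) {
  for (nm in c("ambient", "diffuse", "specular")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) stopf("%s must be a fraction in [0, 1]", nm)
  }
  if (specular_exponent <= 0) stopf("specular_exponent must be > 0")
  structure(list(ambient = ambient, diffuse = diffuse, specular = specular,
                 specular_exponent = specular_exponent, headlight = headlight,
                 render_edges = render_edges,
                 edge_palette = as.matrix(edge_palette),
                 edge_fraction = edge_fraction,
                 base_color = as.numeric(base_color),
                 background = as.numeric(background),
                 light_dir = unitv(as.numeric(light_dir)),
                 headlight_offset_mm = headlight_offset_mm,
                 falloff = falloff, falloff_ref_mm = falloff_ref_mm),
            class = "uro_lighting")
}

default_edge_palette <- function() {
  rbind(c(0.9, 0.2, 0.2), c(0.2, 0.9, 0.2), c(0.2, 0.4, 0.9),
        c(0.9, 0.9, 0.2), c(0.2, 0.9, 0.9))
}

#' @rdname lighting_config
#' @param preset One of `"baseline"`, `"customsurface"`, `"customlight"`.
#' @param ... Overrides passed to [lighting_config()].
#' @export
lighting_preset <- function(preset = c("baseline", "customsurface", "customlight"),
                            ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    baseline      = list(ambient = 0, diffuse = 1, specular = 0,
                         render_edges = TRUE, headlight = FALSE),
    customsurface = list(ambient = 1, diffuse = 0.3, specular = 0,
                         render_edges = TRUE, headlight = FALSE),
    customlight   = list(ambient = 0, diffuse = 0.5, specular = 0.1,
                         render_edges = FALSE, headlight = TRUE))
  do.call(lighting_config, utils::modifyList(args, list(...)))
}

#' Render a mesh interior view
#'
#' Perspective ray casting with first-hit ray-triangle intersection and Phong
#' shading `I = ambient*C + diffuse*C*max(0, n.l) + specular*max(0, r.v)^e`.
#' With a headlight, the light sits at the camera position displaced by a
#' small offset along the negative view direction.  Rays that miss the mesh
#' produce the background color.  Deterministic: identical inputs give
#' identical images.
#'
#' @param mesh A [uro_mesh()] with at least one face.
#' @param pose A [camera_pose()].
#' @param cfg A [lighting_config()].
#' @param resolution `c(height, width)` in pixels.
#' @return `uro_image`: an `H x W x 3` array in `[0, 1]`.
#' @export
render <- function(mesh, pose, cfg = lighting_preset("customlight"),
                   resolution = c(128L, 128L)) {
  stopifnot(inherits(mesh, "uro_mesh"), inherits(pose, "uro_pose"),
            inherits(cfg, "uro_lighting"))
  if (nrow(mesh$faces) == 0L) stopf("cannot render an empty mesh")
  resolution <- as.integer(resolution)
  if (length(resolution) != 2L || any(resolution < 1L))
    stopf("resolution must be two positive integers (height, width)")
  img <- cpp_render(mesh$vertices, mesh$faces,
                    pose$position, pose$view_dir, pose$up, pose$vfov_deg,
                    resolution[2], resolution[1],
                    list(ambient = cfg$ambient, diffuse = cfg$diffuse,
                         specular = cfg$specular,
                         specular_exponent = cfg$specular_exponent,
                         headlight = cfg$headlight, falloff = cfg$falloff,
                         falloff_ref_mm = cfg$falloff_ref_mm,
                         headlight_offset_mm = cfg$headlight_offset_mm,
                         render_edges = cfg$render_edges,
                         edge_fraction = cfg$edge_fraction,
                         base_color = cfg$base_color,
                         background = cfg$background,
                         light_dir = cfg$light_dir,
                         edge_palette = cfg$edge_palette))
  structure(img, class = "uro_image")
}

#' Render a full trajectory
#'
#' @param mesh A [uro_mesh()].
#' @param poses List of [camera_pose()]s (e.g. from [sample_trajectory()]).
#' @param cfg A [lighting_config()].
#' @param resolution `c(height, width)`.
#' @return List of `uro_image`s.
#' @export
render_trajectory <- function(mesh, poses, cfg = lighting_preset("customlight"),
                              resolution = c(128L, 128L)) {
  lapply(poses, function(p) render(mesh, p, cfg, resolution))
}

#' Read/write images as PNG
#'
#' @param img `uro_image` (or plain `H x W x 3` array in `[0, 1]`).
#' @param path PNG file path.
#' @export
write_image <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  structure(arr, class = "uro_image")
}
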