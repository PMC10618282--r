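#' Conductivity interface
#'
#' Pairs one closed surface with the conductivities just inside and just
#' outside of it, relative to the outward facet normal direction.
#'
#' @param mesh a closed, outward-oriented [triangle_mesh()].
#' @param sigma_in,sigma_out conductivities in S/m (non-negative, not both
#'   zero).
#' @param name interface label.
#' @return object of class `bem_interface`.
#' @export
interface <- function(mesh, sigma_in, sigma_out, name = "interface") {
  if (sigma_in < 0 || sigma_out < 0)
    stop("conductivities must be non-negative")
  if (sigma_in == 0 && sigma_out == 0)
    stop("sigma_in = sigma_out = 0: conductivity contrast undefined")
  structure(list(mesh = mesh, sigma_in = sigma_in, sigma_out = sigma_out,
                 name = name),
            class = "bem_interface")
}

#' SimNIBS-style default tissue conductivities
#'
#' Shipped as configuration, not ground truth: scalp 0.465, bone 0.010,
#' CSF 1.654, gray matter 0.275, white matter 0.126 S/m.
#'
#' @return named numeric vector, S/m.
#' @export
default_conductivities <- function() {
  c(scalp = 0.465, bone = 0.010, csf = 1.654, gm = 0.275, wm = 0.126)
}

#' Assemble a multi-compartment head model
#'
#' Concatenates the facets of all interfaces into flat arrays and computes
#' the per-facet conductivity contrast
#' `K = (sigma_in - sigma_out) / (sigma_in + sigma_out)`, which satisfies
#' `|K| <= 1` for non-negative conductivities.  Every closed surface is
#' treated independently through its own `(sigma_in, sigma_out)` pair;
#' nesting consistency is the caller's responsibility (see `audit_nesting`).
#'
#' @param interfaces list of [interface()] objects, conventionally outermost
#'   first.
#' @param audit_nesting if `TRUE`, sample vertices of each interface after
#'   the first are tested for containment in the first (outermost) surface.
#' @return object of class `head_model` with flat per-facet arrays
#'   (`tri9`, `centroids`, `normals`, `areas`, `circumradii`, `K`,
#'   `sigma_in`, `sigma_out`, `interface_id`) and the interface list.
#' @export
build_head_model <- function(interfaces, audit_nesting = FALSE) {
  if (inherits(interfaces, "bem_interface")) interfaces <- list(interfaces)
  if (!length(interfaces)) stop("no interfaces")
  ok <- vapply(interfaces, inherits, logical(1), "bem_interface")
  if (!all(ok)) stop("interfaces must be bem_interface objects")
  nf <- vapply(interfaces, function(s) nrow(s$mesh$triangles), integer(1))
  tri9 <- do.call(rbind, lapply(interfaces, function(s) facet_matrix(s$mesh)))
  centroids <- do.call(rbind, lapply(interfaces, function(s) s$mesh$centroids))
  normals <- do.call(rbind, lapply(interfaces, function(s) s$mesh$normals))
  areas <- unlist(lapply(interfaces, function(s) s$mesh$areas))
  rho <- unlist(lapply(interfaces, function(s) s$mesh$circumradii))
  s_in <- rep(vapply(interfaces, `[[`, numeric(1), "sigma_in"), nf)
  s_out <- rep(vapply(interfaces, `[[`, numeric(1), "sigma_out"), nf)
  K <- (s_in - s_out) / (s_in + s_out)
  iid <- rep(seq_along(interfaces), nf)
  if (audit_nesting && length(interfaces) > 1) {
    outer_mesh <- interfaces[[1]]$mesh
    for (k in seq_along(interfaces)[-1]) {
      vv <- interfaces[[k]]$mesh$vertices
      smp <- vv[unique(round(seq(1, nrow(vv), length.out = 25))), ,
                drop = FALSE]
      if (!all(point_in_mesh(outer_mesh, smp)))
        warning("interface ", k, " (", interfaces[[k]]$name,
                ") has sampled vertices outside interface 1")
    }
  }
  structure(list(interfaces = interfaces, n_facets = sum(nf),
                 facets_per_interface = nf, tri9 = tri9,
                 centroids = centroids, normals = normals, areas = areas,
                 circumradii = rho, K = K, sigma_in = s_in,
                 sigma_out = s_out, interface_id = iid),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("head_model: %d interfaces, %d facets\n",
              length(x$interfaces), x$n_facets))
  for (k in seq_along(x$interfaces)) {
    s <- x$interfaces[[k]]
    cat(sprintf("  %d. %-12s %6d facets  sigma_in=%.3g sigma_out=%.3g  K=%+.3f\n",
                k, s$name, x$facets_per_interface[k], s$sigma_in, s$sigma_out,
                (s$sigma_in - s$sigma_out) / (s$sigma_in + s$sigma_out)))
  }
  invisible(x)
}

#' Four-layer sphere head model
#'
#' Synthetic nested-sphere model (scalp, skull, CSF, brain by default) used
#' for validation against the analytic spherically-symmetric-conductor
#' solution.
#'
#' @param radii strictly decreasing interface radii in meters
#'   (outermost first).
#' @param sigmas conductivities of the media enclosed by each interface,
#'   S/m, same length as `radii`; the medium outside the first interface is
#'   air (0 S/m).
#' @param subdiv_level icosphere subdivision level per interface.
#' @return a `head_model`.
#' @export
nested_sphere_model <- function(radii = c(0.092, 0.086, 0.080, 0.078),
                                sigmas = c(0.465, 0.010, 1.654, 0.275),
                                subdiv_level = 3L) {
  if (length(radii) != length(sigmas))
    stop("radii and sigmas must have the same length")
  meshes <- make_nested_spheres(radii, subdiv_level)
  sig_out <- c(0, sigmas[-length(sigmas)])
  names <- if (length(radii) == 4) c("scalp", "skull", "csf", "brain") else
    paste0("layer", seq_along(radii))
  build_head_model(mapply(function(m, si, so, nm) interface(m, si, so, nm),
                          meshes, sigmas, sig_out, names,
                          SIMPLIFY = FALSE))
}

#' Read a head-model manifest
#'
#' YAML manifest listing one STL file per interface:
#' ```yaml
#' interfaces:
#'   - stl: scalp.stl
#'     name: scalp
#'     sigma_in: 0.465
#'     sigma_out: 0
#'     unit_scale: 0.001
#' ```
#' Relative STL paths are resolved against the manifest directory.
#'
#' @param path manifest file path.
#' @return a `head_model`.
#' @export
read_head_manifest <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$interfaces)) stop("manifest has no 'interfaces' list")
  base <- dirname(normalizePath(path))
  ifs <- lapply(cfg$interfaces, function(e) {
    stl <- e$stl
    if (!file.exists(stl)) stl <- file.path(base, e$stl)
    mesh <- load_stl(stl, unit_scale = if (is.null(e$unit_scale)) 1 else
      e$unit_scale)
    interface(mesh, e$sigma_in, e$sigma_out,
              name = if (is.null(e$name)) basename(e$stl) else e$name)
  })
  build_head_model(ifs)
}
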