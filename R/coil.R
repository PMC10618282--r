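#' TMS coil as elementary current elements
#'
#' A coil is a table of elementary current elements: positions and oriented
#' length vectors ("moments": direction x segment length x winding weight)
#' plus the current slew rate dI/dt.  The primary (free-space, inductive)
#' E-field is `E_p(r) = -(mu0/4pi) * didt * sum_j m_j / |r - p_j|`.
#'
#' @param positions n x 3 matrix of element positions, meters.
#' @param moments n x 3 matrix of oriented length vectors, meters.
#' @param didt current slew rate, A/s.
#' @param name coil label.
#' @return object of class `coil_model`.
#' @export
coil_model <- function(positions, moments, didt = 9.4e7, name = "coil") {
  positions <- as.matrix(positions)
  moments <- as.matrix(moments)
  if (ncol(positions) != 3 || ncol(moments) != 3 ||
      nrow(positions) != nrow(moments) || nrow(positions) < 1)
    stop("positions and moments must be matching n x 3 matrices, n >= 1")
  if (!all(is.finite(positions)) || !all(is.finite(moments)) ||
      !is.finite(didt))
    stop("coil model entries must be finite")
  structure(list(positions = positions, moments = moments,
                 didt = didt, name = name),
            class = "coil_model")
}

#' @export
print.coil_model <- function(x, ...) {
  cat(sprintf("coil_model '%s': %d current elements, dI/dt = %.4g A/s\n",
              x$name, nrow(x$positions), x$didt))
  invisible(x)
}

#' Parametric figure-of-eight coil
#'
#' Two coplanar circular wings with opposite winding sense, centered at the
#' origin in the z = 0 plane; the coil axis is +z and the handle direction
#' +x.  Each wing is a closed polygonal loop of `segments_per_turn` chords,
#' repeated `turns` times, so the per-wing vector sum of moments vanishes.
#'
#' @param radius wing radius, meters.
#' @param turns number of turns per wing.
#' @param segments_per_turn polygon segments per turn (>= 8).
#' @param wing_separation distance between the two wing centers, meters.
#' @param didt current slew rate, A/s.
#' @param name coil label.
#' @return a [coil_model()] with `2 * turns * segments_per_turn` elements.
#' @export
build_figure8_coil <- function(radius = 0.035, turns = 1L,
                               segments_per_turn = 64L,
                               wing_separation = 2 * radius,
                               didt = 9.4e7, name = "figure8") {
  if (radius <= 0) stop("radius must be > 0")
  if (segments_per_turn < 8) stop("segments_per_turn must be >= 8")
  ang <- 2 * pi * (seq_len(segments_per_turn) - 0.5) / segments_per_turn
  ang0 <- 2 * pi * (seq_len(segments_per_turn) - 1) / segments_per_turn
  ang1 <- 2 * pi * seq_len(segments_per_turn) / segments_per_turn
  one_wing <- function(cx, sense) {
    pos <- cbind(cx + radius * cos(ang), radius * sin(ang), 0)
    mom <- cbind(radius * (cos(ang1) - cos(ang0)),
                 radius * (sin(ang1) - sin(ang0)), 0) * sense
    list(pos = pos[rep(seq_len(segments_per_turn), turns), , drop = FALSE],
         mom = mom[rep(seq_len(segments_per_turn), turns), , drop = FALSE])
  }
  left <- one_wing(-wing_separation / 2, +1)
  right <- one_wing(+wing_separation / 2, -1)
  coil_model(rbind(left$pos, right$pos), rbind(left$mom, right$mom),
             didt = didt, name = name)
}

#' Rigid coil placement
#'
#' Rigidly transforms a coil built in its own frame (axis +z, handle +x,
#' centered at the origin) so that the coil axis fires along `axis_dir`
#' (unit vector pointing from the coil into the head), the handle points
#' along `handle_dir`, and the coil center sits at
#' `target - standoff * axis_dir` (i.e. `standoff` meters back from the
#' target along the firing axis).  Moments are rotated, never scaled.
#'
#' @param coil a [coil_model()].
#' @param target stimulation target point, meters.
#' @param axis_dir coil firing direction (into the head).
#' @param handle_dir handle direction; re-orthogonalized against `axis_dir`
#'   when the two are not perpendicular within 1e-6.
#' @param standoff distance from target to coil center along the axis,
#'   meters.
#' @return the transformed `coil_model`.
#' @export
place_coil <- function(coil, target, axis_dir, handle_dir, standoff = 0) {
  a <- as.numeric(axis_dir)
  h <- as.numeric(handle_dir)
  na <- sqrt(sum(a^2))
  nh <- sqrt(sum(h^2))
  if (na == 0 || nh == 0) stop("direction vectors must be non-zero")
  a <- a / na
  h <- h / nh
  if (abs(sum(a * h)) > 1e-6) {
    h <- h - sum(a * h) * a
    nh <- sqrt(sum(h^2))
    if (nh == 0) stop("handle_dir is parallel to axis_dir")
    h <- h / nh
  }
  zhat <- -a                      # coil +z maps away from the head
  xhat <- h
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  R <- cbind(xhat, yhat, zhat)
  center <- as.numeric(target) - standoff * a
  coil_model(sweep(coil$positions %*% t(R), 2, center, `+`),
             coil$moments %*% t(R), didt = coil$didt, name = coil$name)
}

#' Primary (free-space) coil E-field
#'
#' Evaluates `E_p(r) = -(mu0/4pi) * didt * sum_j m_j / |r - p_j|` with
#' `mu0/4pi = 1e-7` exactly.  The default is exact pairwise summation; the
#' `"tree"` backend uses a Barnes-Hut treecode accurate to about the
#' requested precision.
#'
#' @param coil a [coil_model()].
#' @param points n x 3 matrix of observation points, meters.
#' @param backend `"exact"` or `"tree"`.
#' @param precision requested relative accuracy for the tree backend (one
#'   of 1e-1 ... 1e-6).
#' @return n x 3 matrix of E-field vectors, V/m.
#' @export
primary_efield <- function(coil, points, backend = c("exact", "tree"),
                           precision = 1e-4) {
  backend <- match.arg(backend)
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("points must be finite")
  S <- if (backend == "exact")
    cpp_vecpot_sum(coil$positions, coil$moments, points, 1e-12)
  else
    cpp_tree_vecpot(coil$positions, coil$moments, points,
                    tree_theta(precision, "potential"), 1e-12)
  -1e-7 * coil$didt * S
}

#' Write / read a coil element table
#'
#' Delimited text, one row per element (`x,y,z,mx,my,mz`, meters), with
#' `# name:` and `# didt:` header comments.
#'
#' @param coil a [coil_model()].
#' @param path file path.
#' @export
write_coil_csv <- function(coil, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# name:", coil$name),
               paste("# didt:", format(coil$didt, digits = 17)),
               "x,y,z,mx,my,mz"), con)
  utils::write.table(cbind(coil$positions, coil$moments), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coil_csv
#' @param didt optional override of the dI/dt stored in the file, A/s.
#' @export
read_coil_csv <- function(path, didt = NULL) {
  if (!file.exists(path)) stop("coil file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  name <- sub("^#\\s*name:\\s*", "", grep("name:", hdr, value = TRUE)[1])
  file_didt <- as.numeric(sub("^#\\s*didt:\\s*", "",
                              grep("didt:", hdr, value = TRUE)[1]))
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.table(text = body, sep = ",", header = TRUE)
  coil_model(as.matrix(dat[, 1:3]), as.matrix(dat[, 4:6]),
             didt = if (is.null(didt)) file_didt else didt,
             name = if (is.na(name)) "coil" else name)
}
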