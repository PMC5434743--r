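## Source space construction: triangulated cortical sphere, discrete
## surface Laplacian, analytic multilayer-sphere lead field, and named ROI
## gridpoint sets.
##
## Geometry convention: x right, y anterior, z superior, units meters.
## Default shell boundaries 0.087 / 0.092 / 0.100 m (brain | skull | scalp)
## with the cortical mesh at 0.082 m so every dipole sits strictly inside
## the innermost compartment.

#' Build a triangulated spherical source mesh
#'
#' Subdivided icosahedron projected onto a sphere: `10 * 4^s + 2` vertices
#' at subdivision level `s`. Vertex normals are the outward radial unit
#' vectors, which is also the fixed dipole orientation used by the lead
#' field (cortical pyramidal cells are oriented normally to the surface).
#'
#' @param subdivisions non-negative integer subdivision level.
#' @param radius sphere radius in meters.
#' @return A `source_mesh` with `vertices` (`G x 3`), `triangles`
#'   (`F x 3`, 1-based), `normals` (`G x 3`) and `radius`.
#' @export
build_source_mesh <- function(subdivisions = 3, radius = 0.082) {
  stopifnot(subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- edge_mid[[key]]
      if (!is.null(hit)) return(hit)
      m <- vlist[[a]] + vlist[[b]]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      idx <- length(vlist)
      edge_mid[[key]] <- idx
      idx
    }
    fnew <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      fnew[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- fnew
  }
  structure(list(vertices = v * radius, triangles = f, normals = v,
                 radius = radius),
            class = "source_mesh")
}

#' @export
print.source_mesh <- function(x, ...) {
  cat(sprintf("<source_mesh> %d vertices, %d triangles, radius %g m\n",
              nrow(x$vertices), nrow(x$triangles), x$radius))
  invisible(x)
}

mesh_edges <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  unique(e)
}

#' Discrete surface Laplacian of a mesh
#'
#' Uniform graph Laplacian (vertex degree minus adjacency) by default;
#' `weighting = "cotangent"` uses the cotangent scheme. Both are symmetric
#' positive semidefinite with the constant vector in the null space.
#'
#' @param mesh a [build_source_mesh()] result.
#' @param weighting `"graph"` or `"cotangent"`.
#' @return A dense `G x G` symmetric matrix with zero row sums.
#' @export
surface_laplacian <- function(mesh, weighting = c("graph", "cotangent")) {
  weighting <- match.arg(weighting)
  G <- nrow(mesh$vertices)
  L <- matrix(0, G, G)
  if (weighting == "graph") {
    e <- mesh_edges(mesh)
    for (i in seq_len(nrow(e))) {
      a <- e[i, 1]; b <- e[i, 2]
      L[a, b] <- L[a, b] - 1
      L[b, a] <- L[b, a] - 1
    }
  } else {
    v <- mesh$vertices
    cot_at <- function(p, q, r) { # angle at p in triangle pqr
      u <- q - p; w <- r - p
      cr <- sqrt(sum(crossprod3(u, w)^2))
      if (cr < 1e-15) stop("degenerate triangle encountered")
      sum(u * w) / cr
    }
    for (t in seq_len(nrow(mesh$triangles))) {
      tri <- mesh$triangles[t, ]
      for (k in 1:3) {
        p <- tri[k]; q <- tri[k %% 3 + 1]; r <- tri[(k + 1) %% 3 + 1]
        ct <- tryCatch(cot_at(v[p, ], v[q, ], v[r, ]),
                       error = function(e) stop(sprintf(
                         "degenerate triangle %d (vertices %s)", t,
                         paste(tri, collapse = ","))))
        L[q, r] <- L[q, r] - ct / 2
        L[r, q] <- L[r, q] - ct / 2
      }
    }
  }
  diag(L) <- 0
  diag(L) <- -rowSums(L)
  L
}

crossprod3 <- function(u, w) {
  c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
    u[1] * w[2] - u[2] * w[1])
}

#' Standard electrode montage on the outer shell
#'
#' Deterministic Fibonacci-spiral layout over a spherical cap (vertex down
#' to slightly below the equator), emulating an extended 10-20 cap.
#'
#' @param n number of electrodes.
#' @param radius scalp sphere radius in meters.
#' @param cap_z lowest z (as a fraction of the radius) covered by the cap.
#' @return Data frame with `name`, `x`, `y`, `z`.
#' @export
standard_electrodes <- function(n = 64, radius = 0.1, cap_z = -0.35) {
  i <- seq_len(n)
  z <- 1 - (1 - cap_z) * (i - 0.5) / n
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  data.frame(name = sprintf("E%02d", i),
             x = radius * r * cos(th), y = radius * r * sin(th),
             z = radius * z)
}

## Per-degree surface coefficient of a radial unit dipole inside a layered
## sphere with insulating exterior. Radii are normalized by the outer
## radius R; the dipole sits at normalized radius x in the innermost layer.
## Returns c_n such that V(electrode) = sum_n c_n P_n(cos gamma).
layered_sphere_coefs <- function(n_max, x, u_bounds, sigmas, R) {
  n_layers <- length(sigmas)
  cn <- numeric(n_max)
  for (n in seq_len(n_max)) {
    S <- n * x^(n - 1) / (4 * pi * sigmas[1] * R^2) # source u^-(n+1) coef
    ## unknowns: a1, then (a_j, b_j) for j = 2..L
    m <- 2 * n_layers - 1
    A <- matrix(0, m, m); rhs <- numeric(m)
    col_a <- function(j) if (j == 1) 1L else 2L * (j - 1L)
    col_b <- function(j) 2L * (j - 1L) + 1L
    row <- 0
    for (j in seq_len(n_layers - 1)) {
      u <- u_bounds[j]
      ## potential continuity
      row <- row + 1
      A[row, col_a(j)] <- u^n
      if (j > 1) A[row, col_b(j)] <- u^(-(n + 1))
      A[row, col_a(j + 1)] <- -u^n
      A[row, col_b(j + 1)] <- -u^(-(n + 1))
      if (j == 1) rhs[row] <- -S * u^(-(n + 1))
      ## radial current continuity
      row <- row + 1
      A[row, col_a(j)] <- sigmas[j] * n * u^(n - 1)
      if (j > 1) A[row, col_b(j)] <- -sigmas[j] * (n + 1) * u^(-(n + 2))
      A[row, col_a(j + 1)] <- -sigmas[j + 1] * n * u^(n - 1)
      A[row, col_b(j + 1)] <- sigmas[j + 1] * (n + 1) * u^(-(n + 2))
      if (j == 1) rhs[row] <- sigmas[1] * (n + 1) * S * u^(-(n + 2))
    }
    ## insulating outer boundary at u = 1
    row <- row + 1
    A[row, col_a(n_layers)] <- n
    A[row, col_b(n_layers)] <- -(n + 1)
    ## equilibrate: u^(+-n) terms span many orders of magnitude at high n
    rs <- apply(abs(A), 1, max)
    A <- A / rs; rhs <- rhs / rs
    cs <- apply(abs(A), 2, max)
    A <- sweep(A, 2, cs, "/")
    sol <- solve(A, rhs) / cs
    cn[n] <- sol[col_a(n_layers)] + sol[col_b(n_layers)]
  }
  cn
}

## Evaluate sum_n c_n P_n(cos gamma) over a matrix of cosines by upward
## Legendre recursion.
legendre_sum <- function(cn, cosg) {
  p_prev <- matrix(1, nrow(cosg), ncol(cosg)) # P_0
  p_cur <- cosg                               # P_1
  out <- cn[1] * p_cur
  for (n in 2:length(cn)) {
    p_next <- ((2 * n - 1) * cosg * p_cur - (n - 1) * p_prev) / n
    out <- out + cn[n] * p_next
    p_prev <- p_cur; p_cur <- p_next
  }
  out
}

#' Analytic spherical-head lead field
#'
#' Potential at each scalp electrode from a unit radial current dipole at
#' each mesh vertex, for a three-shell concentric-sphere head (brain,
#' skull, scalp) solved by spherical-harmonic series expansion. Columns
#' are average-referenced.
#'
#' @param mesh source mesh (vertices strictly inside the innermost shell).
#' @param electrode_pos `C x 3` matrix or data frame with `x`, `y`, `z`;
#'   positions are projected radially onto the outer shell.
#' @param conductivities length-3 vector `(scalp, skull, brain)` in S/m.
#' @param radii shell boundary radii in meters, innermost first.
#' @param n_max series truncation degree.
#' @return `C x G` lead field matrix (volts per unit dipole moment).
#' @export
spherical_lead_field <- function(mesh, electrode_pos,
                                 conductivities = c(scalp = 0.33,
                                                    skull = 0.022,
                                                    brain = 0.33),
                                 radii = c(0.087, 0.092, 0.100),
                                 n_max = 140) {
  if (is.data.frame(electrode_pos))
    electrode_pos <- as.matrix(electrode_pos[, c("x", "y", "z")])
  R <- radii[length(radii)]
  b <- sqrt(sum(mesh$vertices[1, ]^2))
  if (b >= radii[1])
    stop("geometry error: dipoles must lie strictly inside the innermost shell")
  x <- b / R
  ## conductivities given outside-in (scalp, skull, brain); solve inside-out
  sig <- rev(as.numeric(conductivities))
  cn <- layered_sphere_coefs(n_max, x, u_bounds = radii[-length(radii)] / R,
                             sigmas = sig, R = R)
  epos <- electrode_pos / sqrt(rowSums(electrode_pos^2)) # radial projection
  vdir <- mesh$normals
  cosg <- epos %*% t(vdir)
  cosg[cosg > 1] <- 1; cosg[cosg < -1] <- -1
  K <- legendre_sum(cn, cosg)
  K <- sweep(K, 2, colMeans(K)) # average reference
  dimnames(K) <- NULL
  K
}

#' Default nine-region cortical ROI specification
#'
#' Bilateral inferior occipital, superior parietal and precentral (motor)
#' regions plus three midline regions (anterior cingulate, supplementary
#' motor area, precuneus) whose left/right gridpoint sets are merged
#' across the midline.
#'
#' @param radius ROI radius in meters around each seed.
#' @return A list of ROI specs (`name`, `seeds` matrix, `radius`, `merge`).
#' @export
default_roi_specs <- function(radius = 0.024) {
  unit <- function(v) v / sqrt(sum(v^2))
  one <- function(name, dirs, merge = FALSE)
    list(name = name, seeds = t(apply(dirs, 1, unit)), radius = radius,
         merge = merge)
  list(
    one("L_Occ", rbind(c(-0.40, -0.90, 0.10))),
    one("R_Occ", rbind(c(0.40, -0.90, 0.10))),
    one("L_Par", rbind(c(-0.55, -0.35, 0.75))),
    one("R_Par", rbind(c(0.55, -0.35, 0.75))),
    one("L_Mot", rbind(c(-0.60, 0.20, 0.75))),
    one("R_Mot", rbind(c(0.60, 0.20, 0.75))),
    one("ACC", rbind(c(-0.10, 0.85, 0.45), c(0.10, 0.85, 0.45)), merge = TRUE),
    one("SMA", rbind(c(-0.10, 0.25, 0.96), c(0.10, 0.25, 0.96)), merge = TRUE),
    one("Prec", rbind(c(-0.10, -0.60, 0.78), c(0.10, -0.60, 0.78)),
        merge = TRUE)
  )
}

#' Map named ROIs to mesh gridpoints
#'
#' Each ROI collects the vertices within `radius` (Euclidean) of any of
#' its seed directions (seeds are unit directions scaled to the mesh
#' radius). Merged ROIs union their bilateral seed sets into one region.
#' A vertex claimed by several ROIs goes to the nearest seed.
#'
#' @param mesh source mesh.
#' @param roi_specs list of specs as produced by [default_roi_specs()].
#' @return Named list of integer vertex index vectors.
#' @export
define_roi_gridpoints <- function(mesh, roi_specs) {
  v <- mesh$vertices
  G <- nrow(v)
  best_roi <- rep(NA_integer_, G)
  best_d <- rep(Inf, G)
  for (ri in seq_along(roi_specs)) {
    spec <- roi_specs[[ri]]
    seeds <- spec$seeds * mesh$radius
    for (si in seq_len(nrow(seeds))) {
      d <- sqrt(colSums((t(v) - seeds[si, ])^2))
      hit <- which(d <= spec$radius & d < best_d)
      best_roi[hit] <- ri
      best_d[hit] <- d[hit]
    }
  }
  out <- lapply(seq_along(roi_specs), function(ri) which(best_roi == ri))
  names(out) <- vapply(roi_specs, `[[`, "", "name")
  empty <- names(out)[lengths(out) == 0]
  if (length(empty))
    stop("empty ROI gridpoint set for: ", paste(empty, collapse = ", "))
  out
}

#' Assemble a head model
#'
#' Bundles the source mesh, electrode montage, lead field, surface
#' Laplacian and ROI gridpoint map used by the inverse and synthetic
#' stages.
#'
#' @param subdivisions icosphere subdivision level (`10 * 4^s + 2`
#'   vertices).
#' @param electrodes electrode data frame (default [standard_electrodes()]
#'   with 64 channels).
#' @param conductivities `(scalp, skull, brain)` in S/m.
#' @param radii shell boundary radii in meters, innermost first.
#' @param roi_specs ROI specification (default [default_roi_specs()]).
#' @param laplacian Laplacian weighting scheme.
#' @param mesh_radius cortical mesh radius in meters.
#' @return A `head_model` with fields `mesh`, `electrodes`, `K`, `H_lap`,
#'   `roi_map`, `conductivities`, `radii`.
#' @export
build_head_model <- function(subdivisions = 3,
                             electrodes = standard_electrodes(64),
                             conductivities = c(scalp = 0.33, skull = 0.022,
                                                brain = 0.33),
                             radii = c(0.087, 0.092, 0.100),
                             roi_specs = default_roi_specs(),
                             laplacian = c("graph", "cotangent"),
                             mesh_radius = 0.082) {
  mesh <- build_source_mesh(subdivisions, radius = mesh_radius)
  K <- spherical_lead_field(mesh, electrodes, conductivities, radii)
  H <- surface_laplacian(mesh, match.arg(laplacian))
  roi_map <- define_roi_gridpoints(mesh, roi_specs)
  structure(list(mesh = mesh, electrodes = electrodes, K = K, H_lap = H,
                 roi_map = roi_map, conductivities = conductivities,
                 radii = radii),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %d electrodes x %d gridpoints; %d ROIs (%s)\n",
              nrow(x$K), ncol(x$K), length(x$roi_map),
              paste(names(x$roi_map), collapse = ", ")))
  invisible(x)
}

#' Write / read a mesh in OFF format
#' @param mesh source mesh.
#' @param path destination file.
#' @return `path` (writer) or a `source_mesh` (reader).
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  write.table(format(mesh$vertices, digits = 17), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cbind(3L, mesh$triangles - 1L), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "OFF")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  v <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + counts[1])]),
                                         "\\s+"))), ncol = 3, byrow = TRUE)
  f <- matrix(as.integer(unlist(strsplit(trimws(
    lines[(3 + counts[1]):(2 + counts[1] + counts[2])]), "\\s+"))),
    ncol = 4, byrow = TRUE)[, 2:4] + 1L
  radius <- sqrt(sum(v[1, ]^2))
  structure(list(vertices = v, triangles = f, normals = v / radius,
                 radius = radius),
            class = "source_mesh")
}
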