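# STL surface geometry input. A small self-contained reader (ASCII and
# binary) is included because no STL parser is available in the R stack this
# package targets; micro-CT derived ear surfaces are distributed as STL.

read_stl <- function(path) {
  con <- file(path, "rb")
  head80 <- readBin(con, raw(), n = 80)
  n_tri_bin <- readBin(con, integer(), size = 4, endian = "little")
  size <- file.info(path)$size
  close(con)
  is_binary <- isTRUE(size == 84 + 50 * n_tri_bin)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, raw(), n = 84))
    v <- matrix(0, n_tri_bin * 3L, 3)
    for (i in seq_len(n_tri_bin)) {
      rec <- readBin(con, numeric(), n = 12, size = 4, endian = "little")
      invisible(readBin(con, raw(), n = 2))
      v[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
    return(v)
  }
  txt <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex", txt, value = TRUE)
  if (!length(vx)) abort("Not a readable STL file (no facets found).")
  parts <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  if (nrow(parts) %% 3 != 0) abort("Malformed ASCII STL: vertex count not a multiple of 3.")
  parts
}

#' Load an STL surface geometry
#'
#' Reads a binary or ASCII STL surface, merges coincident vertices, verifies
#' the surface is watertight (every edge shared by exactly two facets, no
#' degenerate facets), measures the enclosed volume by the divergence theorem,
#' and fills the interior with a uniform cut-cell tetrahedral mesh (cubes
#' whose centres lie inside the surface, each split into six tetrahedra).
#' The surface triangles are tagged `shell_wall`.
#'
#' @param path Path to the STL file.
#' @param units Declared STL length unit: `"mm"` (micro-CT convention,
#'   default) or `"m"`.
#' @param target_h Cut-cell size for the interior mesh, m (default: 1/12 of
#'   the largest bounding-box extent).
#' @return An `ear_mesh` whose `meta` records the surface triangle count and
#'   `enclosed_volume_m3`.
#' @export
load_stl_geometry <- function(path, units = c("mm", "m"), target_h = NULL) {
  units <- match.arg(units)
  v <- read_stl(path)
  if (units == "mm") v <- v * 1e-3
  # merge coincident vertices
  scale <- max(apply(v, 2, function(x) diff(range(x))), 1e-300)
  key <- apply(round(v / (scale * 1e-9)), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- v[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  # degenerate facets
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3])) {
    abort("STL surface has degenerate facets.")
  }
  # watertightness: each undirected edge in exactly two facets
  ed <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ek <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(ek)
  if (any(cnt != 2)) {
    abort(sprintf("STL surface is not watertight: %d edge(s) not shared by exactly two facets.",
                  sum(cnt != 2)))
  }
  # enclosed volume (divergence theorem; sign from facet orientation)
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  cc <- verts[faces[, 3], , drop = FALSE]
  vol <- abs(sum(
    a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6)
  ext <- apply(verts, 2, range)
  if (is.null(target_h)) target_h <- max(ext[2, ] - ext[1, ]) / 12
  grid <- lapply(1:3, function(d) {
    seq(ext[1, d] + target_h / 2, ext[2, d] - target_h / 2 + 1e-15, by = target_h)
  })
  centers <- as.matrix(expand.grid(grid[[1]], grid[[2]], grid[[3]]))
  inside <- points_in_surface(centers, verts, faces)
  keep <- centers[inside, , drop = FALSE]
  mesh <- voxel_tets(keep, target_h)
  mesh$tri <- list(shell_wall = NULL)
  mesh$meta <- list(enclosed_volume_m3 = vol, n_surface_facets = nrow(faces),
                    surface_vertices = verts, surface_faces = faces,
                    units = units)
  mesh
}

# z-ray parity test, vectorised over query points per facet
points_in_surface <- function(pts, verts, faces) {
  crossings <- integer(nrow(pts))
  for (i in seq_len(nrow(faces))) {
    tri <- verts[faces[i, ], , drop = FALSE]
    xmin <- min(tri[, 1]); xmax <- max(tri[, 1])
    ymin <- min(tri[, 2]); ymax <- max(tri[, 2])
    cand <- which(pts[, 1] >= xmin & pts[, 1] <= xmax &
                    pts[, 2] >= ymin & pts[, 2] <= ymax)
    if (!length(cand)) next
    d <- tri[2, 1:2] - tri[1, 1:2]
    e <- tri[3, 1:2] - tri[1, 1:2]
    det <- d[1] * e[2] - d[2] * e[1]
    if (abs(det) < 1e-300) next
    px <- pts[cand, 1] - tri[1, 1]
    py <- pts[cand, 2] - tri[1, 2]
    u <- (px * e[2] - py * e[1]) / det
    w <- (-px * d[2] + py * d[1]) / det
    hit <- u >= 0 & w >= 0 & u + w <= 1
    if (!any(hit)) next
    zs <- tri[1, 3] + u[hit] * (tri[2, 3] - tri[1, 3]) + w[hit] * (tri[3, 3] - tri[1, 3])
    above <- zs > pts[cand[hit], 3]
    crossings[cand[hit][above]] <- crossings[cand[hit][above]] + 1L
  }
  crossings %% 2L == 1L
}

# six-tet Kuhn split of axis-aligned cubes centred on `centers`
voxel_tets <- function(centers, h) {
  if (nrow(centers) == 0) abort("No interior voxels; refine `target_h`.")
  corners <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5))) * h
  allv <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(corners, 2, centers[i, ], "+")
  }))
  key <- apply(round(allv / (h * 1e-6)), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  nodes <- allv[uk, , drop = FALSE]
  idx <- matrix(match(key, key[uk]), ncol = 8, byrow = TRUE)
  # Kuhn subdivision along the (1,1,1) diagonal: corners indexed by
  # expand.grid order (x fastest): 1:(---) 2:(+--) 3:(-+-) 4:(++-)
  # 5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  paths <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                 c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  tets <- do.call(rbind, lapply(seq_len(6), function(p) idx[, paths[p, ], drop = FALSE]))
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  structure(list(nodes = nodes, tets = tets, tri = list(), node_pairs = NULL,
                 sphere_radius = NA_real_, h_max = mesh_hmax(nodes, tets)),
            class = "ear_mesh")
}
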